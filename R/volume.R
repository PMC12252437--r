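#' Construct a volume grid
#'
#' The universal image carrier of the package: a 3D array of non-negative
#' intensities (arbitrary activity units) together with its voxel spacing in
#' mm. Axes 0 and 1 (R indices 1 and 2) span the transaxial (XY) plane; axis 2
#' (R index 3) is the axial (Z) direction. No reorientation is performed: the
#' file's i,j,k axes map directly onto the array axes.
#'
#' @param data numeric 3D array of finite intensities.
#' @param spacing numeric length-3 vector of voxel edge lengths in mm, all
#'   strictly positive.
#' @param origin_note free-text provenance tag carried along with the volume.
#' @param affine optional 4x4 affine recorded at load time; passed through on
#'   write, never used for processing (all filtering acts on the voxel
#'   lattice).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing = c(2, 2, 2), origin_note = "",
                        affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (length(spacing) != 3L || !is.numeric(spacing))
    stop("`spacing` must be a numeric vector of length 3")
  spacing <- as.numeric(spacing)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all voxel spacings must be finite and strictly positive")
  if (any(dim(data) < 12L))
    stop("all dimensions must be at least 12 voxels (SSIM window support)")
  if (!all(is.finite(data)))
    stop("volume contains non-finite values")
  storage.mode(data) <- "double"
  structure(
    list(data = data, spacing = spacing,
         origin_note = as.character(origin_note)[1L], affine = affine),
    class = "volume_grid"
  )
}

#' Test for a volume grid
#' @param x object to test.
#' @return `TRUE` if `x` is a `volume_grid`.
#' @export
is_volume_grid <- function(x) inherits(x, "volume_grid")

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]", min(x$data), max(x$data)))
  if (nzchar(x$origin_note)) cat("  (", x$origin_note, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

# Internal: check two volumes share a lattice.
check_same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes have different dimensions")
  if (max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("volumes have different voxel spacings")
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Loads a `.nii` or `.nii.gz` file into a [volume_grid]. Voxel spacing is
#' taken from the header `pixdim`; 4D files with a singleton last dimension
#' are squeezed to 3D. Files containing non-finite voxels, non-3D content, or
#' non-positive spacings are rejected rather than silently passed through.
#'
#' @param path path to a NIfTI-1 file.
#' @return A [volume_grid].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  # drop RNifti's internal attributes; keep only the dims
  attributes(arr) <- list(dim = dim(arr))
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) {
    arr <- array(arr, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop("expected a 3D volume (or 4D with singleton last dimension), got ",
         length(d), "D")
  px <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(px)) || any(px <= 0))
    stop("header voxel spacing must be strictly positive")
  if (!all(is.finite(arr)))
    stop("volume contains non-finite voxels: ", path)
  aff <- tryCatch(structure(RNifti::xform(img), class = NULL),
                  error = function(e) NULL)
  volume_grid(arr, spacing = px, origin_note = basename(path), affine = aff)
}

#' Write a NIfTI-1 volume
#'
#' Stores the volume as 32-bit float NIfTI-1 (intensities are relative
#' activity; precision beyond 1e-6 is meaningless here). Voxel spacing is
#' written to the header exactly; a recorded affine, if any, is passed
#' through.
#'
#' @param v a [volume_grid].
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  stopifnot(is_volume_grid(v))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(v$data)
  if (!is.null(v$affine) && is.matrix(v$affine) &&
      all(dim(v$affine) == c(4L, 4L))) {
    img <- tryCatch(RNifti::`sform<-`(img, structure(v$affine, code = 2L)),
                    error = function(e) img)
  }
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}
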