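#' Convert Gaussian FWHM to standard deviation
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`, the standard identity between the
#' full width at half maximum of a Gaussian kernel and its standard deviation.
#' All user-facing resolution quantities in this package are FWHM in mm;
#' sigma appears only when kernels are built.
#'
#' @param fwhm FWHM in mm (vectorized, each element >= 0).
#' @return Standard deviation(s) in mm.
#' @seealso [sigma_to_fwhm()]
#' @export
fwhm_to_sigma <- function(fwhm) {
  if (any(!is.finite(fwhm)) || any(fwhm < 0))
    stop("fwhm must be finite and non-negative")
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Convert Gaussian standard deviation to FWHM
#' @param sigma standard deviation(s) in mm, each >= 0.
#' @return FWHM(s) in mm.
#' @export
sigma_to_fwhm <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("sigma must be finite and non-negative")
  sigma * (2 * sqrt(2 * log(2)))
}

#' Anisotropic Gaussian filter parameters
#'
#' The optimization variable of the harmonization protocol: one FWHM shared by
#' both in-plane (XY) axes and one FWHM for the axial (Z) axis, both in mm.
#' `(0, 0)` is the identity filter.
#'
#' @param fwhm_xy in-plane FWHM in mm, >= 0.
#' @param fwhm_z axial FWHM in mm, >= 0.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(fwhm_xy, fwhm_z) {
  if (!is.finite(fwhm_xy) || !is.finite(fwhm_z) || fwhm_xy < 0 || fwhm_z < 0)
    stop("filter FWHM components must be finite and >= 0")
  structure(list(fwhm_xy = as.numeric(fwhm_xy), fwhm_z = as.numeric(fwhm_z)),
            class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf("<filter_params> FWHM_XY = %.4g mm, FWHM_Z = %.4g mm\n",
              x$fwhm_xy, x$fwhm_z))
  invisible(x)
}

#' A scanner's effective intrinsic resolution
#'
#' Effective resolution (FWHM in mm) of a PET scanner's reconstructed images,
#' given separately for the transaxial plane and the axial direction, plus
#' optional subject counts for the two diagnostic groups commonly pooled in
#' multicenter FDG studies. Resolutions outside 1--15 mm are rejected as
#' probable unit mistakes.
#'
#' @param name scanner label.
#' @param fwhm_xy,fwhm_z effective resolution in mm (1--15).
#' @param n_subjects_ad,n_subjects_cn optional subject counts.
#' @return An object of class `scanner_profile`.
#' @export
scanner_profile <- function(name, fwhm_xy, fwhm_z,
                            n_subjects_ad = NA_integer_,
                            n_subjects_cn = NA_integer_) {
  if (!is.finite(fwhm_xy) || !is.finite(fwhm_z) ||
      fwhm_xy < 1 || fwhm_xy > 15 || fwhm_z < 1 || fwhm_z > 15)
    stop("scanner resolutions must lie in 1-15 mm; check units")
  structure(list(name = as.character(name)[1L],
                 fwhm_xy = as.numeric(fwhm_xy), fwhm_z = as.numeric(fwhm_z),
                 n_subjects_ad = as.integer(n_subjects_ad),
                 n_subjects_cn = as.integer(n_subjects_cn)),
            class = "scanner_profile")
}

#' @export
print.scanner_profile <- function(x, ...) {
  cat(sprintf("<scanner_profile> %s: FWHM_XY = %.3g mm, FWHM_Z = %.3g mm\n",
              x$name, x$fwhm_xy, x$fwhm_z))
  invisible(x)
}

# Internal: discrete Gaussian taps for a given sigma in voxel units,
# truncated at 4*sigma (sub-1e-4 truncation error), normalized to unit sum.
# sigma below ~1e-4 voxels is treated as the identity (NULL kernel).
gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox < 1e-4) return(NULL)
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  x <- seq.int(-r, r)
  k <- exp(-0.5 * (x / sigma_vox)^2)
  k / sum(k)
}

# Internal: separable convolution of a bare 3D array with per-axis sigmas in
# voxel units; replicate padding at the boundary.
conv3_sigma <- function(arr, sigma_vox) {
  d <- dim(arr)
  x <- as.numeric(arr)
  for (ax in 0:2) {
    k <- gaussian_kernel(sigma_vox[ax + 1L])
    if (!is.null(k)) x <- conv_axis_cpp(x, d, k, ax)
  }
  array(x, dim = d)
}

#' Apply an anisotropic Gaussian filter to a volume
#'
#' Separable Gaussian smoothing with the filter expressed in mm FWHM: the
#' per-axis sigma in voxels is `fwhm_to_sigma(fwhm) / spacing` along that
#' axis. The in-plane FWHM applies identically to both XY axes. Boundary
#' handling is replicate-nearest padding; kernels are truncated at 4 sigma.
#' The identity filter `(0, 0)` returns a voxelwise-equal copy.
#'
#' @param v a [volume_grid].
#' @param theta a [filter_params] (or numeric length-2 `c(fwhm_xy, fwhm_z)`).
#' @return A [volume_grid] with the same shape and spacing.
#' @export
apply_gaussian <- function(v, theta) {
  stopifnot(is_volume_grid(v))
  theta <- as_filter_params(theta)
  sig_mm <- fwhm_to_sigma(c(theta$fwhm_xy, theta$fwhm_xy, theta$fwhm_z))
  out <- conv3_sigma(v$data, sig_mm / v$spacing)
  volume_grid(out, spacing = v$spacing, origin_note = v$origin_note,
              affine = v$affine)
}

# Internal: accept filter_params or numeric length 2.
as_filter_params <- function(theta) {
  if (inherits(theta, "filter_params")) return(theta)
  if (is.numeric(theta) && length(theta) == 2L)
    return(filter_params(theta[1L], theta[2L]))
  stop("`theta` must be a filter_params object or numeric length-2 vector")
}

#' Required filter width from the quadratic combination rule
#'
#' Sequential Gaussian blurs combine in quadrature, so the filter bringing a
#' scanner of effective resolution `FWHM_scanner` to a coarser target
#' resolution satisfies
#' `FWHM_filter^2 = FWHM_target^2 - FWHM_scanner^2`.
#' When the scanner resolution already meets or exceeds the target
#' (`target <= scanner`) the result is clamped to 0 with a warning: no
#' smoothing can sharpen an image.
#'
#' @param target_fwhm target resolution in mm, > 0.
#' @param scanner_fwhm scanner effective resolution in mm, > 0. Applied per
#'   direction with direction-specific scanner values.
#' @return Required filter FWHM in mm.
#' @export
required_filter <- function(target_fwhm, scanner_fwhm) {
  if (!is.finite(target_fwhm) || target_fwhm <= 0 ||
      !is.finite(scanner_fwhm) || scanner_fwhm <= 0)
    stop("target and scanner FWHM must be finite and positive")
  if (target_fwhm <= scanner_fwhm) {
    if (target_fwhm < scanner_fwhm)
      warning(sprintf(
        "target resolution %.3g mm is finer than scanner resolution %.3g mm; filter clamped to 0",
        target_fwhm, scanner_fwhm))
    return(0)
  }
  sqrt(target_fwhm^2 - scanner_fwhm^2)
}

#' Smooth a reference average to a target resolution
#'
#' Applies the quadratic-rule filter, separately in the XY and Z directions,
#' that brings the reference scanner's cohort-average image to the requested
#' target resolution. Components where the scanner already meets the target
#' are clamped to zero (with a warning from [required_filter()]).
#'
#' @param ref_avg the reference cohort-average [volume_grid].
#' @param scanner the reference scanner's [scanner_profile].
#' @param target_fwhm target resolution in mm.
#' @return The smoothed reference [volume_grid].
#' @export
prepare_reference <- function(ref_avg, scanner, target_fwhm) {
  stopifnot(is_volume_grid(ref_avg), inherits(scanner, "scanner_profile"))
  theta <- filter_params(required_filter(target_fwhm, scanner$fwhm_xy),
                         required_filter(target_fwhm, scanner$fwhm_z))
  apply_gaussian(ref_avg, theta)
}
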