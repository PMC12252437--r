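#' Parameters of the 3D structural similarity index
#'
#' Local statistics are computed under a 3D Gaussian-weighted window of
#' standard deviation `window_sigma` voxels truncated at `half_width` voxels
#' per side (defaults 1.5 and 5, i.e. 11x11x11 support), matching the common
#' volumetric SSIM convention. Stabilizers are `C1 = (k1 * L)^2` and
#' `C2 = (k2 * L)^2` with `L` the dynamic range.
#'
#' @param window_sigma Gaussian window sigma in voxels.
#' @param half_width window half-width in voxels (>= 3); support is
#'   `(2 * half_width + 1)^3`.
#' @param k1,k2 dimensionless stabilizer constants, > 0.
#' @param dynamic_range intensity dynamic range `L`. The default (`NULL`)
#'   uses `max(ref) - min(ref)` of the *reference* image, which keeps the
#'   objective fixed while the test image is being filtered; supply a value
#'   to make the score symmetric in its arguments.
#' @param uniform_window if `TRUE`, use a flat (box) window instead of the
#'   Gaussian-weighted one.
#' @return An object of class `ssim_params`.
#' @export
ssim_params <- function(window_sigma = 1.5, half_width = 5L,
                        k1 = 0.01, k2 = 0.03, dynamic_range = NULL,
                        uniform_window = FALSE) {
  if (k1 <= 0 || k2 <= 0) stop("k1 and k2 must be positive")
  if (half_width < 3L) stop("window half-width must be at least 3 voxels")
  if (!is.null(dynamic_range) &&
      (!is.finite(dynamic_range) || dynamic_range <= 0))
    stop("dynamic_range must be positive")
  if (window_sigma <= 0) stop("window_sigma must be positive")
  structure(list(window_sigma = window_sigma,
                 half_width = as.integer(half_width),
                 k1 = k1, k2 = k2, dynamic_range = dynamic_range,
                 uniform_window = isTRUE(uniform_window)),
            class = "ssim_params")
}

# Internal: normalized window taps.
ssim_window_kernel <- function(p) {
  x <- seq.int(-p$half_width, p$half_width)
  k <- if (p$uniform_window) rep(1, length(x))
       else exp(-0.5 * (x / p$window_sigma)^2)
  k / sum(k)
}

# Internal: windowed local mean of a bare array (replicate padding).
win3 <- function(arr, kern) {
  d <- dim(arr)
  x <- as.numeric(arr)
  for (ax in 0:2) x <- conv_axis_cpp(x, d, kern, ax)
  array(x, dim = d)
}

# Internal: precompute reference-side local statistics so that repeated SSIM
# evaluations against the same reference (grid search, refinement) only pay
# for the test side.
ssim_ref_stats <- function(ref_data, p) {
  L <- if (is.null(p$dynamic_range)) max(ref_data) - min(ref_data)
       else p$dynamic_range
  if (!is.finite(L) || L <= 0)
    stop("dynamic range is zero; SSIM undefined for a constant reference")
  kern <- ssim_window_kernel(p)
  mu1 <- win3(ref_data, kern)
  s1 <- win3(ref_data * ref_data, kern) - mu1 * mu1
  list(ref = ref_data, mu1 = mu1, mu1sq = mu1 * mu1, s1 = s1,
       C1 = (p$k1 * L)^2, C2 = (p$k2 * L)^2, kern = kern)
}

# Internal: SSIM map mean given precomputed reference stats.
ssim_from_stats <- function(st, test_data, mask = NULL) {
  mu2 <- win3(test_data, st$kern)
  s2 <- win3(test_data * test_data, st$kern) - mu2 * mu2
  s12 <- win3(st$ref * test_data, st$kern) - st$mu1 * mu2
  map <- ((2 * st$mu1 * mu2 + st$C1) * (2 * s12 + st$C2)) /
         ((st$mu1sq + mu2 * mu2 + st$C1) * (st$s1 + s2 + st$C2))
  if (is.null(mask)) mean(map) else mean(map[mask])
}

#' 3D structural similarity between two volumes
#'
#' Mean over all voxels of the local SSIM map. Local means, variances and
#' covariance are Gaussian-weighted within the window of `p`; the map at each
#' voxel is
#' `((2*mu1*mu2 + C1) * (2*cov + C2)) / ((mu1^2 + mu2^2 + C1) * (var1 + var2 + C2))`.
#' Identical volumes score exactly 1. Deterministic.
#'
#' @param ref,test [volume_grid]s with identical shape and spacing.
#' @param p an [ssim_params].
#' @param mask optional logical array of the same shape; when supplied the
#'   map is averaged over `mask` voxels only (e.g. a brain mask).
#' @return SSIM score in \[-1, 1\].
#' @export
compute_ssim <- function(ref, test, p = ssim_params(), mask = NULL) {
  stopifnot(is_volume_grid(ref), is_volume_grid(test))
  check_same_geometry(ref, test)
  if (!is.null(mask) && !identical(dim(mask), dim(ref$data)))
    stop("mask shape must match the volumes")
  st <- ssim_ref_stats(ref$data, p)
  ssim_from_stats(st, test$data, mask)
}

#' Alternate similarity metrics
#'
#' Metrics other than SSIM that are sometimes used to compare reconstructed
#' volumes: mean squared error, peak signal-to-noise ratio, normalized
#' cross-correlation (Pearson), and mutual information over a 64-bin joint
#' intensity histogram (in nats, each image binned over its own range).
#' Provided for sensitivity comparisons against the SSIM objective.
#'
#' @param ref,test [volume_grid]s with identical shape and spacing.
#' @param metric one of `"mse"`, `"psnr"`, `"ncc"`, `"mi"`.
#' @param dynamic_range range `L` used by PSNR; defaults to the reference
#'   image's `max - min`.
#' @return A single numeric score.
#' @export
compute_alt_metric <- function(ref, test, metric = c("mse", "psnr", "ncc", "mi"),
                               dynamic_range = NULL) {
  stopifnot(is_volume_grid(ref), is_volume_grid(test))
  check_same_geometry(ref, test)
  metric <- match.arg(metric)
  x <- as.numeric(ref$data)
  y <- as.numeric(test$data)
  switch(metric,
    mse = mean((x - y)^2),
    psnr = {
      L <- if (is.null(dynamic_range)) max(x) - min(x) else dynamic_range
      if (L <= 0) stop("dynamic range is zero; PSNR undefined")
      m <- mean((x - y)^2)
      if (m == 0) Inf else 10 * log10(L^2 / m)
    },
    ncc = {
      if (sd(x) == 0 || sd(y) == 0)
        stop("correlation undefined for a constant volume")
      stats::cor(x, y)
    },
    mi = mutual_information(x, y, n_bins = 64L)
  )
}

# Internal: mutual information of a joint intensity histogram, in nats.
# Equal-width bins over each vector's own range; a constant vector collapses
# to a single bin (MI 0 against anything).
mutual_information <- function(x, y, n_bins = 64L) {
  bin_of <- function(v) {
    r <- range(v)
    if (r[2] <= r[1]) return(rep(1L, length(v)))
    b <- floor((v - r[1]) / (r[2] - r[1]) * n_bins) + 1L
    pmin.int(b, n_bins)
  }
  joint <- table(bin_of(x), bin_of(y))
  p <- joint / sum(joint)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' SSIM over a 2D grid of filter widths
#'
#' Evaluates `compute_ssim(ref, apply_gaussian(test, c(xy, z)), p)` for every
#' combination of the supplied in-plane and axial FWHM values. Because the
#' filter is separable, the in-plane smoothing of the test volume is computed
#' once per `xy` value and reused across the `z` values. The resulting
#' surface is the optimization landscape of the harmonization objective.
#'
#' @param ref,test [volume_grid]s with identical shape and spacing.
#' @param xy_grid,z_grid non-empty ascending vectors of FWHM values in mm,
#'   all >= 0.
#' @param p an [ssim_params].
#' @param mask optional logical array passed to the SSIM average.
#' @return A numeric matrix of scores with `length(xy_grid)` rows and
#'   `length(z_grid)` columns; grids attached as `dimnames` and as
#'   attributes `xy_grid` / `z_grid`.
#' @export
ssim_surface <- function(ref, test, xy_grid, z_grid, p = ssim_params(),
                         mask = NULL) {
  stopifnot(is_volume_grid(ref), is_volume_grid(test))
  check_same_geometry(ref, test)
  check_grid <- function(g, nm) {
    if (length(g) == 0 || any(!is.finite(g)) || any(g < 0) ||
        is.unsorted(g, strictly = TRUE) && length(g) > 1)
      stop(nm, " must be a non-empty, strictly ascending, non-negative grid")
  }
  check_grid(xy_grid, "xy_grid")
  check_grid(z_grid, "z_grid")
  st <- ssim_ref_stats(ref$data, p)
  d <- dim(test$data)
  out <- matrix(NA_real_, length(xy_grid), length(z_grid),
                dimnames = list(format(xy_grid), format(z_grid)))
  for (i in seq_along(xy_grid)) {
    sig_xy_vox <- fwhm_to_sigma(xy_grid[i]) / test$spacing[1:2]
    txy <- conv3_sigma(test$data, c(sig_xy_vox, 0))
    for (j in seq_along(z_grid)) {
      sig_z_vox <- fwhm_to_sigma(z_grid[j]) / test$spacing[3]
      tz <- conv3_sigma(txy, c(0, 0, sig_z_vox))
      out[i, j] <- ssim_from_stats(st, tz, mask)
    }
  }
  attr(out, "xy_grid") <- xy_grid
  attr(out, "z_grid") <- z_grid
  out
}

#' Write an SSIM surface to CSV
#'
#' Long-format export with columns `fwhm_xy_mm`, `fwhm_z_mm`, `ssim`.
#'
#' @param surface a matrix from [ssim_surface()].
#' @param path output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_ssim_surface <- function(surface, path) {
  xy <- attr(surface, "xy_grid")
  z <- attr(surface, "z_grid")
  if (is.null(xy) || is.null(z))
    stop("`surface` must come from ssim_surface()")
  df <- data.frame(
    fwhm_xy_mm = rep(xy, times = length(z)),
    fwhm_z_mm = rep(z, each = length(xy)),
    ssim = as.numeric(surface)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
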