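#' Intensity-normalize a volume
#'
#' Rescales a volume so that mean uptake is comparable across subjects before
#' averaging. `global_mean` divides by the mean over all voxels;
#' `masked_mean` divides by the mean over voxels above 20% of the volume's
#' maximum (a crude object mask that excludes empty background); `none` is
#' the identity. After normalization the mean over the chosen region is 1.
#'
#' @param v a [volume_grid].
#' @param mode one of `"global_mean"`, `"masked_mean"`, `"none"`.
#' @return A [volume_grid].
#' @export
normalize_intensity <- function(v, mode = c("global_mean", "masked_mean", "none")) {
  stopifnot(is_volume_grid(v))
  mode <- match.arg(mode)
  if (mode == "none") return(v)
  denom <- switch(mode,
    global_mean = mean(v$data),
    masked_mean = {
      m <- v$data > 0.2 * max(v$data)
      if (!any(m)) stop("empty mask: volume has no voxels above 20% of max")
      mean(v$data[m])
    })
  if (!is.finite(denom) || denom <= 0)
    stop("normalization denominator must be positive (all-zero volume?)")
  volume_grid(v$data / denom, spacing = v$spacing,
              origin_note = v$origin_note, affine = v$affine)
}

#' Average a cohort of volumes
#'
#' Voxelwise arithmetic mean of the intensity-normalized volumes of one
#' scanner's cohort. Averaging suppresses inter-subject metabolic differences
#' and image noise, leaving resolution as the dominant difference between two
#' scanners' averages — the premise of the harmonization protocol.
#'
#' @param volumes non-empty list of [volume_grid]s sharing shape and spacing.
#' @param mode normalization mode applied to each volume before averaging
#'   (see [normalize_intensity()]).
#' @return An object of class `cohort_average` with fields `mean_volume`
#'   (a [volume_grid]), `n_images` and `normalization_mode`.
#' @export
average_cohort <- function(volumes, mode = c("global_mean", "masked_mean", "none")) {
  mode <- match.arg(mode)
  if (!is.list(volumes) || length(volumes) == 0)
    stop("`volumes` must be a non-empty list")
  for (v in volumes) {
    stopifnot(is_volume_grid(v))
    check_same_geometry(volumes[[1L]], v)
  }
  acc <- array(0, dim = dim(volumes[[1L]]$data))
  for (v in volumes) acc <- acc + normalize_intensity(v, mode)$data
  mv <- volume_grid(acc / length(volumes), spacing = volumes[[1L]]$spacing,
                    origin_note = sprintf("cohort average (n=%d)", length(volumes)))
  structure(list(mean_volume = mv, n_images = length(volumes),
                 normalization_mode = mode),
            class = "cohort_average")
}

#' @export
print.cohort_average <- function(x, ...) {
  cat(sprintf("<cohort_average> n = %d, normalization = %s\n",
              x$n_images, x$normalization_mode))
  print(x$mean_volume)
  invisible(x)
}

#' Estimate the harmonizing filter by SSIM maximization
#'
#' Solves `theta* = argmax SSIM(ref_avg, G(theta) * test_avg)` over
#' `theta = (FWHM_XY, FWHM_Z)` in `[0, upper_bound]^2`, in two stages:
#' an exhaustive grid search at `grid_step` spacing, then bounded
#' derivative-free (Nelder-Mead) refinement started at the grid optimum,
#' with parameters clamped to the box. Refinement never degrades the
#' objective: if it fails to improve on the grid optimum, the grid optimum is
#' returned with `converged = FALSE`. Ties on a flat grid plateau break
#' toward the smallest `fwhm_xy`, then smallest `fwhm_z` (least smoothing).
#' Deterministic given its inputs.
#'
#' @param ref_avg reference cohort-average [volume_grid] (already smoothed to
#'   the target resolution, see [prepare_reference()]).
#' @param test_avg test cohort-average [volume_grid].
#' @param upper_bound upper box bound in mm for both components, > 0.
#' @param p an [ssim_params].
#' @param grid_step grid spacing in mm for the search stage, > 0
#'   (default 0.5 mm, finer than the ~1 mm uncertainty scale of the SSIM
#'   landscape).
#' @param mask optional logical array passed to the SSIM average.
#' @param refine_tol parameter tolerance (mm) for declaring the refinement
#'   converged.
#' @return An object of class `optimization_result`: `theta`
#'   (a [filter_params]), `ssim` at the optimum, `surface` (the stage-1 grid,
#'   as from [ssim_surface()]), `grid_theta` (stage-1 optimum), `converged`,
#'   `boundary` (`TRUE` when a component of the optimum sits at the upper
#'   bound — the bound is likely too tight), and `n_eval`.
#' @export
estimate_filter <- function(ref_avg, test_avg, upper_bound,
                            p = ssim_params(), grid_step = 0.5,
                            mask = NULL, refine_tol = 1e-3) {
  stopifnot(is_volume_grid(ref_avg), is_volume_grid(test_avg))
  check_same_geometry(ref_avg, test_avg)
  if (!is.finite(upper_bound) || upper_bound <= 0)
    stop("upper_bound must be positive")
  if (!is.finite(grid_step) || grid_step <= 0)
    stop("grid_step must be positive")

  grid <- seq(0, upper_bound, by = grid_step)
  if (max(grid) < upper_bound - 1e-9) grid <- c(grid, upper_bound)

  surface <- ssim_surface(ref_avg, test_avg, grid, grid, p, mask)
  best <- max(surface)
  hits <- which(surface == best, arr.ind = TRUE)
  # tie-break: smallest fwhm_xy, then smallest fwhm_z
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  grid_theta <- c(grid[hits[1L, 1L]], grid[hits[1L, 2L]])
  grid_ssim <- best

  st <- ssim_ref_stats(ref_avg$data, p)
  n_eval <- length(surface)
  objective <- function(par) {
    par <- pmin(pmax(par, 0), upper_bound)
    sig <- fwhm_to_sigma(c(par[1L], par[1L], par[2L])) / test_avg$spacing
    n_eval <<- n_eval + 1L
    -ssim_from_stats(st, conv3_sigma(test_avg$data, sig), mask)
  }
  opt <- stats::optim(grid_theta, objective, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 300L))
  refined <- pmin(pmax(opt$par, 0), upper_bound)
  refined_ssim <- -opt$value

  if (refined_ssim >= grid_ssim) {
    theta <- refined
    ssim_opt <- refined_ssim
    converged <- opt$convergence == 0L
  } else {
    theta <- grid_theta
    ssim_opt <- grid_ssim
    converged <- FALSE
  }
  boundary <- any(theta >= upper_bound - max(grid_step / 2, refine_tol))
  if (boundary)
    warning("optimum lies at the upper bound; the bound is likely too tight")

  structure(list(theta = filter_params(theta[1L], theta[2L]),
                 ssim = ssim_opt, surface = surface,
                 grid_theta = filter_params(grid_theta[1L], grid_theta[2L]),
                 converged = converged, boundary = boundary,
                 upper_bound = upper_bound, n_eval = n_eval),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "<optimization_result> FWHM_XY = %.3f mm, FWHM_Z = %.3f mm (SSIM %.6f)\n",
    x$theta$fwhm_xy, x$theta$fwhm_z, x$ssim))
  cat(sprintf("  %d objective evaluations; converged: %s; boundary: %s\n",
              x$n_eval, x$converged, x$boundary))
  invisible(x)
}

#' Apply an estimated filter to a set of volumes
#'
#' Filters every test volume with the harmonizing filter, preserving order.
#' By linearity of the mean and of convolution, the average of the harmonized
#' cohort equals the filtered cohort average.
#'
#' @param volumes list of [volume_grid]s.
#' @param theta a [filter_params] (or numeric length-2).
#' @return List of filtered [volume_grid]s in the input order.
#' @export
apply_harmonization <- function(volumes, theta) {
  theta <- as_filter_params(theta)
  lapply(volumes, apply_gaussian, theta = theta)
}
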