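# Internal: accept a scanner_profile, a list with fwhm_xy/fwhm_z, or a
# numeric c(xy, z); simulation only needs the blur widths, and tests of the
# degenerate (near-zero blur) limit need values below the 1 mm sanity floor
# that scanner_profile enforces for real hardware.
as_scanner_blur <- function(scanner) {
  if (inherits(scanner, "scanner_profile"))
    return(list(name = scanner$name, fwhm_xy = scanner$fwhm_xy,
                fwhm_z = scanner$fwhm_z))
  if (is.numeric(scanner) && length(scanner) == 2L)
    return(list(name = "scanner", fwhm_xy = scanner[1L], fwhm_z = scanner[2L]))
  if (is.list(scanner) && all(c("fwhm_xy", "fwhm_z") %in% names(scanner)))
    return(list(name = if (is.null(scanner$name)) "scanner" else scanner$name,
                fwhm_xy = scanner$fwhm_xy, fwhm_z = scanner$fwhm_z))
  stop("`scanner` must be a scanner_profile, list(fwhm_xy=, fwhm_z=), or numeric length-2")
}

#' Recipe for a simulated single-scanner cohort
#'
#' Bundles every knob of the synthetic generator: the phantom geometry, the
#' scanner blur, and the four sources that make two scanners' image sets
#' differ — inter-subject metabolic variability (a global intensity scalar
#' plus a smooth multiplicative regional field), image noise, residual
#' misregistration after spatial normalization (random rigid translation),
#' and scanner resolution itself.
#'
#' @param scanner a [scanner_profile] (or `list(fwhm_xy=, fwhm_z=)` /
#'   numeric length-2) giving the blur applied to every subject.
#' @param n_subjects number of subjects, >= 1.
#' @param shape voxel dimensions (default 79 x 95 x 78, the common
#'   template-space grid for spatially normalized brain PET).
#' @param spacing voxel size in mm (default 2 mm isotropic).
#' @param gm_wm_ratio gray-to-white-matter activity contrast, > 1
#'   (default 4, the standard FDG brain-phantom convention).
#' @param subject_intensity_cv coefficient of variation of the per-subject
#'   global intensity scalar (default 0.05).
#' @param regional_variability_fwhm smoothness (FWHM, mm) of the per-subject
#'   multiplicative regional field (default 20 mm).
#' @param regional_variability_amplitude relative amplitude (SD) of that
#'   field (default 0.05).
#' @param noise_sd_fraction additive Gaussian noise SD as a fraction of the
#'   phantom's mean gray-matter intensity (default 0.05).
#' @param misreg_sd SD in mm of the per-subject random rigid translation
#'   emulating imperfect spatial normalization (default 0.5 mm).
#' @param seed integer seed; each subject's randomness is derived from
#'   `(seed, subject_index)` so cohorts are extensible without reshuffling
#'   earlier subjects.
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(scanner, n_subjects,
                                  shape = c(79L, 95L, 78L),
                                  spacing = c(2, 2, 2),
                                  gm_wm_ratio = 4,
                                  subject_intensity_cv = 0.05,
                                  regional_variability_fwhm = 20,
                                  regional_variability_amplitude = 0.05,
                                  noise_sd_fraction = 0.05,
                                  misreg_sd = 0.5,
                                  seed = 1L) {
  sc <- as_scanner_blur(scanner)
  if (!is.finite(sc$fwhm_xy) || !is.finite(sc$fwhm_z) ||
      sc$fwhm_xy < 0 || sc$fwhm_z < 0)
    stop("scanner blur widths must be finite and >= 0")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (gm_wm_ratio <= 1) stop("gm_wm_ratio must exceed 1")
  vp <- c(subject_intensity_cv, regional_variability_fwhm,
          regional_variability_amplitude, noise_sd_fraction, misreg_sd)
  if (any(!is.finite(vp)) || any(vp < 0))
    stop("variability parameters must be finite and >= 0")
  structure(list(scanner = sc, n_subjects = as.integer(n_subjects),
                 shape = as.integer(shape), spacing = as.numeric(spacing),
                 gm_wm_ratio = gm_wm_ratio,
                 subject_intensity_cv = subject_intensity_cv,
                 regional_variability_fwhm = regional_variability_fwhm,
                 regional_variability_amplitude = regional_variability_amplitude,
                 noise_sd_fraction = noise_sd_fraction,
                 misreg_sd = misreg_sd, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

# Internal: per-subject seed derived from (cohort seed, subject index);
# arithmetic in doubles stays exact well below 2^53 and the result is kept
# inside the 32-bit signed range R requires.
derive_seed <- function(seed, subject_index) {
  as.integer(((abs(as.numeric(seed)) %% 2147483647) * 7919 +
                as.numeric(subject_index) * 104729 + 1) %% 2147483647)
}

#' Deterministic digital brain phantom
#'
#' A piecewise-constant, brain-like activity distribution: an outer "gray
#' matter" ellipsoidal shell whose inner boundary is sinusoidally folded, at
#' intensity `gm_wm_ratio`; an inner "white matter" compartment at intensity
#' 1; two small zero-intensity "ventricle" ellipsoids; zero background. All
#' structures scale with the physical extent of the grid. Identical arguments
#' give bit-identical output.
#'
#' @param shape voxel dimensions, each >= 32.
#' @param spacing voxel size in mm.
#' @param gm_wm_ratio gray-to-white activity contrast, > 1.
#' @return A [volume_grid] whose values are exactly
#'   `{0, 1, gm_wm_ratio}`.
#' @export
make_phantom <- function(shape = c(79L, 95L, 78L), spacing = c(2, 2, 2),
                         gm_wm_ratio = 4) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("phantom grid must be 3D with at least 32 voxels per axis")
  if (gm_wm_ratio <= 1) stop("gm_wm_ratio must exceed 1")
  # All geometry is defined in coordinates normalized by the grid extent, so
  # the phantom scales exactly with the physical field of view and the voxel
  # pattern depends on the shape alone.
  ax <- lapply(1:3, function(i) (seq_len(shape[i]) - (shape[i] + 1) / 2) / shape[i])
  X <- array(rep(ax[[1L]], times = shape[2L] * shape[3L]), dim = shape)
  Y <- array(rep(rep(ax[[2L]], each = shape[1L]), times = shape[3L]), dim = shape)
  Z <- array(rep(ax[[3L]], each = shape[1L] * shape[2L]), dim = shape)

  a_out <- 0.40                            # outer cortical surface semi-axes
  a_wm <- 0.62 * a_out                     # mean GM/WM boundary semi-axes
  e_out <- (X / a_out)^2 + (Y / a_out)^2 + (Z / a_out)^2
  # sinusoidal perturbation folds the GM/WM boundary like cortical sulci
  fold <- 0.25 * sin(10 * pi * X) * sin(11 * pi * Y) * sin(13 * pi * Z)
  e_wm <- (X / a_wm)^2 + (Y / a_wm)^2 + (Z / a_wm)^2

  brain <- e_out <= 1
  wm <- brain & (e_wm <= 1 + fold)
  vx <- 0.10                               # ventricle offset from midline
  vax <- c(0.05, 0.11, 0.08)               # lateral-ventricle semi-axes
  vent <- (((X - vx) / vax[1L])^2 + (Y / vax[2L])^2 + (Z / vax[3L])^2 <= 1) |
    (((X + vx) / vax[1L])^2 + (Y / vax[2L])^2 + (Z / vax[3L])^2 <= 1)

  vol <- array(0, dim = shape)
  vol[brain] <- gm_wm_ratio                # gray-matter shell
  vol[wm] <- 1                             # white-matter core
  vol[vent & brain] <- 0                   # CSF-filled ventricles
  volume_grid(vol, spacing = spacing, origin_note = "digital brain phantom")
}

#' Simulate one subject's image
#'
#' Applies the difference-source pipeline to the phantom, in order:
#' (1) multiply by a subject-specific smooth random field (white noise
#' smoothed to `regional_variability_fwhm`, rescaled to mean 1 and the
#' requested amplitude) and by a global scalar with CV
#' `subject_intensity_cv`; (2) translate by a random 3D sub-voxel shift with
#' per-axis SD `misreg_sd` (separable cubic interpolation); (3) blur with the
#' scanner's `(fwhm_xy, fwhm_z)`; (4) add Gaussian noise with SD
#' `noise_sd_fraction` times the phantom's mean gray-matter intensity (no
#' clipping: reconstructed PET data legitimately contain small negative
#' excursions in low-activity regions). All randomness
#' comes from a generator seeded by `(spec$seed, subject_index)`: the
#' function is pure, reproducible, and order-independent across subjects.
#'
#' @param phantom the noiseless [volume_grid] to degrade.
#' @param spec a [synthetic_cohort_spec].
#' @param subject_index 0-based subject index.
#' @return A [volume_grid].
#' @export
simulate_subject <- function(phantom, spec, subject_index) {
  stopifnot(is_volume_grid(phantom), inherits(spec, "synthetic_cohort_spec"))
  d <- dim(phantom$data)
  sp <- phantom$spacing
  gm_thresh <- (1 + spec$gm_wm_ratio) / 2
  gm_mean <- mean(phantom$data[phantom$data > gm_thresh])
  if (!is.finite(gm_mean)) gm_mean <- max(phantom$data)

  withr::with_seed(derive_seed(spec$seed, subject_index), {
    img <- phantom$data
    # (1) inter-subject metabolic variability
    if (spec$regional_variability_amplitude > 0 &&
        spec$regional_variability_fwhm > 0) {
      w <- array(rnorm(prod(d)), dim = d)
      s <- conv3_sigma(w, rep(fwhm_to_sigma(spec$regional_variability_fwhm), 3) / sp)
      ssd <- sd(s)
      if (ssd > 0) {
        field <- 1 + spec$regional_variability_amplitude * (s - mean(s)) / ssd
        img <- img * field
      }
    }
    if (spec$subject_intensity_cv > 0)
      img <- img * max(1 + spec$subject_intensity_cv * rnorm(1L), 0.05)
    # (2) residual misregistration: random rigid translation
    if (spec$misreg_sd > 0) {
      sh_vox <- rnorm(3L, 0, spec$misreg_sd) / sp
      x <- as.numeric(img)
      for (axi in 0:2)
        if (abs(sh_vox[axi + 1L]) > 1e-12)
          x <- shift_axis_cpp(x, d, sh_vox[axi + 1L], axi)
      img <- array(x, dim = d)
    }
    # (3) scanner resolution
    sig <- fwhm_to_sigma(c(spec$scanner$fwhm_xy, spec$scanner$fwhm_xy,
                           spec$scanner$fwhm_z)) / sp
    img <- conv3_sigma(img, sig)
    # (4) image noise
    if (spec$noise_sd_fraction > 0)
      img <- img + array(rnorm(prod(d), 0, spec$noise_sd_fraction * gm_mean),
                         dim = d)
    volume_grid(img, spacing = sp,
                origin_note = sprintf("synthetic subject %d (%s)",
                                      subject_index, spec$scanner$name))
  })
}

#' Simulate a full cohort
#'
#' Runs [simulate_subject()] for subject indices `0 .. n_subjects - 1`
#' against one phantom (built from the spec's geometry unless supplied).
#'
#' @param spec a [synthetic_cohort_spec].
#' @param phantom optional [volume_grid]; defaults to
#'   `make_phantom(spec$shape, spec$spacing, spec$gm_wm_ratio)`.
#' @return List of `n_subjects` [volume_grid]s.
#' @export
simulate_cohort <- function(spec, phantom = NULL) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  if (is.null(phantom))
    phantom <- make_phantom(spec$shape, spec$spacing, spec$gm_wm_ratio)
  lapply(seq_len(spec$n_subjects) - 1L, simulate_subject,
         phantom = phantom, spec = spec)
}
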