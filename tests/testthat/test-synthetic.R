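test_that("the phantom is piecewise constant with exact GM/WM contrast", {
  ph <- make_phantom(c(40, 44, 40), c(2, 2, 2), gm_wm_ratio = 4)
  vals <- sort(unique(as.numeric(ph$data)))
  expect_identical(vals, c(0, 1, 4))
  gm <- ph$data == 4
  wm <- ph$data == 1
  expect_gt(sum(gm), 0)
  expect_gt(sum(wm), 0)
  expect_identical(mean(ph$data[gm]) / mean(ph$data[wm]), 4)

  again <- make_phantom(c(40, 44, 40), c(2, 2, 2), gm_wm_ratio = 4)
  expect_identical(ph$data, again$data)

  expect_error(make_phantom(c(20, 44, 40)), "32")
  expect_error(make_phantom(gm_wm_ratio = 1), "exceed 1")
})

test_that("phantom structures scale with the grid's physical extent", {
  a <- make_phantom(c(40, 44, 40), c(2, 2, 2))
  b <- make_phantom(c(40, 44, 40), c(4, 4, 4))
  # same voxel-level construction at proportional extents
  expect_identical(a$data, b$data)
})

test_that("simulate_subject degenerates to the phantom when all effects vanish", {
  ph <- make_phantom(c(36, 40, 36), c(2, 2, 2))
  spec <- synthetic_cohort_spec(
    scanner = c(1e-4, 1e-4), n_subjects = 1, shape = c(36, 40, 36),
    spacing = c(2, 2, 2), subject_intensity_cv = 0,
    regional_variability_amplitude = 0, noise_sd_fraction = 0,
    misreg_sd = 0, seed = 3)
  out <- simulate_subject(ph, spec, 0)
  expect_lt(max(abs(out$data - ph$data)) / max(ph$data), 1e-3)
})

test_that("simulation is a pure function of (phantom, spec, subject index)", {
  ph <- make_phantom(c(36, 40, 36), c(2, 2, 2))
  spec <- synthetic_cohort_spec(scanner = c(5.5, 6), n_subjects = 4,
                                shape = c(36, 40, 36), spacing = c(2, 2, 2),
                                seed = 12)
  a <- simulate_subject(ph, spec, 2)
  b <- simulate_subject(ph, spec, 2)
  expect_identical(a$data, b$data)
  c2 <- simulate_subject(ph, spec, 3)
  expect_false(identical(a$data, c2$data))
  # calling inside a cohort gives the same subjects (order independence)
  cohort <- simulate_cohort(spec, phantom = ph)
  expect_identical(cohort[[3]]$data, a$data)
  expect_identical(length(cohort), 4L)
  # global RNG state is left untouched
  withr::with_seed(99, before <- rnorm(1))
  withr::with_seed(99, {
    invisible(simulate_subject(ph, spec, 1))
    after <- rnorm(1)
  })
  expect_identical(before, after)
})

test_that("different cohort seeds change the data but not the geometry", {
  base <- list(scanner = c(5.5, 6), n_subjects = 2, shape = c(36, 40, 36),
               spacing = c(2, 2, 2))
  s1 <- do.call(synthetic_cohort_spec, c(base, seed = 1))
  s2 <- do.call(synthetic_cohort_spec, c(base, seed = 2))
  c1 <- simulate_cohort(s1)
  c2 <- simulate_cohort(s2)
  expect_false(identical(c1[[1]]$data, c2[[1]]$data))
  expect_identical(dim(c1[[1]]$data), dim(c2[[1]]$data))
  expect_identical(c1[[1]]$spacing, c2[[1]]$spacing)
})

test_that("cohort-average deviation shrinks like 1/sqrt(n)", {
  shape <- c(32, 34, 32)
  ph <- make_phantom(shape, c(2, 2, 2))
  noiseless <- apply_gaussian(ph, c(5.5, 5.5))
  mk <- function(n) synthetic_cohort_spec(
    scanner = c(5.5, 5.5), n_subjects = n, shape = shape,
    spacing = c(2, 2, 2), subject_intensity_cv = 0,
    regional_variability_amplitude = 0, misreg_sd = 0,
    noise_sd_fraction = 0.05, seed = 21)
  dev_sd <- function(n) {
    avg <- average_cohort(simulate_cohort(mk(n), phantom = ph),
                          mode = "none")$mean_volume
    sd(avg$data - noiseless$data)
  }
  sd4 <- dev_sd(4)
  sd64 <- dev_sd(64)
  expect_lt(sd64, (sd4 / 4) * 1.5)
  expect_gt(sd64, (sd4 / 4) / 1.5)
})

test_that("clean-limit planted-filter recovery through the full stack", {
  shape <- c(40, 44, 40)
  clean <- function(scanner, seed) synthetic_cohort_spec(
    scanner = scanner, n_subjects = 32, shape = shape, spacing = c(2, 2, 2),
    subject_intensity_cv = 0, regional_variability_amplitude = 0,
    noise_sd_fraction = 0, misreg_sd = 0, seed = seed)
  ph <- make_phantom(shape, c(2, 2, 2))
  sharp <- scanner_profile("A", 4.5, 4.5)
  coarse <- scanner_profile("B", 6.0, 5.5)
  avg_a <- average_cohort(simulate_cohort(clean(c(4.5, 4.5), 1), ph))$mean_volume
  avg_b <- average_cohort(simulate_cohort(clean(c(6.0, 5.5), 2), ph))$mean_volume
  res <- estimate_filter(avg_b, avg_a, upper_bound = 8, grid_step = 0.5)
  expect_equal(res$theta$fwhm_xy, sqrt(6^2 - 4.5^2), tolerance = 0.3)
  expect_equal(res$theta$fwhm_z, sqrt(5.5^2 - 4.5^2), tolerance = 0.3)
})

test_that("averaging with registration jitter only degrades resolution", {
  shape <- c(36, 40, 36)
  ph <- make_phantom(shape, c(2, 2, 2))
  spec <- synthetic_cohort_spec(
    scanner = c(5.5, 6), n_subjects = 40, shape = shape, spacing = c(2, 2, 2),
    subject_intensity_cv = 0, regional_variability_amplitude = 0,
    noise_sd_fraction = 0, misreg_sd = 1.5, seed = 31)
  avg <- average_cohort(simulate_cohort(spec, ph), mode = "none")$mean_volume
  # estimate the blur of the jittered average against the raw phantom: it
  # must exceed the scanner's nominal width in XY
  res <- estimate_filter(avg, normalize_intensity(ph, "none"),
                         upper_bound = 10, grid_step = 0.5)
  expect_gt(res$theta$fwhm_xy, 5.5)
})

test_that("spec validation rejects nonsense parameters", {
  expect_error(synthetic_cohort_spec(scanner = c(5, 5), n_subjects = 0), ">= 1")
  expect_error(synthetic_cohort_spec(scanner = c(5, 5), n_subjects = 2,
                                     gm_wm_ratio = 1), "exceed 1")
  expect_error(synthetic_cohort_spec(scanner = c(5, 5), n_subjects = 2,
                                     misreg_sd = -1), ">= 0")
  expect_error(synthetic_cohort_spec(scanner = "x", n_subjects = 2), "scanner")
})
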