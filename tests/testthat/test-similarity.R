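test_that("SSIM of a volume with itself is exactly 1", {
  v <- make_smooth_volume(shape = c(16, 16, 16), seed = 2)
  expect_identical(compute_ssim(v, v), 1)
})

test_that("constant volumes reproduce the luminance-only closed form", {
  a <- volume_grid(array(3, dim = c(14, 14, 14)))
  b <- volume_grid(array(5, dim = c(14, 14, 14)))
  p <- ssim_params(dynamic_range = 10)
  C1 <- (0.01 * 10)^2
  expected <- (2 * 3 * 5 + C1) / (3^2 + 5^2 + C1)
  expect_equal(compute_ssim(a, b, p), expected, tolerance = 1e-8)
})

test_that("SSIM matches an independent brute-force oracle", {
  # full 3D-window reimplementation, no shared code with the package
  for (seed in 1:20) {
    withr::with_seed(seed, {
      r <- apply_gaussian(
        volume_grid(array(abs(rnorm(16^3)) + 0.2, dim = c(16, 16, 16))),
        c(4, 4))
      t <- apply_gaussian(
        volume_grid(array(abs(rnorm(16^3)) + 0.2, dim = c(16, 16, 16))),
        c(6, 2))
    })
    expect_equal(compute_ssim(r, t), ssim_oracle(r$data, t$data),
                 tolerance = 1e-10)
  }
})

test_that("SSIM is symmetric under an explicit dynamic range and bounded by 1", {
  a <- make_smooth_volume(shape = c(18, 18, 18), seed = 4)
  b <- make_smooth_volume(shape = c(18, 18, 18), seed = 9)
  p <- ssim_params(dynamic_range = max(a$data, b$data))
  expect_equal(compute_ssim(a, b, p), compute_ssim(b, a, p), tolerance = 1e-14)
  expect_lt(compute_ssim(a, b, p), 1)
  expect_lte(compute_ssim(a, b), 1)
})

test_that("SSIM rejects mismatched geometry and constant references", {
  a <- volume_grid(array(1, dim = c(14, 14, 14)))
  b <- volume_grid(array(1, dim = c(14, 14, 15)))
  expect_error(compute_ssim(a, b), "dimensions")
  c1 <- volume_grid(array(1, dim = c(14, 14, 14)), spacing = c(1, 2, 2))
  expect_error(compute_ssim(a, c1), "spacings")
  expect_error(compute_ssim(a, a), "dynamic range")
})

test_that("alternate metrics have their defining values", {
  v <- make_smooth_volume(shape = c(14, 14, 14), seed = 6)
  expect_identical(compute_alt_metric(v, v, "mse"), 0)
  expect_equal(compute_alt_metric(v, v, "ncc"), 1, tolerance = 1e-12)
  doubled <- volume_grid(2 * v$data, spacing = v$spacing)
  expect_equal(compute_alt_metric(v, doubled, "ncc"), 1, tolerance = 1e-12)
  expect_gt(compute_alt_metric(v, doubled, "mse"), 0)
  cst <- volume_grid(array(2, dim = dim(v$data)), spacing = v$spacing)
  expect_error(compute_alt_metric(v, cst, "ncc"), "constant")
  # PSNR consistency with MSE
  mse <- compute_alt_metric(v, doubled, "mse")
  L <- max(v$data) - min(v$data)
  expect_equal(compute_alt_metric(v, doubled, "psnr"), 10 * log10(L^2 / mse),
               tolerance = 1e-12)
})

test_that("mutual information matches a histogram-entropy oracle", {
  withr::with_seed(13, {
    x <- array(sample(0:9, 12^3, replace = TRUE), dim = c(12, 12, 12))
    y <- (x + array(sample(0:3, 12^3, replace = TRUE), dim = c(12, 12, 12))) %% 10
  })
  a <- volume_grid(x + 0)
  b <- volume_grid(y + 0)
  # oracle: MI = H(X) + H(Y) - H(X,Y) from 64-bin equal-width histograms
  bin64 <- function(v) pmin(floor((v - min(v)) / (max(v) - min(v)) * 64) + 1, 64)
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
  }
  bx <- bin64(as.numeric(x))
  by <- bin64(as.numeric(y))
  expected <- ent(table(bx)) + ent(table(by)) - ent(table(bx, by))
  expect_equal(compute_alt_metric(a, b, "mi"), expected, tolerance = 1e-10)
  # MI of an image with itself equals its own entropy
  expect_equal(compute_alt_metric(a, a, "mi"), ent(table(bx)), tolerance = 1e-10)
})

test_that("ssim_surface recovers a planted blur at its argmax", {
  v <- make_blob_volume(shape = c(33, 33, 33))
  ref <- apply_gaussian(v, c(4, 6))
  xy_grid <- seq(0, 8, by = 2)
  z_grid <- seq(0, 8, by = 2)
  surf <- ssim_surface(ref, v, xy_grid, z_grid)
  hit <- which(surf == max(surf), arr.ind = TRUE)
  expect_equal(xy_grid[hit[1, 1]], 4)
  expect_equal(z_grid[hit[1, 2]], 6)
})

test_that("a 1x1 surface equals a direct SSIM evaluation", {
  v <- make_blob_volume(shape = c(25, 25, 25))
  ref <- apply_gaussian(v, c(5, 5))
  surf <- ssim_surface(ref, v, 5, 5)
  expect_equal(surf[1, 1], compute_ssim(ref, apply_gaussian(v, c(5, 5))),
               tolerance = 1e-14)
})

test_that("the noiseless planted SSIM surface is unimodal", {
  v <- make_blob_volume(shape = c(33, 33, 33))
  ref <- apply_gaussian(v, c(5, 3))
  g <- seq(0, 8, by = 1)
  surf <- ssim_surface(ref, v, g, g)
  # no strict local maximum under 4-neighborhood other than the global one
  n_local_max <- 0L
  for (i in seq_along(g)) {
    for (j in seq_along(g)) {
      nb <- c(if (i > 1) surf[i - 1, j], if (i < nrow(surf)) surf[i + 1, j],
              if (j > 1) surf[i, j - 1], if (j < ncol(surf)) surf[i, j + 1])
      if (all(surf[i, j] > nb)) n_local_max <- n_local_max + 1L
    }
  }
  expect_identical(n_local_max, 1L)
})

test_that("surfaces export to long-format CSV", {
  v <- make_blob_volume(shape = c(25, 25, 25))
  surf <- ssim_surface(apply_gaussian(v, c(4, 4)), v, c(0, 4), c(0, 2, 4))
  path <- tempfile(fileext = ".csv")
  df <- write_ssim_surface(surf, path)
  got <- read.csv(path)
  expect_identical(nrow(got), 6L)
  expect_identical(names(got), c("fwhm_xy_mm", "fwhm_z_mm", "ssim"))
  expect_equal(got$ssim, as.numeric(surf), tolerance = 1e-12)
  unlink(path)
})
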