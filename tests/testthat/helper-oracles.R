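# Independent oracles and fixture builders shared across the test files.
# The SSIM oracle deliberately uses a literal 3D-window formulation (full
# 11^3 weight array, clamped indexing, no separability) so it shares no code
# path with the package's separable implementation.

# Literal windowed SSIM: mean over voxels of the local map.
ssim_oracle <- function(ref, test, window_sigma = 1.5, half_width = 5L,
                        k1 = 0.01, k2 = 0.03, dynamic_range = NULL) {
  d <- dim(ref)
  off <- seq.int(-half_width, half_width)
  w1 <- exp(-0.5 * (off / window_sigma)^2)
  w3 <- outer(outer(w1, w1), w1)          # full 3D weight block
  w3 <- w3 / sum(w3)
  wmean <- function(arr) {
    acc <- array(0, dim = d)
    for (a in seq_along(off)) {
      ia <- pmin(pmax(seq_len(d[1]) + off[a], 1L), d[1])
      for (b in seq_along(off)) {
        jb <- pmin(pmax(seq_len(d[2]) + off[b], 1L), d[2])
        for (cc in seq_along(off)) {
          kc <- pmin(pmax(seq_len(d[3]) + off[cc], 1L), d[3])
          acc <- acc + w3[a, b, cc] * arr[ia, jb, kc]
        }
      }
    }
    acc
  }
  L <- if (is.null(dynamic_range)) max(ref) - min(ref) else dynamic_range
  C1 <- (k1 * L)^2
  C2 <- (k2 * L)^2
  mu1 <- wmean(ref)
  mu2 <- wmean(test)
  s1 <- wmean(ref^2) - mu1^2
  s2 <- wmean(test^2) - mu2^2
  s12 <- wmean(ref * test) - mu1 * mu2
  mean(((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
         ((mu1^2 + mu2^2 + C1) * (s1 + s2 + C2)))
}

# FWHM of a 1D profile in mm, by linear interpolation of the half-maximum
# crossings on either side of the peak.
measure_fwhm <- function(profile, spacing) {
  pk <- which.max(profile)
  half <- profile[pk] / 2
  cross <- function(idx_seq) {
    prev <- pk
    for (i in idx_seq) {
      if (profile[i] < half) {
        frac <- (profile[prev] - half) / (profile[prev] - profile[i])
        return(abs(i - prev) * frac + abs(prev - pk))
      }
      prev <- i
    }
    stop("profile does not fall below half maximum")
  }
  left <- cross(seq.int(pk - 1L, 1L))
  right <- cross(seq.int(pk + 1L, length(profile)))
  (left + right) * spacing
}

# Smooth random volume: white noise smoothed well inside the grid, positive.
make_smooth_volume <- function(shape = c(24, 24, 24), spacing = c(2, 2, 2),
                               seed = 1, smooth_fwhm = 12) {
  withr::with_seed(seed, {
    v <- volume_grid(array(abs(rnorm(prod(shape))) + 0.5, dim = shape),
                     spacing = spacing)
    apply_gaussian(v, c(smooth_fwhm, smooth_fwhm))
  })
}

# A compactly supported blob whose support stays far from the boundary.
make_blob_volume <- function(shape = c(33, 33, 33), spacing = c(2, 2, 2)) {
  ctr <- (shape + 1) / 2
  ax <- lapply(1:3, function(i) (seq_len(shape[i]) - ctr[i]) * spacing[i])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  volume_grid(exp(-r2 / (2 * 6^2)), spacing = spacing)
}

tiny_spacing <- c(2, 2, 2)
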