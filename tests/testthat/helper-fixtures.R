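# Shared fixtures and independent oracles. Everything here is built in
# code at test time; no binary fixtures.

default_axis <- function() make_wavelength_axis(462, 648, 6)

tiny_axis <- function(bands = 5, start = 500, step = 10) {
  make_wavelength_axis(start, start + step * (bands - 1), step)
}

# Two overlapping Gaussian-like endmembers on a small axis.
toy_library <- function(axis = tiny_axis(), normalization = "raw") {
  lam <- axis$centers
  build_library(
    list(
      A = exp(-((lam - lam[2]) / 12)^2),
      B = exp(-((lam - lam[length(lam) - 1]) / 15)^2)
    ),
    axis, normalization = normalization
  )
}

uniform_cube <- function(spectrum, rows = 4, cols = 4, axis, bit_depth = 16) {
  data <- aperm(array(spectrum, c(length(spectrum), rows, cols)), c(2, 3, 1))
  spectral_cube(data, axis, bit_depth = bit_depth)
}

# Independent OLS oracle: coarse-to-fine grid search over abundance pairs,
# minimizing the residual sum of squares directly.
grid_search_ols2 <- function(s, x, lo = -10, hi = 10, stages = 4, n = 41) {
  best <- c(0, 0)
  width <- hi - lo
  center <- c((lo + hi) / 2, (lo + hi) / 2)
  for (st in seq_len(stages)) {
    g <- seq(-width / 2, width / 2, length.out = n)
    a1 <- center[1] + g
    a2 <- center[2] + g
    rss <- outer(a1, a2, Vectorize(function(p, q) sum((x - s[, 1] * p - s[, 2] * q)^2)))
    idx <- arrayInd(which.min(rss), dim(rss))
    best <- c(a1[idx[1]], a2[idx[2]])
    center <- best
    width <- width * 4 / (n - 1) # keep a margin of two grid cells
  }
  best
}

# Nonnegative variant of the same oracle.
grid_search_nnls2 <- function(s, x, hi = 10, stages = 4, n = 41) {
  center <- c(hi / 2, hi / 2)
  width <- hi
  best <- c(0, 0)
  for (st in seq_len(stages)) {
    g <- seq(-width / 2, width / 2, length.out = n)
    a1 <- pmax(center[1] + g, 0)
    a2 <- pmax(center[2] + g, 0)
    rss <- outer(a1, a2, Vectorize(function(p, q) sum((x - s[, 1] * p - s[, 2] * q)^2)))
    idx <- arrayInd(which.min(rss), dim(rss))
    best <- c(a1[idx[1]], a2[idx[2]])
    center <- best
    width <- width * 4 / (n - 1)
  }
  best
}

# Noise-free spike-in scenario: pure autofluorescence control whose level-0
# detection threshold comes from a bright AF patch co-located with the
# spike region, so numerical abundance residue outside stays below it.
noise_free_sensitivity_fixture <- function(shape = c(64, 64)) {
  axis <- default_axis()
  p <- preset("confocal")
  lib <- preset_library(p, axis)
  r <- square_roi(shape, side = 30)
  af <- matrix(50, shape[1], shape[2])
  af <- af + 10 * sin(seq_len(shape[1])) %o% cos(seq_len(shape[2]))
  af[r$mask] <- af[r$mask] * 10
  ab <- array(0, c(shape, 3), dimnames = list(NULL, NULL, lib$names))
  ab[, , "AF"] <- af
  list(control = reconstruct(ab, lib), library = lib, roi = r, axis = axis)
}
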