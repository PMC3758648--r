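test_that("exact library members unmix to their coefficients with zero residual", {
  ax <- tiny_axis()
  lib <- toy_library(ax)
  cube <- uniform_cube(3 * lib$spectra[, "A"], 2, 2, ax)
  res <- unmix(cube, lib)
  expect_equal(unname(res$abundances[1, 1, "A"]), 3)
  expect_equal(unname(res$abundances[1, 1, "B"]), 0, tolerance = 1e-12)
  expect_equal(max(res$rms_error), 0, tolerance = 1e-12)
  expect_equal(percent_rms_error(res), 0, tolerance = 1e-10)
})

test_that("orthonormal libraries project measurements directly", {
  ax <- tiny_axis(2)
  lib <- build_library(list(A = c(1, 0), B = c(0, 1)), ax)
  res <- unmix(uniform_cube(c(3, 5), 1, 1, ax), lib)
  expect_equal(as.vector(res$abundances[1, 1, ]), c(3, 5))
})

test_that("ols matches an independent grid-search oracle", {
  set.seed(41)
  ax <- tiny_axis()
  lib <- toy_library(ax)
  s <- lib$spectra
  for (i in 1:10) {
    x <- runif(5, 0, 8)
    res <- unmix(uniform_cube(x, 1, 1, ax), lib, "ols")
    oracle <- grid_search_ols2(s, x)
    expect_equal(as.vector(res$abundances[1, 1, ]), oracle, tolerance = 1e-3)
  }
})

test_that("nnls abundances are nonnegative and beat the clipped-ols residual", {
  set.seed(42)
  ax <- tiny_axis()
  lib <- toy_library(ax)
  s <- lib$spectra
  for (i in 1:10) {
    # spectra with a strong negative component pull ols below zero
    x <- pmax(2 * s[, 1] - runif(1, 1, 4) * s[, 2] + rnorm(5, 0, 0.2), 0)
    ols <- unmix(uniform_cube(x, 1, 1, ax), lib, "ols")
    nn <- unmix(uniform_cube(x, 1, 1, ax), lib, "nnls")
    a_nn <- as.vector(nn$abundances[1, 1, ])
    expect_true(all(a_nn >= 0))
    a_clip <- pmax(as.vector(ols$abundances[1, 1, ]), 0)
    rss_nn <- sum((x - s %*% a_nn)^2)
    rss_clip <- sum((x - s %*% a_clip)^2)
    expect_lte(rss_nn, rss_clip + 1e-10)
    # and matches a nonnegative grid-search oracle
    oracle <- grid_search_nnls2(s, x)
    expect_lte(rss_nn, sum((x - s %*% oracle)^2) + 1e-6)
  }
})

test_that("rank-deficient libraries are rejected with a pointer to diagnostics", {
  ax <- tiny_axis(3)
  lib <- build_library(list(A = c(1, 2, 1), B = c(2, 4, 2)), ax)
  cube <- uniform_cube(c(1, 1, 1), 1, 1, ax)
  expect_error(unmix(cube, lib), "condition_report")
})

test_that("per-pixel RMS error follows the band-averaged residual formula", {
  ax <- tiny_axis(4)
  lib <- build_library(list(A = c(1, 0, 0, 0), B = c(0, 1, 0, 0)), ax)
  x <- c(2, 3, 1, 2) # residual lives on bands 3-4
  res <- unmix(uniform_cube(x, 1, 1, ax), lib)
  expect_equal(res$rms_error[1, 1], sqrt((1^2 + 2^2) / 4))
  expect_equal(res$rms_signal[1, 1], sqrt(mean(x^2)))
})

test_that("the two percent-RMS conventions differ exactly as computed by hand", {
  ax <- tiny_axis(4)
  lib <- build_library(list(A = c(1, 0, 0, 0), B = c(0, 1, 0, 0)), ax)
  # two pixels whose residuals and signals are known in closed form
  d <- array(0, c(1, 2, 4))
  d[1, 1, ] <- c(1, 0, 1, 0) # rms_error sqrt(1/4), rms_signal sqrt(2/4)
  d[1, 2, ] <- c(5, 0, 3, 0) # rms_error sqrt(9/4), rms_signal sqrt(34/4)
  res <- unmix(spectral_cube(d, ax), lib)
  e <- c(sqrt(1 / 4), sqrt(9 / 4))
  s <- c(sqrt(2 / 4), sqrt(34 / 4))
  expect_equal(percent_rms_error(res, "image_averaged"),
               100 * mean(e) / mean(s))
  pw <- percent_rms_error(res, "pixelwise")
  expect_equal(as.vector(pw), 100 * e / s)
  expect_false(isTRUE(all.equal(100 * mean(e) / mean(s), mean(100 * e / s))))

  # homogeneous images: both conventions agree
  dh <- array(rep(c(1, 0, 1, 0), each = 4), c(2, 2, 4))
  resh <- unmix(spectral_cube(dh, ax), lib)
  expect_equal(percent_rms_error(resh, "image_averaged"),
               mean(percent_rms_error(resh, "pixelwise")))
})

test_that("pixelwise percent RMS excludes zero-signal pixels with a count", {
  ax <- tiny_axis(3)
  lib <- build_library(list(A = c(1, 1, 0)), ax)
  d <- array(0, c(1, 2, 3))
  d[1, 2, ] <- c(2, 2, 0)
  res <- unmix(spectral_cube(d, ax), lib)
  pw <- percent_rms_error(res, "pixelwise")
  expect_true(is.na(pw[1, 1]))
  expect_equal(attr(pw, "n_excluded"), 1)
})

test_that("reconstruct inverts render_scene and matches a loop oracle", {
  ax <- tiny_axis()
  lib <- toy_library(ax)
  zero <- array(0, c(2, 2, 2), dimnames = list(NULL, NULL, lib$names))
  expect_true(all(reconstruct(zero, lib)$data == 0))

  sc <- render_scene(scene_spec(c(6, 6), list(
    list(endmember = "A", shape = "disk", center = c(3, 3), radius = 2, level = 4),
    list(endmember = "B", shape = "background", level = 1)
  )), lib)
  expect_equal(reconstruct(sc$abundances, lib)$data, sc$cube$data)

  set.seed(44)
  ab <- array(runif(3 * 3 * 2), c(3, 3, 2), dimnames = list(NULL, NULL, lib$names))
  got <- reconstruct(ab, lib)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(
      as.vector(got$data[i, j, ]),
      ab[i, j, 1] * lib$spectra[, 1] + ab[i, j, 2] * lib$spectra[, 2]
    )
  }
})

test_that("noise-free scenes are recovered exactly by unmixing", {
  ax <- default_axis()
  p <- preset("widefield")
  lib <- preset_library(p, ax)
  sc <- render_scene(preset_scene(p, c(16, 16)), lib)
  res <- unmix(sc$cube, lib)
  expect_lt(max(abs(res$abundances - sc$abundances)), 1e-8)
})

test_that("abundance error shrinks as illumination grows", {
  ax <- default_axis()
  p <- preset("confocal")
  lib <- preset_library(p, ax)
  sc <- render_scene(preset_scene(p, c(24, 24)), lib)
  errs <- vapply(c(0.2, 1, 5), function(il) {
    det <- detector_model("pmt", illumination_scale = il, bit_depth = 16)
    cube <- acquire(sc$cube, det, 1, seed = 45)$cubes[[1]]
    res <- unmix(cube, lib)
    mean(abs(res$abundances / il - sc$abundances))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
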