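test_that("gaussian endmembers honour peak, FWHM, and pointwise formula", {
  ax <- make_wavelength_axis(462, 648, 6)
  m <- endmember_model("GFP", peak_nm = 510, width_nm = 40)
  s <- gaussian_endmember(m, ax)
  expect_equal(s[ax$centers == 510], 1.0)
  half <- make_wavelength_axis(490, 530, 20) # 490, 510, 530 = peak -/+ FWHM/2
  sh <- gaussian_endmember(m, half)
  expect_equal(sh, c(0.5, 1, 0.5))

  b <- endmember_model("X", peak_nm = 537, width_nm = 63, relative_brightness = 2.5)
  expect_equal(
    gaussian_endmember(b, ax),
    2.5 * exp(-4 * log(2) * (ax$centers - 537)^2 / 63^2)
  )
})

test_that("render_scene mixes abundances linearly", {
  ax <- tiny_axis()
  lib <- toy_library(ax)

  empty <- render_scene(scene_spec(c(4, 4), list()), lib)
  expect_true(all(empty$abundances == 0))
  expect_true(all(empty$cube$data == 0))

  bg <- render_scene(scene_spec(c(3, 3), list(
    list(endmember = "A", shape = "background", level = 7)
  )), lib)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(as.vector(bg$cube$data[i, j, ]), 7 * lib$spectra[, "A"])
  }

  two <- render_scene(scene_spec(c(9, 9), list(
    list(endmember = "A", shape = "disk", center = c(4, 4), radius = 3, level = 2),
    list(endmember = "B", shape = "disk", center = c(5, 5), radius = 3, level = 5)
  )), lib)
  # loop oracle at an overlap pixel and across the full frame
  for (px in list(c(4, 5), c(1, 1), c(5, 5))) {
    expected <- two$abundances[px[1], px[2], "A"] * lib$spectra[, "A"] +
      two$abundances[px[1], px[2], "B"] * lib$spectra[, "B"]
    expect_equal(as.vector(two$cube$data[px[1], px[2], ]), expected)
  }

  expect_error(render_scene(scene_spec(c(3, 3), list(
    list(endmember = "nope", shape = "background", level = 1)
  )), lib), "unknown endmember")
})

test_that("noise-free cube equals library matrix times abundances at every pixel", {
  ax <- default_axis()
  p <- preset("confocal")
  lib <- preset_library(p, ax)
  sc <- render_scene(preset_scene(p, c(16, 16)), lib)
  a <- matrix(sc$abundances, 16 * 16, 3)
  expect_equal(matrix(sc$cube$data, 16 * 16, 32), a %*% t(lib$spectra))
})

test_that("acquire is deterministic under a seed and respects degenerate settings", {
  ax <- tiny_axis(4)
  lib <- toy_library(ax)
  truth <- render_scene(scene_spec(c(6, 6), list(
    list(endmember = "A", shape = "background", level = 50)
  )), lib)

  dark <- detector_model("pmt", illumination_scale = 0)
  s0 <- acquire(truth$cube, dark, n_replicates = 3, seed = 1)
  expect_true(all(vapply(s0$cubes, function(x) all(x$data == 0), logical(1))))

  det <- detector_model("pmt", read_noise = 3, excess_noise_factor = 1.2,
                        offset = 10)
  s1 <- acquire(truth$cube, det, n_replicates = 4, seed = 42)
  s2 <- acquire(truth$cube, det, n_replicates = 4, seed = 42)
  expect_identical(lapply(s1$cubes, `[[`, "data"), lapply(s2$cubes, `[[`, "data"))
})

test_that("simulated intensities never leave the detector range", {
  ax <- tiny_axis(4)
  lib <- toy_library(ax)
  truth <- render_scene(scene_spec(c(8, 8), list(
    list(endmember = "A", shape = "background", level = 300)
  )), lib)
  det <- detector_model("emccd", gain = 5, read_noise = 50, offset = 200,
                        bit_depth = 8, excess_noise_factor = 2)
  s <- acquire(truth$cube, det, n_replicates = 3, seed = 5)
  for (cb in s$cubes) {
    expect_gte(min(cb$data), 0)
    expect_lte(max(cb$data), 255)
  }
})

test_that("shot-noise SNR grows as the square root of illumination", {
  ax <- tiny_axis(2)
  lib <- build_library(list(E = c(1, 1)), ax)
  truth <- render_scene(scene_spec(c(12, 12), list(
    list(endmember = "E", shape = "background", level = 100)
  )), lib)
  scales <- c(0.5, 2, 8)
  snrs <- vapply(seq_along(scales), function(i) {
    det <- detector_model("pmt", illumination_scale = scales[i], bit_depth = 16)
    composite_snr(snr_map(acquire(truth$cube, det, 100, seed = 100 + i)))
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))
  # closed form sqrt(mean): within sampling error at 100 replicates
  expect_equal(snrs, sqrt(100 * scales), tolerance = 0.1)
})

test_that("bleaching simulation applies mono-exponential decay before mixing", {
  ax <- tiny_axis()
  lib <- toy_library(ax)
  truth <- render_scene(scene_spec(c(5, 5), list(
    list(endmember = "A", shape = "background", level = 10),
    list(endmember = "B", shape = "background", level = 4)
  )), lib)

  still <- simulate_bleaching(truth$abundances, lib, c(A = 0, B = 0),
                              times_s = c(0, 10, 20), detector = NULL)
  for (cb in still$cubes) expect_equal(cb$data, truth$cube$data)

  k <- 0.05
  bl <- simulate_bleaching(truth$abundances, lib, c(A = k, B = 0),
                           times_s = c(0, 1 / k), detector = NULL)
  expected <- truth$abundances
  expected[, , "A"] <- expected[, , "A"] * exp(-1)
  expect_equal(bl$cubes[[2]]$data, reconstruct(expected, lib)$data)

  d <- detector_model("pmt")
  b1 <- simulate_bleaching(truth$abundances, lib, c(A = k), c(0, 5, 10), d, seed = 9)
  b2 <- simulate_bleaching(truth$abundances, lib, c(A = k), c(0, 5, 10), d, seed = 9)
  expect_identical(lapply(b1$cubes, `[[`, "data"), lapply(b2$cubes, `[[`, "data"))
})

test_that("presets differ in autofluorescence peak but share label peaks", {
  w <- preset("widefield")
  c_ <- preset("confocal")
  expect_equal(w$endmembers$af$peak_nm, 505)
  expect_equal(c_$endmembers$af$peak_nm, 545)
  expect_equal(w$endmembers$gfp$peak_nm, c_$endmembers$gfp$peak_nm)
  expect_equal(w$endmembers$hoechst$peak_nm, c_$endmembers$hoechst$peak_nm)
  expect_equal(w$detector$kind, "emccd")
  expect_equal(c_$detector$kind, "pmt")
  expect_error(preset("lightsheet"))
})
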