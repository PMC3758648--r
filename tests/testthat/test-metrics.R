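replicate_series_from_values <- function(values, rows = 1, cols = 1, bands = 1,
                                         axis = tiny_axis(bands, step = 6)) {
  cubes <- lapply(values, function(v) {
    spectral_cube(array(v, c(rows, cols, bands)), axis)
  })
  acquisition_series(cubes, "replicate")
}

test_that("snr_map computes replicate mean over sample standard deviation", {
  s <- replicate_series_from_values(c(8, 10, 12, 10, 10))
  m <- snr_map(s)
  expect_equal(m$mean[1, 1, 1], 10)
  expect_equal(m$sd[1, 1, 1], sqrt(2))
  expect_equal(m$snr[1, 1, 1], 7.0711, tolerance = 1e-4)
  expect_equal(m$n_replicates, 5)

  ident <- replicate_series_from_values(c(4, 4, 4))
  mi <- snr_map(ident)
  expect_true(all(mi$undefined_mask))
  expect_true(all(is.na(mi$snr)))
  expect_error(composite_snr(mi), "no defined")
})

test_that("composite SNR averages defined values, restricted by ROI", {
  ax <- tiny_axis(1, step = 6)
  make <- function(field) spectral_cube(array(field, c(2, 2, 1)), ax)
  # left column fluctuates around 10, right column around 100
  a <- matrix(c(9, 9, 99, 99), 2, 2)
  b <- matrix(c(11, 11, 101, 101), 2, 2)
  s <- acquisition_series(list(make(a), make(b)), "replicate")
  m <- snr_map(s)
  left <- roi(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(composite_snr(m, left), 10 / sd(c(9, 11)))
  expect_equal(composite_snr(m),
               mean(c(10, 10, 100, 100) / sd(c(9, 11))))

  # loop oracle over a random map
  set.seed(51)
  cubes <- lapply(1:4, function(i) {
    spectral_cube(array(sample(1:50, 3 * 3 * 2, TRUE), c(3, 3, 2)),
                  tiny_axis(2))
  })
  sr <- acquisition_series(cubes, "replicate")
  mr <- snr_map(sr)
  vals <- c()
  for (i in 1:3) for (j in 1:3) for (b in 1:2) {
    x <- vapply(cubes, function(cb) cb$data[i, j, b], numeric(1))
    if (sd(x) > 0) vals <- c(vals, mean(x) / sd(x))
  }
  expect_equal(composite_snr(mr), mean(vals))
})

test_that("SNR is invariant to a common positive rescaling of all replicates", {
  set.seed(52)
  cubes <- lapply(1:5, function(i) {
    spectral_cube(array(sample(10:90, 4 * 4 * 3, TRUE), c(4, 4, 3)),
                  tiny_axis(3))
  })
  s1 <- acquisition_series(cubes, "replicate")
  s2 <- acquisition_series(lapply(cubes, function(cb) {
    spectral_cube(cb$data * 2.5, cb$axis, meta = list(corrected = TRUE))
  }), "replicate")
  expect_equal(snr_map(s1)$snr, snr_map(s2)$snr, tolerance = 1e-12)
})

test_that("per-band SNR peaks near the emission peak of the imaged fluorophore", {
  ax <- default_axis()
  p <- preset("confocal")
  gfp <- gaussian_endmember(p$endmembers$gfp, ax)
  lib1 <- build_library(list(GFP = gfp), ax)
  truth <- render_scene(scene_spec(c(16, 16), list(
    list(endmember = "GFP", shape = "background", level = 500)
  )), lib1)
  det <- detector_model("pmt", bit_depth = 16)
  s <- acquire(truth$cube, det, n_replicates = 20, seed = 53)
  per_band <- snr_per_band(snr_map(s))
  peak_band <- which.max(gfp)
  expect_lte(abs(which.max(per_band) - peak_band), 1)

  # single-band map: per-band vector collapses to the composite
  s1 <- replicate_series_from_values(c(8, 10, 12))
  m1 <- snr_map(s1)
  expect_equal(unname(snr_per_band(m1)), composite_snr(m1))

  # a band with constant zero signal is undefined
  ax2 <- tiny_axis(2)
  cubes <- lapply(c(4, 6), function(v) {
    d <- array(0, c(2, 2, 2)); d[, , 1] <- v
    spectral_cube(d, ax2)
  })
  m2 <- snr_map(acquisition_series(cubes, "replicate"))
  expect_true(is.na(snr_per_band(m2)[2]))
})

test_that("unmixed-abundance SNR rises in an ROI holding the pure component", {
  ax <- default_axis()
  p <- preset("confocal")
  lib <- preset_library(p, ax)
  sc <- render_scene(preset_scene(p, c(32, 32)), lib)
  series <- acquire(sc$cube, p$detector, n_replicates = 5, seed = 54)
  gfp_mask <- sc$abundances[, , "GFP"] > 0
  r <- roi(gfp_mask)
  whole <- unmixed_snr(series, lib)
  in_roi <- unmixed_snr(series, lib, roi = r)
  expect_gt(in_roi["GFP"], whole["GFP"])

  # noise-free replicates have zero abundance variance: all undefined
  nf <- acquisition_series(list(sc$cube, sc$cube), "replicate")
  expect_true(all(is.na(unmixed_snr(nf, lib))))
})

test_that("brighter signals yield higher unmixed SNR under Poisson noise", {
  ax <- default_axis()
  p <- preset("confocal")
  lib <- preset_library(p, ax)
  sc <- render_scene(scene_spec(c(24, 24), list(
    list(endmember = "GFP", shape = "background", level = 100),
    list(endmember = "Hoechst", shape = "background", level = 1000)
  )), lib)
  det <- detector_model("pmt", bit_depth = 16)
  series <- acquire(sc$cube, det, n_replicates = 10, seed = 55)
  snr <- unmixed_snr(series, lib)
  expect_gt(snr["Hoechst"], snr["GFP"])
})

test_that("ROI coefficient of variation follows its closed form", {
  r <- roi(matrix(TRUE, 1, 1))
  expect_equal(roi_cv(replicate_series_from_values(c(9, 10, 11)), r), 0.1)
  expect_equal(roi_cv(replicate_series_from_values(c(7, 7, 7)), r), 0)

  # CV shrinks with photon budget
  ax <- tiny_axis(2)
  lib <- build_library(list(E = c(1, 1)), ax)
  truth <- render_scene(scene_spec(c(8, 8), list(
    list(endmember = "E", shape = "background", level = 50)
  )), lib)
  rr <- roi(matrix(TRUE, 8, 8))
  cvs <- vapply(c(0.5, 20), function(il) {
    det <- detector_model("pmt", illumination_scale = il, bit_depth = 16)
    roi_cv(acquire(truth$cube, det, 10, seed = 56), rr)
  }, numeric(1))
  expect_gt(cvs[1], cvs[2])
})

test_that("band-integrated irradiance matches closed forms", {
  flat <- data.frame(wavelength_nm = seq(300, 700, 10), irradiance = 0)
  expect_equal(integrate_irradiance(flat, 430, 40), 0)

  const <- data.frame(wavelength_nm = seq(300, 700, 10), irradiance = 2.5)
  expect_equal(integrate_irradiance(const, 430, 40), 2.5 * 80)

  # triangular spectrum peaking at 500 with half-base 100: area b*h/2
  wl <- seq(300, 700, 1)
  tri <- data.frame(wl, pmax(0, 1 - abs(wl - 500) / 100))
  expect_equal(integrate_irradiance(tri, 500, 100), 100, tolerance = 1e-9)
  # partial window: trapezoid over [450, 550]
  expect_equal(integrate_irradiance(tri, 500, 50), (1 + 0.5) / 2 * 100,
               tolerance = 1e-9)

  expect_error(integrate_irradiance(const, 320, 40), "outside")
})
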