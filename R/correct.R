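# Background subtraction and flat spectral correction.
#
# The wavelength-dependent attenuation of a tunable-filter/camera system is
# measured with dark and bright calibration acquisitions and a traceable
# lamp spectrum. The transfer function TF(lambda) = (bright - dark)/lamp is
# inverted to a correction coefficient CC = 1/TF; corrected data are
# (raw - dark) * CC per pixel per band, clamped at zero.

#' Assemble a calibration set
#'
#' Dark and bright inputs may be per-band spectra or whole calibration
#' cubes; cubes are reduced to spectra by spatial averaging over the full
#' frame (the natural estimator for a spatially uniform response; see
#' [spectrum_from_cube()] for ROI-restricted reductions).
#'
#' @param dark Dark spectrum (vector) or dark `spectral_cube`.
#' @param bright Bright (lamp-illuminated) spectrum or `spectral_cube`.
#' @param lamp Lamp irradiance spectrum on the same axis, strictly positive.
#' @param axis `wavelength_axis` all three live on.
#' @return A `calibration_set`. Bands where bright < dark (non-physical
#'   transfer) are flagged with a warning and recorded in `$suspect_bands`.
#' @export
calibration_set <- function(dark, bright, lamp, axis) {
  stopifnot(inherits(axis, "wavelength_axis"))
  as_spec <- function(x, what) {
    if (inherits(x, "spectral_cube")) {
      stop_if_axis_mismatch(x$axis, axis, what)
      return(spectrum_from_cube(x))
    }
    if (length(x) != n_bands(axis)) {
      stop(what, " spectrum length ", length(x), " does not match the ",
           n_bands(axis), "-band axis")
    }
    as.numeric(x)
  }
  dark <- as_spec(dark, "dark")
  bright <- as_spec(bright, "bright")
  lamp <- as_spec(lamp, "lamp")
  if (any(lamp <= 0)) {
    stop("lamp spectrum must be strictly positive at every band")
  }
  suspect <- which(bright < dark)
  if (length(suspect)) {
    warning("bright < dark at band(s) ",
            paste(axis$centers[suspect], collapse = ", "),
            " nm; transfer function is non-physical there")
  }
  structure(
    list(dark_spectrum = dark, bright_spectrum = bright,
         lamp_spectrum = lamp, axis = axis, suspect_bands = suspect),
    class = "calibration_set"
  )
}

#' Pixel-averaged spectrum of a cube
#'
#' @param cube A `spectral_cube`.
#' @param roi Optional `roi`; if given, only pixels inside it are averaged.
#' @return Per-band mean spectrum (numeric vector).
#' @export
spectrum_from_cube <- function(cube, roi = NULL) {
  m <- cube_matrix(cube)
  if (is.null(roi)) {
    colMeans(m)
  } else {
    roi <- roi_for_cube(roi, cube)
    colMeans(m[as.vector(roi$mask), , drop = FALSE])
  }
}

#' Spectral transfer function and correction coefficient
#'
#' `TF(lambda) = (bright(lambda) - dark(lambda)) / lamp(lambda)`; the
#' correction coefficient is its reciprocal. Bands where the transfer
#' function is not strictly positive abort the computation (correcting
#' through a dead band would fabricate response rather than measure it).
#'
#' @param cal A `calibration_set`.
#' @return A `correction_coefficient` with fields `tf`, `cc` and `axis`.
#' @export
transfer_function <- function(cal) {
  stopifnot(inherits(cal, "calibration_set"))
  tf <- (cal$bright_spectrum - cal$dark_spectrum) / cal$lamp_spectrum
  bad <- which(tf <= 0)
  if (length(bad)) {
    stop("transfer function is not positive at band(s) ",
         paste(cal$axis$centers[bad], collapse = ", "),
         " nm; correction is undefined there")
  }
  structure(list(tf = tf, cc = 1 / tf, axis = cal$axis),
            class = "correction_coefficient")
}

#' Apply dark subtraction and flat spectral correction
#'
#' Per pixel and band: `corrected = max(0, raw - dark) * CC`. Negative
#' post-subtraction residuals are noise and are clamped at zero; the clamp
#' count is recorded in the output's provenance. Corrected intensities may
#' exceed the raw bit-depth ceiling.
#'
#' @param raw Raw `spectral_cube`.
#' @param cal `calibration_set` providing the dark spectrum.
#' @param coeff `correction_coefficient` from [transfer_function()].
#' @return Corrected `spectral_cube` with `meta$corrected = TRUE`,
#'   `meta$n_clamped`, and the calibration recorded in `meta$calibration`.
#' @export
apply_correction <- function(raw, cal, coeff) {
  stopifnot(inherits(raw, "spectral_cube"), inherits(cal, "calibration_set"),
            inherits(coeff, "correction_coefficient"))
  stop_if_axis_mismatch(raw$axis, cal$axis, "raw cube and calibration")
  stop_if_axis_mismatch(raw$axis, coeff$axis, "raw cube and coefficient")
  m <- cube_matrix(raw)
  m <- sweep(m, 2, cal$dark_spectrum, `-`)
  m <- clamp0(m)
  n_clamped <- attr(m, "n_clamped")
  m <- sweep(m, 2, coeff$cc, `*`)
  meta <- raw$meta
  meta$corrected <- TRUE
  meta$n_clamped <- n_clamped
  meta$calibration <- list(dark = cal$dark_spectrum, cc = coeff$cc)
  matrix_to_cube(m, raw, meta = meta)
}

#' Subtract a background spectrum from a cube
#'
#' The background may be supplied directly as a per-band spectrum or as a
#' blank `roi` within the cube, in which case the background spectrum is
#' the pixel-averaged spectrum over that region. The result is clamped at
#' zero bandwise. This is the whole correction applied to systems with a
#' traceable detector (no flat spectral correction needed).
#'
#' @param cube A `spectral_cube`.
#' @param background Per-band numeric spectrum, or an `roi` marking a blank
#'   region of the cube.
#' @return Background-subtracted `spectral_cube` (`meta$corrected = TRUE`,
#'   clamp count in `meta$n_clamped`).
#' @export
background_subtract <- function(cube, background) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (inherits(background, "roi")) {
    background <- spectrum_from_cube(cube, background)
  }
  if (length(background) != n_bands(cube$axis)) {
    stop("background spectrum length does not match the cube axis")
  }
  m <- sweep(cube_matrix(cube), 2, as.numeric(background), `-`)
  m <- clamp0(m)
  meta <- cube$meta
  meta$corrected <- TRUE
  meta$n_clamped <- attr(m, "n_clamped")
  meta$background <- as.numeric(background)
  matrix_to_cube(m, cube, meta = meta)
}
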