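#' Create a spectral image cube
#'
#' The atomic image object: a rows x cols x bands array of nonnegative
#' intensities with a wavelength axis and detector bit depth. Band index 1
#' is the shortest wavelength; pixel (1,1) is the top-left corner.
#'
#' Raw (uncorrected) cubes must respect the detector ceiling
#' `2^bit_depth - 1`. Corrected cubes (flagged via `meta$corrected`) may
#' exceed it -- flat spectral correction rescales intensities -- but remain
#' nonnegative.
#'
#' @param data Numeric array, rows x cols x bands. A matrix is treated as a
#'   single-band cube.
#' @param axis `wavelength_axis` whose band count matches `dim(data)[3]`.
#' @param bit_depth Detector bit depth in bits (8-16).
#' @param meta Free-form provenance list. Set `meta$corrected = TRUE` for
#'   cubes that have been through correction and are no longer bounded by
#'   the raw ceiling.
#' @return A `spectral_cube`.
#' @export
spectral_cube <- function(data, axis, bit_depth = 16, meta = list()) {
  stopifnot(inherits(axis, "wavelength_axis"), is.list(meta))
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!(is.array(data) && length(dim(data)) == 3L)) {
    stop("data must be a rows x cols x bands array")
  }
  if (dim(data)[3] != n_bands(axis)) {
    stop(
      "cube has ", dim(data)[3], " band planes but the axis has ",
      n_bands(axis), " bands"
    )
  }
  if (!(bit_depth %in% 8:16)) stop("bit_depth must be an integer in 8..16")
  if (anyNA(data)) stop("cube intensities must not be NA")
  if (min(data) < 0) stop("cube intensities must be nonnegative")
  ceiling_ok <- isTRUE(meta$corrected) || max(data) <= 2^bit_depth - 1
  if (!ceiling_ok) {
    stop(
      "raw cube exceeds the ", bit_depth, "-bit ceiling ",
      2^bit_depth - 1, " (max ", max(data), "); set meta$corrected = TRUE ",
      "for corrected data"
    )
  }
  structure(
    list(data = data, axis = axis, bit_depth = bit_depth, meta = meta),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(
    "spectral_cube: ", d[1], " x ", d[2], " pixels, ", d[3], " bands (",
    x$axis$start_nm, "-", x$axis$stop_nm, " nm), ", x$bit_depth, "-bit\n",
    sep = ""
  )
  invisible(x)
}

cube_dim <- function(cube) dim(cube$data)

#' Flatten a cube to a pixels x bands matrix
#'
#' Row-major pixel order is irrelevant to the statistics computed here; the
#' same reshaping is used everywhere so pixel indices stay consistent.
#' @param cube A `spectral_cube`.
#' @return Matrix with one row per pixel and one column per band.
#' @keywords internal
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
}

# Model reconstructions (unmixing fits) may dip below zero where fitted
# abundances are negative; they are built directly rather than through the
# acquisition-cube constructor, which enforces nonnegative intensities.
model_cube <- function(data, axis, bit_depth = 16, meta = list()) {
  meta$corrected <- TRUE
  structure(
    list(data = data, axis = axis, bit_depth = bit_depth, meta = meta),
    class = "spectral_cube"
  )
}

matrix_to_cube <- function(m, template, meta = template$meta) {
  d <- dim(template$data)
  spectral_cube(
    array(m, dim = d), template$axis,
    bit_depth = template$bit_depth, meta = meta
  )
}

#' Total fluorescence emission image
#'
#' Per-pixel sum of all wavelength bands; the image used for intensity
#' thresholding when defining regions of interest.
#'
#' @param cube A `spectral_cube`.
#' @return A rows x cols numeric matrix.
#' @export
total_emission_image <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  rowSums(cube$data, dims = 2L)
}

#' Create a region of interest
#'
#' @param mask Logical rows x cols matrix with at least one `TRUE` pixel.
#' @param label Optional text label.
#' @return An object of class `roi`.
#' @export
roi <- function(mask, label = "") {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (anyNA(mask)) stop("roi mask must not contain NA")
  if (!any(mask)) stop("roi must contain at least one pixel")
  structure(list(mask = mask, label = label), class = "roi")
}

#' Square region of interest
#'
#' Convenience constructor for the square spike-in regions used by the
#' sensitivity study (default side 30, i.e. 900 pixels).
#'
#' @param dim Image dimensions, `c(rows, cols)`.
#' @param side Side length in pixels.
#' @param at Top-left corner `c(row, col)`; defaults to centering the square.
#' @param label Optional text label.
#' @return An `roi`.
#' @export
square_roi <- function(dim, side = 30, at = NULL, label = "") {
  stopifnot(length(dim) == 2, side >= 1, side <= min(dim))
  if (is.null(at)) at <- floor((dim - side) / 2) + 1
  mask <- matrix(FALSE, dim[1], dim[2])
  mask[at[1]:(at[1] + side - 1), at[2]:(at[2] + side - 1)] <- TRUE
  roi(mask, label)
}

roi_for_cube <- function(r, cube) {
  d <- dim(cube$data)
  if (!all(dim(r$mask) == d[1:2])) {
    stop("roi geometry ", paste(dim(r$mask), collapse = "x"),
         " does not match cube ", paste(d[1:2], collapse = "x"))
  }
  r
}

#' Create an acquisition series
#'
#' An ordered set of cubes of identical geometry: either sequential
#' replicates of a static scene (for noise statistics) or a photobleaching
#' time series with acquisition times.
#'
#' @param cubes List of `spectral_cube`s sharing geometry and axis.
#' @param kind `"replicate"` or `"timeseries"`.
#' @param times_s Acquisition times in seconds, strictly increasing;
#'   required iff `kind == "timeseries"`.
#' @param check If `TRUE` (default), reject invalid series. Use
#'   `check = FALSE` to build a series purely for [validate_series()].
#' @return An `acquisition_series`.
#' @export
acquisition_series <- function(cubes, kind = c("replicate", "timeseries"),
                               times_s = NULL, check = TRUE) {
  kind <- match.arg(kind)
  s <- structure(
    list(cubes = cubes, kind = kind, times_s = times_s),
    class = "acquisition_series"
  )
  if (check) {
    problems <- validate_series(s)
    if (length(problems)) {
      stop("invalid acquisition series:\n  ", paste(problems, collapse = "\n  "))
    }
  }
  s
}

#' Validate an acquisition series
#'
#' Validation never raises: it returns a character vector listing every
#' violated invariant, empty when the series is valid.
#'
#' @param series An `acquisition_series` (possibly built with
#'   `check = FALSE`).
#' @return Character vector of violation messages (zero length if valid).
#' @export
validate_series <- function(series) {
  problems <- character()
  cubes <- series$cubes
  if (!length(cubes)) {
    return("series contains no cubes")
  }
  if (!all(vapply(cubes, inherits, logical(1), "spectral_cube"))) {
    return("all series members must be spectral_cube objects")
  }
  d1 <- dim(cubes[[1]]$data)
  same_geom <- vapply(cubes, function(x) all(dim(x$data) == d1), logical(1))
  if (!all(same_geom)) problems <- c(problems, "cubes do not share identical geometry")
  same_axis <- vapply(
    cubes, function(x) axes_identical(x$axis, cubes[[1]]$axis), logical(1)
  )
  if (!all(same_axis)) problems <- c(problems, "cubes do not share a wavelength axis")
  if (series$kind == "replicate") {
    if (length(cubes) < 2) {
      problems <- c(problems, "replicate series needs >=2 cubes (SNR needs a standard deviation)")
    }
    if (!is.null(series$times_s)) {
      problems <- c(problems, "replicate series must not carry times_s")
    }
  } else {
    if (is.null(series$times_s)) {
      problems <- c(problems, "timeseries requires times_s")
    } else {
      if (length(series$times_s) != length(cubes)) {
        problems <- c(problems, "times_s length does not match cube count")
      }
      if (length(series$times_s) > 1 && any(diff(series$times_s) <= 0)) {
        problems <- c(problems, "times not strictly increasing")
      }
    }
  }
  problems
}

#' @export
print.acquisition_series <- function(x, ...) {
  cat(
    "acquisition_series: ", length(x$cubes), " cubes (", x$kind, ")\n",
    sep = ""
  )
  invisible(x)
}

series_array <- function(series) {
  # rows x cols x bands x n array (explicit dims: simplify2array drops
  # singleton dimensions)
  d <- dim(series$cubes[[1]]$data)
  array(unlist(lapply(series$cubes, function(x) x$data)),
        dim = c(d, length(series$cubes)))
}
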