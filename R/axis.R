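#' Construct a wavelength axis of evenly spaced band centers
#'
#' A wavelength axis describes the spectral sampling of a hyperspectral
#' acquisition as a set of band-center wavelengths: an inclusive range from
#' `start_nm` to `stop_nm` sampled every `step_nm` nanometres. Band centers
#' (not band edges) define the axis; any filter bandwidth is metadata.
#' The canonical emission axis used throughout the examples is 462-648 nm in
#' 6 nm increments, which yields 32 bands.
#'
#' @param start_nm First band center, in nm.
#' @param stop_nm Last band center, in nm. The span `stop_nm - start_nm`
#'   must be an exact nonnegative multiple of `step_nm`.
#' @param step_nm Band spacing, in nm. Must be positive.
#' @return An object of class `wavelength_axis` with fields `start_nm`,
#'   `stop_nm`, `step_nm` and `centers` (strictly increasing, evenly spaced).
#' @examples
#' ax <- make_wavelength_axis(462, 648, 6)
#' n_bands(ax) # 32
#' @export
make_wavelength_axis <- function(start_nm, stop_nm, step_nm) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (step_nm <= 0) {
    stop("step_nm must be positive (got ", step_nm, ")")
  }
  span <- stop_nm - start_nm
  if (span < 0) {
    stop("stop_nm (", stop_nm, ") must not be below start_nm (", start_nm, ")")
  }
  k <- span / step_nm
  if (abs(k - round(k)) > 1e-9) {
    stop(
      "band count is not integral: (", stop_nm, " - ", start_nm, ")/",
      step_nm, " = ", format(k), " is not a whole number"
    )
  }
  centers <- start_nm + step_nm * seq(0, round(k))
  structure(
    list(
      start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
      centers = centers
    ),
    class = "wavelength_axis"
  )
}

#' Number of spectral bands on a wavelength axis
#'
#' @param axis A `wavelength_axis`.
#' @return Integer band count.
#' @export
n_bands <- function(axis) {
  stopifnot(inherits(axis, "wavelength_axis"))
  length(axis$centers)
}

#' @export
print.wavelength_axis <- function(x, ...) {
  cat(
    "wavelength_axis: ", x$start_nm, "-", x$stop_nm, " nm, step ",
    x$step_nm, " nm (", length(x$centers), " bands)\n",
    sep = ""
  )
  invisible(x)
}

axes_identical <- function(a, b) {
  isTRUE(all.equal(a$centers, b$centers, tolerance = 1e-9))
}

stop_if_axis_mismatch <- function(a, b, what = "inputs") {
  if (!axes_identical(a, b)) {
    stop("wavelength axes of ", what, " do not match")
  }
  invisible(TRUE)
}
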