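# Replicate-based noise characterization: per-pixel-per-band SNR, composite
# and per-band summaries, unmixed-abundance SNR, ROI coefficient of
# variation, and band-integrated excitation irradiance.

#' Per-pixel, per-band signal-to-noise ratio from replicate acquisitions
#'
#' For each pixel and wavelength band, the SNR is the mean over replicates
#' divided by the sample standard deviation (denominator n - 1) across
#' replicates. Pixels/bands with zero standard deviation are undefined and
#' recorded in `undefined_mask` rather than mapped to infinite SNR.
#'
#' @param series Replicate `acquisition_series` (>= 2 cubes).
#' @return An `snr_map`: `snr`, `mean`, `sd` (rows x cols x bands arrays),
#'   `n_replicates`, `undefined_mask`.
#' @export
snr_map <- function(series) {
  stopifnot(inherits(series, "acquisition_series"))
  if (series$kind != "replicate" || length(series$cubes) < 2) {
    stop("snr_map needs a replicate series with >= 2 cubes")
  }
  arr <- series_array(series) # r x c x b x n
  n <- dim(arr)[4]
  mu <- rowMeans(arr, dims = 3)
  ss <- rowSums(arr^2, dims = 3)
  v <- (ss - n * mu^2) / (n - 1)
  v[v < 0] <- 0 # guard tiny negative round-off
  sd <- sqrt(v)
  undef <- sd == 0
  snr <- mu / sd
  snr[undef] <- NA_real_
  structure(
    list(snr = snr, mean = mu, sd = sd, n_replicates = n,
         undefined_mask = undef, axis = series$cubes[[1]]$axis),
    class = "snr_map"
  )
}

snr_roi_index <- function(map, roi) {
  d <- dim(map$snr)
  if (is.null(roi)) {
    array(TRUE, d)
  } else {
    stopifnot(inherits(roi, "roi"))
    if (!all(dim(roi$mask) == d[1:2])) {
      stop("roi geometry does not match the SNR map")
    }
    array(rep(roi$mask, d[3]), d)
  }
}

#' Composite SNR of a spectral image
#'
#' The mean of all defined per-pixel-per-band SNR values, averaged over the
#' field of view (or an ROI) and over all wavelengths.
#'
#' @param map An `snr_map`.
#' @param roi Optional `roi` restricting the spatial average.
#' @return Scalar composite SNR.
#' @export
composite_snr <- function(map, roi = NULL) {
  stopifnot(inherits(map, "snr_map"))
  sel <- snr_roi_index(map, roi) & !map$undefined_mask
  if (!any(sel)) stop("no defined SNR values in the requested region")
  mean(map$snr[sel])
}

#' Wavelength-resolved SNR
#'
#' Per-band mean of defined SNR values over the field of view (or an ROI).
#' Bands with no defined pixels return `NA`.
#'
#' @param map An `snr_map`.
#' @param roi Optional `roi`.
#' @return Named numeric vector, one value per band (names are band-center
#'   wavelengths in nm).
#' @export
snr_per_band <- function(map, roi = NULL) {
  stopifnot(inherits(map, "snr_map"))
  sel <- snr_roi_index(map, roi) & !map$undefined_mask
  d <- dim(map$snr)
  out <- vapply(seq_len(d[3]), function(b) {
    s <- sel[, , b]
    if (!any(s)) return(NA_real_)
    mean(map$snr[, , b][s])
  }, numeric(1))
  names(out) <- map$axis$centers
  out
}

#' Per-endmember SNR of unmixed abundance images
#'
#' Unmixes each replicate independently, then treats the per-replicate
#' abundance images as repeated measurements: per endmember and pixel the
#' SNR is mean/sample-sd of abundance across replicates, averaged over the
#' defined pixels of the field of view (or an ROI).
#'
#' @param series Replicate `acquisition_series`.
#' @param library A `spectral_library`.
#' @param solver Unmixing solver, `"ols"` or `"nnls"`.
#' @param roi Optional `roi`.
#' @return Named per-endmember SNR vector.
#' @export
unmixed_snr <- function(series, library, solver = "ols", roi = NULL) {
  stopifnot(inherits(series, "acquisition_series"))
  if (series$kind != "replicate" || length(series$cubes) < 2) {
    stop("unmixed_snr needs a replicate series with >= 2 cubes")
  }
  abs_ <- lapply(series$cubes, function(cb) unmix(cb, library, solver)$abundances)
  d3 <- dim(abs_[[1]])
  arr <- array(unlist(abs_), dim = c(d3, length(abs_))) # r x c x k x n
  n <- dim(arr)[4]
  mu <- rowMeans(arr, dims = 3)
  v <- (rowSums(arr^2, dims = 3) - n * mu^2) / (n - 1)
  v[v < 0] <- 0
  sd <- sqrt(v)
  sel_spatial <- if (is.null(roi)) {
    matrix(TRUE, dim(arr)[1], dim(arr)[2])
  } else {
    stopifnot(inherits(roi, "roi"))
    roi$mask
  }
  out <- vapply(seq_along(library$names), function(k) {
    s <- sel_spatial & sd[, , k] > 0
    if (!any(s)) return(NA_real_)
    mean((mu[, , k] / sd[, , k])[s])
  }, numeric(1))
  names(out) <- library$names
  out
}

#' Coefficient of variation of ROI-mean intensity across replicates
#'
#' For each replicate the total fluorescence emission is averaged over the
#' ROI; the CV is the sample standard deviation of those scalars divided by
#' their mean.
#'
#' @param series Replicate `acquisition_series`.
#' @param roi An `roi`.
#' @return Scalar CV.
#' @export
roi_cv <- function(series, roi) {
  stopifnot(inherits(series, "acquisition_series"), inherits(roi, "roi"))
  if (series$kind != "replicate" || length(series$cubes) < 2) {
    stop("roi_cv needs a replicate series with >= 2 cubes")
  }
  means <- vapply(series$cubes, function(cb) {
    mean(total_emission_image(roi_cube_check(cb, roi))[roi$mask])
  }, numeric(1))
  m <- mean(means)
  if (m == 0) stop("ROI mean intensity is zero; CV undefined")
  stats::sd(means) / m
}

roi_cube_check <- function(cube, roi) {
  roi_for_cube(roi, cube)
  cube
}

#' Band-integrated excitation irradiance
#'
#' Trapezoidal integral of a measured irradiance spectrum over a window
#' `center_nm +/- halfwidth_nm` (e.g. an excitation filter band widened by
#' 40 nm to each side, or a 10 nm window around a laser line). The window
#' must lie inside the tabulated support; endpoint values are linearly
#' interpolated.
#'
#' @param spectrum Two-column data frame or matrix: wavelength (nm) and
#'   irradiance.
#' @param center_nm Window center (nm).
#' @param halfwidth_nm Window half width (nm), > 0.
#' @return Integrated irradiance (irradiance units times nm).
#' @export
integrate_irradiance <- function(spectrum, center_nm, halfwidth_nm) {
  spectrum <- as.data.frame(spectrum)
  stopifnot(ncol(spectrum) >= 2, halfwidth_nm > 0)
  wl <- spectrum[[1]]
  ir <- spectrum[[2]]
  o <- order(wl)
  wl <- wl[o]; ir <- ir[o]
  lo <- center_nm - halfwidth_nm
  hi <- center_nm + halfwidth_nm
  if (lo < min(wl) || hi > max(wl)) {
    stop("integration window [", lo, ", ", hi,
         "] nm lies outside the tabulated spectrum support [",
         min(wl), ", ", max(wl), "] nm")
  }
  knots <- sort(unique(c(lo, hi, wl[wl > lo & wl < hi])))
  vals <- stats::approx(wl, ir, xout = knots)$y
  pracma::trapz(knots, vals)
}
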