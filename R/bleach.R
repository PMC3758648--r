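# Photobleaching time-series analysis: normalized per-endmember decay
# curves, mono-exponential rate estimation, and unmixing error over time.

#' Normalized per-endmember bleaching curves
#'
#' Unmixes every time point and averages each endmember's abundance over
#' the entire field of view, then normalizes each curve to its value at the
#' first time point. Endmembers whose initial field-of-view abundance is
#' not positive cannot be normalized and are flagged (`NA` curve).
#'
#' @param series `acquisition_series` of kind `"timeseries"` with >= 3
#'   time points.
#' @param library A `spectral_library`.
#' @param solver Unmixing solver.
#' @param every_s Optional analysis cadence in seconds: only time points at
#'   (approximate) multiples of `every_s` from the first are analyzed.
#' @return Data frame with columns `time_s`, `endmember`, `abundance`
#'   (field-of-view mean), `normalized`.
#' @export
bleaching_curves <- function(series, library, solver = "ols", every_s = NULL) {
  stopifnot(inherits(series, "acquisition_series"))
  if (series$kind != "timeseries") stop("bleaching_curves needs a timeseries")
  times <- series$times_s
  keep <- seq_along(times)
  if (!is.null(every_s)) {
    rel <- times - times[1]
    keep <- which(abs(rel - round(rel / every_s) * every_s) < 1e-6)
  }
  if (length(keep) < 3) stop("need >= 3 analyzed time points")
  means <- t(vapply(keep, function(i) {
    ab <- unmix(series$cubes[[i]], library, solver)$abundances
    apply(ab, 3, mean)
  }, numeric(length(library$names))))
  colnames(means) <- library$names
  init <- means[1, ]
  flagged <- init <= 0
  if (any(flagged)) {
    warning("initial abundance <= 0 for: ",
            paste(library$names[flagged], collapse = ", "),
            "; curve(s) not normalized")
  }
  norm <- sweep(means, 2, ifelse(flagged, NA_real_, init), `/`)
  data.frame(
    time_s = rep(times[keep], times = length(library$names)),
    endmember = rep(library$names, each = length(keep)),
    abundance = as.vector(means),
    normalized = as.vector(norm)
  )
}

#' Fit a mono-exponential photobleaching rate
#'
#' Fits `I(t) = exp(-k t)` to a normalized decay curve by weighted
#' log-linear least squares (`log I ~ t`, weights proportional to the
#' intensity, which restores ordinary least-squares behaviour on the
#' original scale for small residuals). Non-positive intensities cannot be
#' log-transformed and are excluded; the exclusion count is reported.
#'
#' @param time_s Time points (s).
#' @param intensity Normalized intensities at those times.
#' @return List with `rate` (1/s), `intercept` (log scale), `n_used`,
#'   `n_excluded`, `residual_sd` (log scale).
#' @export
fit_decay_rate <- function(time_s, intensity) {
  stopifnot(length(time_s) == length(intensity))
  ok <- is.finite(intensity) & intensity > 0 & is.finite(time_s)
  n_excluded <- sum(!ok)
  t <- time_s[ok]
  y <- intensity[ok]
  if (length(t) < 3) stop("need >= 3 positive intensity points to fit a rate")
  fit <- stats::lm(log(y) ~ t, weights = y)
  k <- -unname(stats::coef(fit)[2])
  list(
    rate = k,
    intercept = unname(stats::coef(fit)[1]),
    n_used = length(t),
    n_excluded = n_excluded,
    residual_sd = stats::sigma(fit)
  )
}

#' Fit rates for every endmember of a bleaching-curve table
#'
#' @param curves Output of [bleaching_curves()].
#' @return Named vector of decay rates (1/s); `NA` for flagged endmembers.
#' @export
fit_decay_rates <- function(curves) {
  ems <- unique(curves$endmember)
  out <- vapply(ems, function(e) {
    cc <- curves[curves$endmember == e, ]
    if (all(is.na(cc$normalized))) return(NA_real_)
    fit_decay_rate(cc$time_s, cc$normalized)$rate
  }, numeric(1))
  names(out) <- ems
  out
}

#' Unmixing error as a function of bleaching time
#'
#' @param series Timeseries `acquisition_series`.
#' @param library A `spectral_library`.
#' @param solver Unmixing solver.
#' @param every_s Optional analysis cadence (see [bleaching_curves()]).
#' @return Data frame with `time_s`, `pct_rms_image_averaged` and
#'   `pct_rms_pixelwise_mean` (mean over pixels with nonzero signal).
#' @export
error_vs_time <- function(series, library, solver = "ols", every_s = NULL) {
  stopifnot(inherits(series, "acquisition_series"))
  if (series$kind != "timeseries") stop("error_vs_time needs a timeseries")
  times <- series$times_s
  keep <- seq_along(times)
  if (!is.null(every_s)) {
    rel <- times - times[1]
    keep <- which(abs(rel - round(rel / every_s) * every_s) < 1e-6)
  }
  rows <- lapply(keep, function(i) {
    res <- unmix(series$cubes[[i]], library, solver)
    px <- percent_rms_error(res, "pixelwise")
    data.frame(
      time_s = times[i],
      pct_rms_image_averaged = percent_rms_error(res, "image_averaged"),
      pct_rms_pixelwise_mean = mean(px, na.rm = TRUE)
    )
  })
  do.call(rbind, rows)
}
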