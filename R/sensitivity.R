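# Theoretical sensitivity/specificity study: spike a known endmember
# spectrum into a control cube at graded peak intensities, unmix, derive a
# detection threshold from the zero-added abundance distribution, and
# quantify response slope and positive-pixel counts.

#' Rescale a cube to a common bit depth
#'
#' Multiplies intensities by `(2^target - 1)/(2^source - 1)` so full scale
#' maps to full scale (a 12-bit 4095 becomes a 16-bit 65535, and 0 stays
#' 0), allowing intensity-level comparison between detectors of different
#' depth.
#'
#' @param cube A `spectral_cube`.
#' @param target_bits Target bit depth (default 16).
#' @return Rescaled `spectral_cube` with updated `bit_depth`.
#' @export
rescale_to_common_depth <- function(cube, target_bits = 16) {
  stopifnot(inherits(cube, "spectral_cube"), target_bits %in% 8:16)
  f <- (2^target_bits - 1) / (2^cube$bit_depth - 1)
  meta <- cube$meta
  meta$rescaled_from_bits <- cube$bit_depth
  spectral_cube(cube$data * f, cube$axis, bit_depth = target_bits, meta = meta)
}

#' Add a scaled endmember spectrum inside a region of interest
#'
#' The spectrum is scaled so that its maximum band value equals
#' `peak_intensity` and added to every pixel inside the ROI; pixels outside
#' are untouched. A peak intensity of zero returns an identical cube.
#'
#' @param cube A `spectral_cube`.
#' @param spectrum Per-band spectrum on the cube's axis (nonzero).
#' @param roi An `roi` within the cube.
#' @param peak_intensity Peak band intensity to add (>= 0).
#' @return The spiked `spectral_cube`.
#' @export
add_spikein <- function(cube, spectrum, roi, peak_intensity) {
  stopifnot(inherits(cube, "spectral_cube"), peak_intensity >= 0)
  roi <- roi_for_cube(roi, cube)
  if (length(spectrum) != n_bands(cube$axis)) {
    stop("spike spectrum length does not match the cube axis")
  }
  if (max(spectrum) <= 0) stop("spike spectrum must be nonzero")
  if (peak_intensity == 0) return(cube)
  add <- spectrum / max(spectrum) * peak_intensity
  m <- cube_matrix(cube)
  idx <- as.vector(roi$mask)
  m[idx, ] <- sweep(m[idx, , drop = FALSE], 2, add, `+`)
  meta <- cube$meta
  meta$corrected <- TRUE # spiked values may exceed the raw ceiling
  meta$spike <- list(peak_intensity = peak_intensity)
  matrix_to_cube(m, cube, meta = meta)
}

#' Specification of a spike-in sensitivity study
#'
#' @param target Endmember name whose spectrum is spiked and whose unmixed
#'   abundance is tracked.
#' @param roi Optional `roi` receiving the spike; defaults to a centered
#'   square of side 30 (900 pixels).
#' @param levels Peak intensities to add; must include 0, which defines the
#'   detection threshold. Default 0..1000 in steps of 100 (A.U.).
#' @param quantile Detection quantile applied to the zero-added ROI
#'   abundance distribution (default 0.985; 0.9985 is the stricter variant).
#' @param scale_to_bits Common bit depth the control is rescaled to before
#'   spiking (default 16).
#' @return A `spikein_spec`.
#' @export
spikein_spec <- function(target, roi = NULL, levels = seq(0, 1000, by = 100),
                         quantile = 0.985, scale_to_bits = 16) {
  stopifnot(is.character(target), length(target) == 1)
  if (!0 %in% levels) stop("levels must include 0 (the null level defining the threshold)")
  if (any(levels < 0)) stop("levels must be >= 0")
  if (!(quantile > 0 && quantile < 1)) stop("quantile must lie strictly in (0, 1)")
  structure(
    list(target = target, roi = roi, levels = sort(unique(levels)),
         quantile = quantile, scale_to_bits = scale_to_bits),
    class = "spikein_spec"
  )
}

#' Classify pixels as positive against an abundance threshold
#'
#' A pixel is positive iff its abundance is greater than or equal to the
#' threshold (ties count as positive).
#'
#' @param abundance_image Per-pixel abundance matrix.
#' @param threshold Finite abundance threshold.
#' @return List with `mask` (logical matrix), `count`, and `fraction_pct`
#'   (count over total pixels, as a percentage).
#' @export
classify_positives <- function(abundance_image, threshold) {
  stopifnot(is.matrix(abundance_image), is.finite(threshold))
  mask <- abundance_image >= threshold
  count <- sum(mask)
  list(mask = mask, count = count,
       fraction_pct = 100 * count / length(abundance_image))
}

#' Run a spike-in theoretical sensitivity study
#'
#' For each level: the target spectrum is added to the ROI at that peak
#' intensity, the cube is unmixed, and the target-abundance distribution
#' inside the ROI is recorded. An ordinary least-squares line (with
#' intercept) is fitted to mean ROI abundance versus level. The detection
#' threshold is the nearest-rank `quantile` of the zero-added ROI
#' abundances; at every level, all pixels of the whole image are classified
#' against it, and the false-positive fraction counts positives outside the
#' ROI over the total pixel count.
#'
#' @param control `spectral_cube` containing no target-endmember signal
#'   (e.g. an autofluorescence-only control). Rescaled to
#'   `spec$scale_to_bits` before spiking.
#' @param library A `spectral_library` containing the target.
#' @param spec A `spikein_spec`.
#' @param solver Unmixing solver.
#' @return A `sensitivity_report`: `levels`, `roi_abundances` (list of
#'   per-level ROI abundance vectors), `mean_abundance`, `slope`,
#'   `intercept`, `threshold`, `positive_count`, `false_positive_pct`
#'   (per level), `n_total_pixels`, `quantile`, `roi`.
#' @export
run_sensitivity <- function(control, library, spec, solver = "ols") {
  stopifnot(inherits(control, "spectral_cube"),
            inherits(library, "spectral_library"),
            inherits(spec, "spikein_spec"))
  if (!spec$target %in% library$names) {
    stop("target endmember ", spec$target, " is not in the library")
  }
  d <- dim(control$data)
  r <- if (is.null(spec$roi)) {
    square_roi(d[1:2], side = min(30, min(d[1:2])))
  } else {
    roi_for_cube(spec$roi, control)
  }
  control <- rescale_to_common_depth(control, spec$scale_to_bits)
  spectrum <- library$spectra[, spec$target]
  idx <- as.vector(r$mask)
  per_level <- lapply(spec$levels, function(L) {
    spiked <- add_spikein(control, spectrum, r, L)
    res <- unmix(spiked, library, solver)
    ab <- res$abundances[, , spec$target]
    list(ab = ab, roi_values = ab[r$mask])
  })
  roi_ab <- lapply(per_level, `[[`, "roi_values")
  mean_ab <- vapply(roi_ab, mean, numeric(1))
  fit <- stats::lm(mean_ab ~ spec$levels)
  threshold <- nearest_rank_quantile(roi_ab[[which(spec$levels == 0)]],
                                     spec$quantile)
  pos <- lapply(per_level, function(pl) classify_positives(pl$ab, threshold))
  n_total <- prod(d[1:2])
  fp_pct <- vapply(pos, function(p) 100 * sum(p$mask & !r$mask) / n_total,
                   numeric(1))
  structure(
    list(
      target = spec$target, levels = spec$levels, roi_abundances = roi_ab,
      mean_abundance = mean_ab,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      threshold = threshold,
      positive_count = vapply(pos, `[[`, numeric(1), "count"),
      false_positive_pct = fp_pct,
      n_total_pixels = n_total, quantile = spec$quantile, roi = r
    ),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("sensitivity_report for ", x$target, ": slope ",
      format(x$slope, digits = 6), ", threshold ",
      format(x$threshold, digits = 6), " (q = ", x$quantile, ")\n",
      "levels: ", paste(x$levels, collapse = ", "), "\n",
      "positive pixels: ", paste(x$positive_count, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
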