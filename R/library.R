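# Endmember spectral libraries: construction from single-fluorophore
# control cubes, normalization, and conditioning diagnostics.

#' Build a spectral library
#'
#' @param spectra Named list of per-band spectra, or a bands x endmember
#'   matrix with column names. All spectra must be nonnegative, nonzero,
#'   and on the common axis.
#' @param axis The shared `wavelength_axis`.
#' @param normalization `"raw"` (spectra kept as given), `"peak1"` (each
#'   divided by its maximum, so unmixed abundances are in peak-intensity
#'   units), or `"area1"` (each divided by its band sum).
#' @return A `spectral_library` with fields `names`, `spectra` (bands x
#'   endmember matrix), `axis`, `normalization`.
#' @export
build_library <- function(spectra, axis, normalization = c("raw", "peak1", "area1")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(axis, "wavelength_axis"))
  if (is.list(spectra)) {
    if (is.null(names(spectra)) || any(!nzchar(names(spectra)))) {
      stop("spectra must be named")
    }
    spectra <- do.call(cbind, spectra)
  }
  stopifnot(is.matrix(spectra))
  if (is.null(colnames(spectra))) stop("library spectra must carry names")
  if (anyDuplicated(colnames(spectra))) stop("duplicate endmember names")
  if (nrow(spectra) != n_bands(axis)) {
    stop("spectra length ", nrow(spectra), " does not match the ",
         n_bands(axis), "-band axis")
  }
  if (min(spectra) < 0) stop("library spectra must be nonnegative")
  if (any(colSums(spectra) == 0)) {
    stop("endmember(s) ",
         paste(colnames(spectra)[colSums(spectra) == 0], collapse = ", "),
         " are all-zero")
  }
  spectra <- switch(normalization,
    raw = spectra,
    peak1 = sweep(spectra, 2, apply(spectra, 2, max), `/`),
    area1 = sweep(spectra, 2, colSums(spectra), `/`)
  )
  structure(
    list(names = colnames(spectra), spectra = spectra, axis = axis,
         normalization = normalization),
    class = "spectral_library"
  )
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("spectral_library: ", length(x$names), " endmembers (",
      paste(x$names, collapse = ", "), "), ", n_bands(x$axis),
      " bands, normalization ", x$normalization, "\n", sep = "")
  invisible(x)
}

#' Extract an endmember spectrum from a single-fluorophore control cube
#'
#' Defines a region of interest by intensity thresholding of the total
#' fluorescence emission image (sum of all bands): pixels at or above the
#' `threshold_quantile` quantile of total emission enter the ROI. The
#' endmember spectrum is the pixel-averaged spectrum over the ROI. The cube
#' should be background-subtracted first.
#'
#' A quantile threshold (default 0.95, nearest-rank estimator) is
#' reproducible across exposure scales, unlike an absolute count threshold.
#'
#' @param cube Background-subtracted `spectral_cube` of a single-fluorophore
#'   control.
#' @param threshold_quantile Fraction in (0, 1).
#' @return List with `spectrum` (per-band vector) and `roi`.
#' @export
extract_endmember <- function(cube, threshold_quantile = 0.95) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (!(threshold_quantile > 0 && threshold_quantile < 1)) {
    stop("threshold_quantile must lie strictly between 0 and 1")
  }
  tot <- total_emission_image(cube)
  thr <- nearest_rank_quantile(as.vector(tot), threshold_quantile)
  mask <- tot >= thr
  if (!any(mask)) stop("thresholding produced an empty ROI")
  r <- roi(mask, label = sprintf("total emission >= q%.3g", threshold_quantile))
  list(spectrum = spectrum_from_cube(cube, r), roi = r)
}

#' Conditioning report for a spectral library
#'
#' Near-collinear endmembers make unmixing ill-posed: abundance estimates
#' trade off along the shared direction and noise is amplified. This
#' reports all pairwise cosine similarities between endmember spectra and
#' the condition number of the library matrix (ratio of extreme singular
#' values; `Inf` for rank-deficient libraries).
#'
#' @param library A `spectral_library` with >= 2 endmembers.
#' @return List with `cosine` (symmetric matrix), `condition_number`, and
#'   `rank_deficient` flag.
#' @export
condition_report <- function(library) {
  stopifnot(inherits(library, "spectral_library"))
  s <- library$spectra
  if (ncol(s) < 2) stop("condition report needs >= 2 endmembers")
  norms <- sqrt(colSums(s^2))
  cosine <- crossprod(s) / tcrossprod(norms)
  sv <- svd(s, nu = 0, nv = 0)$d
  tol <- max(dim(s)) * .Machine$double.eps * max(sv)
  deficient <- min(sv) <= tol
  list(
    cosine = cosine,
    condition_number = if (deficient) Inf else max(sv) / min(sv),
    rank_deficient = deficient
  )
}
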