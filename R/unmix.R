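# Per-pixel linear spectral unmixing and its error metrics.
#
# Each pixel's measured spectrum x is decomposed over the library matrix S
# (bands x endmembers) by least squares: minimize ||x - S a||^2 over the
# abundance vector a, unconstrained (ols) or under a >= 0 (nnls). The
# reconstruction S a and the per-pixel RMS residual quantify fit quality.

#' Linearly unmix a spectral cube against a library
#'
#' Solves the per-pixel least-squares problem for every pixel. The default
#' solver is unconstrained ordinary least squares; `"nnls"` constrains
#' abundances to be nonnegative (negative abundances are non-physical).
#' No sum-to-one constraint is applied: abundances are in the units set by
#' the library normalization and need not sum to anything.
#'
#' The per-pixel RMS error is
#' `sqrt(mean over bands of (measured - fitted)^2)`, with the band count
#' as the averaging denominator; `rms_signal` is the same norm of the
#' measured spectrum itself.
#'
#' @param cube A `spectral_cube`.
#' @param library A `spectral_library` on the same axis with fewer
#'   endmembers than bands.
#' @param solver `"ols"` or `"nnls"`.
#' @return An `unmix_result`: `abundances` (rows x cols x endmember array),
#'   `fit` (reconstructed cube), `rms_error` and `rms_signal` (per-pixel
#'   matrices), `solver`, `library`.
#' @export
unmix <- function(cube, library, solver = c("ols", "nnls")) {
  solver <- match.arg(solver)
  stopifnot(inherits(cube, "spectral_cube"), inherits(library, "spectral_library"))
  stop_if_axis_mismatch(cube$axis, library$axis, "cube and library")
  s <- library$spectra
  if (ncol(s) > nrow(s)) {
    stop("library must not have more endmembers than bands")
  }
  if (qr(s)$rank < ncol(s)) {
    stop("library matrix is rank deficient; see condition_report() for ",
         "pairwise endmember similarity")
  }
  x <- t(cube_matrix(cube)) # bands x pixels
  a <- if (solver == "ols") {
    solve(crossprod(s), crossprod(s, x))
  } else {
    apply(x, 2, function(px) pracma::lsqnonneg(s, px)$x)
  }
  fit <- s %*% a # bands x pixels
  rms_error <- sqrt(colMeans((x - fit)^2))
  rms_signal <- sqrt(colMeans(x^2))
  d <- dim(cube$data)
  ab <- array(t(a), dim = c(d[1], d[2], ncol(s)),
              dimnames = list(NULL, NULL, library$names))
  fit_cube <- model_cube(
    array(t(fit), dim = d), cube$axis, bit_depth = cube$bit_depth,
    meta = list(fit_of = "unmix")
  )
  structure(
    list(
      abundances = ab, fit = fit_cube,
      rms_error = matrix(rms_error, d[1], d[2]),
      rms_signal = matrix(rms_signal, d[1], d[2]),
      solver = solver, library = library
    ),
    class = "unmix_result"
  )
}

#' @export
print.unmix_result <- function(x, ...) {
  cat("unmix_result: ", paste(dimnames(x$abundances)[[3]], collapse = ", "),
      " via ", x$solver, "; mean RMS error ",
      format(mean(x$rms_error), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Percent RMS error of an unmixing result
#'
#' Two conventions, which behave differently on heterogeneous images:
#' `"image_averaged"` divides the image-averaged RMS error by the
#' image-averaged RMS signal (one scalar); `"pixelwise"` divides per pixel
#' (an image). Both are scaled to percent. Pixels with zero RMS signal are
#' excluded from the pixelwise map (returned as `NA`), with the exclusion
#' count attached as an attribute.
#'
#' @param result An `unmix_result`.
#' @param mode `"image_averaged"` or `"pixelwise"`.
#' @return Scalar percentage, or a per-pixel percentage matrix.
#' @export
percent_rms_error <- function(result, mode = c("image_averaged", "pixelwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "unmix_result"))
  if (mode == "image_averaged") {
    ms <- mean(result$rms_signal)
    if (ms <= 0) stop("image-averaged RMS signal is zero")
    100 * mean(result$rms_error) / ms
  } else {
    out <- 100 * result$rms_error / result$rms_signal
    zero <- result$rms_signal == 0
    out[zero] <- NA_real_
    attr(out, "n_excluded") <- sum(zero)
    out
  }
}

#' Reconstruct a cube from abundances and a library
#'
#' Per-pixel linear combination of library spectra; the exact inverse of
#' [render_scene()] for noise-free input.
#'
#' @param abundances rows x cols x endmember array (dimnames naming the
#'   endmembers in library order or a subset/permutation of it).
#' @param library A `spectral_library`.
#' @return A `spectral_cube` (marked corrected: mixtures are not bounded by
#'   a detector ceiling).
#' @export
reconstruct <- function(abundances, library) {
  stopifnot(is.array(abundances), length(dim(abundances)) == 3,
            inherits(library, "spectral_library"))
  nm <- dimnames(abundances)[[3]]
  if (is.null(nm)) stop("abundance array must carry endmember dimnames")
  if (!all(nm %in% library$names)) {
    stop("unknown endmember(s): ", paste(setdiff(nm, library$names), collapse = ", "))
  }
  d <- dim(abundances)
  a <- matrix(abundances, d[1] * d[2], d[3]) # pixels x endmembers
  s <- library$spectra[, nm, drop = FALSE] # bands x endmembers
  m <- a %*% t(s) # pixels x bands
  model_cube(array(m, dim = c(d[1], d[2], nrow(s))), library$axis)
}
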