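# Shared numeric helpers.

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the previous
#' generator state afterwards, so seeded simulations do not disturb the
#' caller's random stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Nearest-rank sample quantile
#'
#' The smallest order statistic whose cumulative fraction is at least `q`:
#' `sort(x)[ceiling(q * length(x))]`. Distribution-free and exact on small
#' samples; used for the spike-in detection threshold. For 900 values
#' 1..900 and `q = 0.985` this is the value at rank 887.
#'
#' @param x Numeric vector.
#' @param q Quantile in (0, 1).
#' @return A single value of `x`.
#' @export
nearest_rank_quantile <- function(x, q) {
  stopifnot(length(x) >= 1, is.numeric(q), length(q) == 1)
  if (!(q > 0 && q < 1)) stop("quantile must lie strictly between 0 and 1")
  sort(x)[ceiling(q * length(x))]
}

clamp0 <- function(x) {
  n_clamped <- sum(x < 0)
  x[x < 0] <- 0
  attr(x, "n_clamped") <- n_clamped
  x
}
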