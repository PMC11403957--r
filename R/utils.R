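# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' Every source of randomness in the package draws its seed from one master
#' seed through this function, so that stages (simulation, fold assignment,
#' tie-breaking in k-NN, holdout splits) are decoupled: changing the number
#' of draws in one stage does not perturb another.
#'
#' @param seed master seed (integer).
#' @param offset non-negative integer identifying the consumer stream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(offset))
  m <- 2147483647  # 2^31 - 1, Mersenne prime used by Lehmer generators
  s <- (abs(as.numeric(seed)) %% m)
  as.integer(((s * 48271 + 11 + as.numeric(offset) * 7919) %% (m - 1)) + 1)
}

#' Sample skewness (method-of-moments)
#' @param x numeric vector.
#' @return the third standardized sample moment.
#' @keywords internal
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean(((x - m) / s)^3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, e) {
  stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE)
}
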