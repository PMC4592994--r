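#' Draw from the Polya-Gamma distribution
#'
#' Exact sampling from PG(b, c) for positive integer shape `b` via Devroye's
#' alternating-series rejection sampler for PG(1, c); a PG(b, c) variate is
#' the sum of `b` independent PG(1, c) variates (the distribution is
#' infinitely divisible in its shape). The density is symmetric in the tilt:
#' PG(b, c) and PG(b, -c) are the same distribution. The mean is
#' `b * tanh(c/2) / (2c)` (and `b/4` at `c = 0`).
#'
#' Augmenting a logistic likelihood with PG variates makes every conditional
#' of the liability-threshold model Gaussian or otherwise standard, which is
#' what turns the logit-link ordinal model into an exact Gibbs sampler.
#'
#' @param n number of draws.
#' @param shape positive integer shape parameter `b` (the model uses 2).
#' @param tilt real tilt parameter `c`, recycled to length `n`.
#' @return numeric vector of `n` positive draws.
#' @examples
#' set.seed(1)
#' mean(rpolyagamma(1e4, 2, 0))   # ~ 0.5
#' mean(rpolyagamma(1e4, 2, 2))   # ~ tanh(1)/2
#' @export
rpolyagamma <- function(n, shape = 2, tilt = 0) {
  if (length(shape) != 1 || !is.finite(shape) || shape <= 0 ||
      shape != round(shape)) {
    abort("`shape` must be a single positive integer.",
          class = "ordpg_invalid_parameter")
  }
  if (length(tilt) < 1 || any(!is.finite(tilt))) {
    abort("`tilt` must be finite.", class = "ordpg_invalid_parameter")
  }
  cpp_rpg(as.integer(n), as.integer(shape), as.double(tilt))
}

#' Draw from a truncated normal distribution
#'
#' Samples N(`mean`, `sd^2`) restricted to the open interval
#' (`lower`, `upper`). The sampler is tail-safe: intervals lying many
#' standard deviations into a tail are handled by shifted-exponential or
#' tilted-uniform rejection rather than naive retry or inverse-CDF
#' evaluation, so draws stay finite and inside the interval even for
#' intervals like (8, 9) on a standard normal.
#'
#' @param n number of draws.
#' @param mean,sd mean and standard deviation, recycled to length `n`.
#' @param lower,upper truncation bounds (may be `-Inf` / `Inf`), recycled.
#' @return numeric vector of `n` draws, each strictly inside its interval.
#' @examples
#' set.seed(1)
#' mean(rtruncnorm(1e4, 0, 1, lower = 0))  # ~ sqrt(2/pi)
#' range(rtruncnorm(1e3, 0, 1, lower = 8, upper = 9))
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    abort("`sd` must be positive and finite.",
          class = "ordpg_invalid_parameter")
  }
  if (any(is.na(lower)) || any(is.na(upper))) {
    abort("truncation bounds must not be NA.",
          class = "ordpg_invalid_parameter")
  }
  if (any(rep_len(lower, n) >= rep_len(upper, n))) {
    abort("`lower` must be strictly below `upper`.",
          class = "ordpg_invalid_interval")
  }
  cpp_rtnorm(as.integer(n), as.double(mean), as.double(sd),
             as.double(lower), as.double(upper))
}

#' Draw from a scaled inverse chi-square distribution
#'
#' A scaled-inverse-chi-square(df, scale) variate is `df * scale / X` with
#' `X ~ chi-square(df)`; its mean is `df * scale / (df - 2)` for `df > 2`.
#' This is the conjugate full conditional of both variance components of the
#' model (polygenic and coefficient variances).
#'
#' @param n number of draws.
#' @param df positive degrees of freedom.
#' @param scale positive scale.
#' @return numeric vector of `n` positive draws.
#' @export
rscinvchisq <- function(n, df, scale) {
  if (any(!is.finite(df)) || any(df <= 0) ||
      any(!is.finite(scale)) || any(scale <= 0)) {
    abort("`df` and `scale` must be positive and finite.",
          class = "ordpg_invalid_parameter")
  }
  df * scale / rchisq(n, df)
}

#' Derive a reproducible sub-seed
#'
#' Deterministically maps a master seed and a replicate (or task) index to a
#' new seed in `[1, 2^31 - 2]` via two multiplicative-congruential steps, so
#' replicate-level random streams are independent of execution order and
#' bit-reproducible across runs.
#'
#' @param seed master integer seed.
#' @param index non-negative integer index of the sub-stream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime of the Lehmer generator
  h <- (abs(as.double(seed)) %% m) * 48271 %% m
  h <- (h + as.double(index) + 1) %% m
  h <- (h * 69621) %% m
  as.integer(h %% (m - 1) + 1)
}
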