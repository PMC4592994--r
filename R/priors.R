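#' Prior specification for the Bayesian ordinal model
#'
#' Priors follow the conjugate structure of the liability-threshold model:
#' `beta | sigma2_beta ~ N(beta0, Sigma0 * sigma2_beta)`, scaled inverse
#' chi-square priors on both variance components, and order statistics of
#' U(`gamma_min`, `gamma_max`) on the `C - 1` thresholds.
#'
#' The defaults are the weakly informative real-data settings:
#' `beta0 = 0`, `Sigma0 = 10000 * I`, `nu_beta = 3`, `S_beta = 0.001` and
#' threshold bounds of +/- 1000. For replicated simulation work use
#' `sim_prior()`, which fixes `sigma2_beta = 1` and tightens the threshold
#' bounds to +/- 4.
#'
#' @param beta0 prior mean of the coefficients; a scalar is recycled.
#' @param sigma0 prior covariance of `beta` up to the factor `sigma2_beta`:
#'   either a scalar `v` (meaning `v * I`, required for the n-dimensional
#'   ridge draw when `p >> n`) or a full positive-definite matrix.
#' @param nu_beta,S_beta degrees of freedom and scale of the scaled inverse
#'   chi-square prior on `sigma2_beta`.
#' @param nu_b,S_b prior for the polygenic variance `sigma2_b` (used only
#'   when a polygenic term is fitted).
#' @param gamma_min,gamma_max support bounds of the uniform order-statistics
#'   prior on the thresholds; these bound the threshold draws only, never
#'   the liability partition itself (whose outer cells extend to +/- Inf).
#' @param fix_sigma_beta if `TRUE`, `sigma2_beta` is held at 1 and its
#'   update is skipped (the simulation-study configuration).
#' @param improper_beta if `TRUE`, a flat prior `p(beta) ~ constant` is used
#'   and all `Sigma0`-dependent terms vanish from the coefficient update;
#'   this forces `fix_sigma_beta` since `sigma2_beta` then has no role.
#' @return an object of class `blor_prior`.
#' @seealso [blor()], [blor_chain()], [sim_prior()]
#' @export
blor_prior <- function(beta0 = 0, sigma0 = 10000,
                       nu_beta = 3, S_beta = 0.001,
                       nu_b = 5, S_b = 1,
                       gamma_min = -1000, gamma_max = 1000,
                       fix_sigma_beta = FALSE, improper_beta = FALSE) {
  if (!is.finite(gamma_min) || !is.finite(gamma_max) ||
      gamma_min >= gamma_max) {
    abort("`gamma_min` must be strictly below `gamma_max` and both finite.",
          class = "ordpg_invalid_parameter")
  }
  scalar_sigma0 <- length(sigma0) == 1 && !is.matrix(sigma0)
  if (scalar_sigma0 && (!is.finite(sigma0) || sigma0 <= 0)) {
    abort("scalar `sigma0` must be positive.",
          class = "ordpg_invalid_parameter")
  }
  if (improper_beta) fix_sigma_beta <- TRUE
  if (!fix_sigma_beta && (nu_beta <= 0 || S_beta <= 0)) {
    abort("`nu_beta` and `S_beta` must be positive when sigma2_beta is sampled.",
          class = "ordpg_invalid_parameter")
  }
  if (nu_b <= 0 || S_b <= 0) {
    abort("`nu_b` and `S_b` must be positive.",
          class = "ordpg_invalid_parameter")
  }
  structure(
    list(beta0 = beta0, sigma0 = sigma0, nu_beta = nu_beta, S_beta = S_beta,
         nu_b = nu_b, S_b = S_b, gamma_min = gamma_min, gamma_max = gamma_max,
         fix_sigma_beta = fix_sigma_beta, improper_beta = improper_beta),
    class = "blor_prior"
  )
}

#' Simulation-study prior
#'
#' The prior used by the replicated simulation harness: `beta ~ N(0,
#' 10000 * I)` with `sigma2_beta` fixed at 1, and threshold bounds of
#' +/- 4.
#'
#' @return a [blor_prior()] object.
#' @export
sim_prior <- function() {
  blor_prior(beta0 = 0, sigma0 = 10000, fix_sigma_beta = TRUE,
             gamma_min = -4, gamma_max = 4)
}

#' Chain configuration for the Gibbs sampler
#'
#' Chains are never thinned: every post-burn-in sweep is stored, since
#' subsampling MCMC output only loses precision for posterior means,
#' variances and quantiles.
#'
#' @param n_iter total Gibbs sweeps.
#' @param burn_in sweeps discarded before storage (`burn_in < n_iter`).
#' @param link `"logit"` (Polya-Gamma augmented, the default) or
#'   `"probit"`, which pins every augmentation value at 1 and reduces the
#'   sampler to the classic probit threshold-model Gibbs sampler.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param profile optional shorthand setting `n_iter`/`burn_in`:
#'   `"realdata"` = 60000 / 20000, `"simulation"` = 20000 / 10000.
#' @param ridge how to draw the coefficient block: `"auto"` switches to the
#'   n-dimensional identity-equivalent draw when `p > 2n` (requires the
#'   scalar zero-mean prior), `"direct"` always factorizes the p x p
#'   precision, `"woodbury"` always uses the n-dimensional route.
#' @param pin_omega testing hook: keep all augmentation values at 1 in
#'   logit mode without consuming random numbers, so a logit-configured
#'   chain reproduces the probit chain draw-for-draw under a shared seed.
#' @param store_liabilities store the post-burn-in liability draws
#'   (memory-heavy; used for invariant checks).
#' @param verbose print progress every 1000 sweeps.
#' @return an object of class `blor_chain`.
#' @export
blor_chain <- function(n_iter = 60000, burn_in = 20000,
                       link = c("logit", "probit"), seed = NULL,
                       profile = NULL,
                       ridge = c("auto", "direct", "woodbury"),
                       pin_omega = FALSE, store_liabilities = FALSE,
                       verbose = FALSE) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("realdata", "simulation"))
    if (profile == "realdata") {
      n_iter <- 60000; burn_in <- 20000
    } else {
      n_iter <- 20000; burn_in <- 10000
    }
  }
  link <- match.arg(link)
  ridge <- match.arg(ridge)
  if (burn_in >= n_iter || burn_in < 0) {
    abort("`burn_in` must be non-negative and strictly below `n_iter`.",
          class = "ordpg_invalid_parameter")
  }
  structure(
    list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
         link = link, seed = seed, ridge = ridge, pin_omega = pin_omega,
         store_liabilities = store_liabilities, verbose = verbose),
    class = "blor_chain"
  )
}
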