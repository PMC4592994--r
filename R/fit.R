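#' Fit a Bayesian ordinal regression by Polya-Gamma Gibbs sampling
#'
#' Fits the latent-liability cumulative-link model
#' `l = X beta + Z b + e`, `y = c` iff `gamma_{c-1} < l < gamma_c`,
#' with logistic errors (logit link, the BLOR model) or standard-normal
#' errors (probit link, the BPOR model). Under the logit link each
#' observation carries a Polya-Gamma augmentation variable `omega ~ PG(2, .)`
#' that renders every full conditional standard, so the sampler is an exact
#' Gibbs sampler, not an approximation; fixing all `omega = 1` recovers the
#' probit sampler as a special case.
#'
#' One Gibbs sweep updates, in order: liabilities (truncated normal),
#' augmentation values (Polya-Gamma), coefficients (multivariate normal),
#' polygenic effects (multivariate normal, if present), the polygenic
#' variance (scaled inverse chi-square), the thresholds (uniform on the
#' interval pinched by the liabilities and neighboring thresholds), and the
#' coefficient variance (scaled inverse chi-square).
#'
#' When all markers enter the design matrix with the scalar shrinkage prior
#' `beta ~ N(0, I sigma2_beta)` the model is a threshold Bayesian ridge
#' regression; for `p > 2n` the coefficient draw automatically switches to
#' an n-dimensional algorithm with the identical sampling distribution.
#'
#' @param data a data frame with one row per observation.
#' @param formula model formula, e.g. `y ~ x1 + x2 + x3`. The response must
#'   be ordinal categories coded 1..C; no intercept is fitted (thresholds
#'   absorb it, and a constant column in the design is an error).
#' @param line optional bare column name identifying the genotype/line of
#'   each observation; required for a polygenic term.
#' @param G optional genomic relationship matrix (I x I, symmetric positive
#'   definite, rows/columns ordered as the first appearance of each line).
#'   Supplying `G` turns on the polygenic term.
#' @param prior a [blor_prior()].
#' @param chain a [blor_chain()]; its `link` entry selects BLOR vs BPOR.
#' @return an object of class `blor_fit` with stored post-burn-in draws.
#'   Use [tidy()] for posterior summaries, [glance()] for fit-level metrics
#'   (DIC, training Brier score), [predict()] for category probabilities,
#'   and [autoplot()] for trace plots.
#' @examples
#' sim <- simulate_ordinal(sim_spec(n_i = 5, seed = 42), rep = 1)
#' fit <- blor(sim, y ~ x1 + x2 + x3, prior = sim_prior(),
#'             chain = blor_chain(500, 250, seed = 1))
#' tidy(fit)
#' @export
blor <- function(data, formula, line = NULL, G = NULL,
                 prior = blor_prior(), chain = blor_chain()) {
  line_vec <- resolve_column(data, rlang::enquo(line))
  inp <- build_model_inputs(data, formula, line_vec, G)
  fit <- blor_matrix(inp$y, inp$X, line = inp$line, G = inp$G,
                     prior = prior, chain = chain)
  fit$formula <- formula
  fit$call <- match.call()
  fit
}

#' Fit the Bayesian ordinal model from a response vector and design matrix
#'
#' Matrix interface behind [blor()], convenient for whole-genome marker
#' matrices (the threshold-ridge `p >> n` mode).
#'
#' @param y integer ordinal response in 1..C; every category must occur.
#' @param X numeric n x p design matrix, complete, without a constant
#'   column. Marker codes should be centered by the caller if desired.
#' @param line optional integer/factor vector of line identifiers.
#' @param G optional relationship matrix; turns on the polygenic term.
#' @inheritParams blor
#' @return an object of class `blor_fit`.
#' @export
blor_matrix <- function(y, X, line = NULL, G = NULL,
                        prior = blor_prior(), chain = blor_chain()) {
  stopifnot(inherits(prior, "blor_prior"), inherits(chain, "blor_chain"))
  inp <- validate_ordinal_data(y, X, line, G)
  p <- ncol(inp$X)

  beta0 <- rep_len(as.double(prior$beta0), p)
  scalar_sigma0 <- length(prior$sigma0) == 1 && !is.matrix(prior$sigma0)
  if (scalar_sigma0) {
    Sigma0inv <- diag(1 / prior$sigma0, p)
    sigma0_scalar <- as.double(prior$sigma0)
  } else {
    S0 <- as.matrix(prior$sigma0)
    if (nrow(S0) != p || ncol(S0) != p) {
      abort(sprintf("`sigma0` must be %d x %d.", p, p))
    }
    Sigma0inv <- tryCatch(chol2inv(chol(S0)), error = function(e) {
      abort("`sigma0` must be positive definite.",
            class = "ordpg_matrix_conditioning")
    })
    sigma0_scalar <- NA_real_
  }
  if (prior$improper_beta) Sigma0inv <- matrix(0, p, p)

  Ginv <- matrix(0, 0, 0)
  if (!is.null(inp$G)) Ginv <- chol2inv(chol(inp$G))

  cpp_prior <- list(
    beta0 = beta0, Sigma0inv = Sigma0inv, improper = prior$improper_beta,
    sigma0_scalar = sigma0_scalar, nu_beta = prior$nu_beta,
    S_beta = prior$S_beta, fix_sigma_beta = prior$fix_sigma_beta,
    nu_b = prior$nu_b, S_b = prior$S_b,
    gamma_min = prior$gamma_min, gamma_max = prior$gamma_max
  )
  cpp_config <- list(
    n_iter = chain$n_iter, burn_in = chain$burn_in,
    probit = chain$link == "probit", pin_omega = chain$pin_omega,
    ridge_method = match(chain$ridge, c("auto", "direct", "woodbury")) - 1L,
    store_liabilities = chain$store_liabilities, verbose = chain$verbose
  )
  if (!is.null(chain$seed)) set.seed(chain$seed)

  draws <- cpp_gibbs(inp$y, inp$X,
                     if (is.null(inp$line)) integer(0) else inp$line,
                     Ginv, inp$C, cpp_prior, cpp_config)

  term_names <- colnames(inp$X)
  if (is.null(term_names)) term_names <- paste0("beta", seq_len(p))
  colnames(draws$beta) <- term_names
  colnames(draws$gamma) <- paste0("gamma", seq_len(inp$C - 1))

  structure(
    list(
      samples = list(
        beta = draws$beta, gamma = draws$gamma,
        sigma2_beta = as.numeric(draws$sigma2_beta),
        sigma2_b = as.numeric(draws$sigma2_b),
        b = draws$b, liabilities = draws$liabilities
      ),
      y = inp$y, X = inp$X, line = inp$line, G = inp$G, C = inp$C,
      link = chain$link, k = NULL, prior = prior, chain = chain,
      used_woodbury = draws$used_woodbury, call = match.call()
    ),
    class = "blor_fit"
  )
}

# Posterior (or k-scaled) point estimates of (beta, gamma, b)
point_estimates <- function(fit) {
  list(
    beta = colMeans(fit$samples$beta),
    gamma = colMeans(fit$samples$gamma),
    b = if (length(fit$samples$b)) colMeans(fit$samples$b) else NULL
  )
}

#' @export
coef.blor_fit <- function(object, ...) point_estimates(object)

#' @export
print.blor_fit <- function(x, ...) {
  kept <- nrow(x$samples$beta)
  cat(sprintf(
    "Bayesian %s ordinal regression (%s)\n",
    x$link, if (x$link == "logit") "Polya-Gamma augmented Gibbs" else
      "probit threshold-model Gibbs"
  ))
  if (!is.null(x$k)) {
    cat(sprintf("  k-scaled approximation of the logit fit (k = %g)\n", x$k))
  }
  cat(sprintf(
    "  n = %d observations, %d categories, p = %d coefficient(s)%s\n",
    length(x$y), x$C, ncol(x$X),
    if (length(x$samples$b)) sprintf(", %d polygenic line(s)", ncol(x$samples$b))
    else ""
  ))
  cat(sprintf("  %d stored draws (%d sweeps, %d burn-in)%s\n",
              kept, x$chain$n_iter, x$chain$burn_in,
              if (isTRUE(x$used_woodbury)) ", n-dimensional ridge draw" else ""))
  print(tidy(x), n = 12)
  invisible(x)
}

#' Posterior summaries of a fitted ordinal model
#'
#' One row per model term (coefficients, thresholds, variance components)
#' with posterior mean, SD and an equal-tailed credible interval.
#'
#' @param x a `blor_fit`.
#' @param conf.level credible level of the equal-tailed interval.
#' @param ... unused.
#' @return a tibble with columns `term`, `type`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.blor_fit <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  block <- function(mat, type) {
    tibble::tibble(
      term = colnames(mat), type = type,
      estimate = unname(colMeans(mat)),
      std.error = apply(mat, 2, sd),
      conf.low = apply(mat, 2, quantile, probs = a),
      conf.high = apply(mat, 2, quantile, probs = 1 - a)
    )
  }
  out <- dplyr::bind_rows(
    block(x$samples$beta, "coefficient"),
    block(x$samples$gamma, "threshold")
  )
  if (!x$prior$fix_sigma_beta && !x$prior$improper_beta) {
    m <- matrix(x$samples$sigma2_beta, dimnames = list(NULL, "sigma2_beta"))
    out <- dplyr::bind_rows(out, block(m, "variance"))
  }
  if (length(x$samples$sigma2_b)) {
    m <- matrix(x$samples$sigma2_b, dimnames = list(NULL, "sigma2_b"))
    out <- dplyr::bind_rows(out, block(m, "variance"))
  }
  out
}

#' Fit-level summary of a Bayesian ordinal model
#'
#' @param x a `blor_fit`.
#' @param ... unused.
#' @return a one-row tibble: observations, categories, stored draws, link,
#'   DIC, and the halved training Brier score.
#' @export
glance.blor_fit <- function(x, ...) {
  pe <- point_estimates(x)
  eta <- drop(x$X %*% pe$beta)
  if (!is.null(pe$b)) eta <- eta + pe$b[x$line]
  pr <- category_probabilities(eta, pe$gamma, prob_link(x))
  tibble::tibble(
    nobs = length(x$y), n_categories = x$C,
    n_draws = nrow(x$samples$beta), link = x$link,
    dic = dic(x), brier = brier_score(pr, x$y)
  )
}

# Link used for probability computations: a k-scaled probit fit predicts
# through the logistic CDF.
prob_link <- function(fit) if (!is.null(fit$k)) "logit" else fit$link

#' Predicted category probabilities
#'
#' Computes per-category probabilities `pi_c = F(gamma_c - eta) -
#' F(gamma_{c-1} - eta)` for each observation, by default from the posterior
#' means of the parameters (so k-scaled approximations are handled
#' identically); `average_draws = TRUE` instead averages the probabilities
#' over the stored posterior draws.
#'
#' @param object a `blor_fit`.
#' @param newdata optional data frame with the model covariates (and line
#'   column when a polygenic term was fitted; unknown lines get a zero
#'   polygenic effect). Defaults to the training data.
#' @param average_draws average probabilities over posterior draws rather
#'   than plugging in posterior means.
#' @param ... unused.
#' @return a tibble with `C` columns `.pred_1` .. `.pred_C`, one row per
#'   observation; rows sum to one.
#' @export
predict.blor_fit <- function(object, newdata = NULL, average_draws = FALSE,
                             ...) {
  Xb <- newdata_design(object, newdata)
  link <- prob_link(object)
  if (!average_draws) {
    pe <- point_estimates(object)
    eta <- drop(Xb$X %*% pe$beta)
    if (!is.null(pe$b) && !is.null(Xb$line)) {
      eta <- eta + ifelse(is.na(Xb$line), 0, pe$b[Xb$line])
    }
    pr <- category_probabilities(eta, pe$gamma, link)
  } else {
    pr <- posterior_prob_array(object, Xb, link)$mean
  }
  colnames(pr) <- paste0(".pred_", seq_len(object$C))
  tibble::as_tibble(pr)
}

# Resolve the design (and line indices) for predict()/posterior probability
# functions; NULL newdata means the training design.
newdata_design <- function(fit, newdata) {
  if (is.null(newdata)) {
    return(list(X = fit$X, line = fit$line))
  }
  if (is.matrix(newdata)) {
    return(list(X = newdata, line = NULL))
  }
  if (is.null(fit$formula)) {
    abort("`newdata` as a data frame requires a model fitted via blor(data, formula).")
  }
  tt <- delete.response(terms(fit$formula))
  mf <- model.frame(tt, as.data.frame(newdata))
  mm <- model.matrix(tt, mf)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  list(X = mm, line = NULL)
}

#' Trace and density plots of the stored draws
#'
#' @param object a `blor_fit`.
#' @param pars which parameter blocks to show.
#' @param type `"trace"` or `"density"`.
#' @param ... unused.
#' @return a ggplot object, faceted by parameter.
#' @export
autoplot.blor_fit <- function(object,
                              pars = c("coefficient", "threshold", "variance"),
                              type = c("trace", "density"), ...) {
  type <- match.arg(type)
  pars <- match.arg(pars, several.ok = TRUE)
  long <- draws_long(object)
  long <- dplyr::filter(long, .data$type %in% pars)
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$.iteration, y = .data$value)) +
      ggplot2::geom_line(linewidth = 0.2, colour = "steelblue") +
      ggplot2::facet_wrap(~term, scales = "free_y") +
      ggplot2::labs(x = "stored sweep", y = NULL)
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
      ggplot2::facet_wrap(~term, scales = "free") +
      ggplot2::labs(x = NULL, y = "posterior density")
  }
}

draws_long <- function(fit) {
  blocks <- list(
    tibble::as_tibble(fit$samples$beta) |>
      dplyr::mutate(.iteration = dplyr::row_number()) |>
      tidyr::pivot_longer(-".iteration", names_to = "term") |>
      dplyr::mutate(type = "coefficient"),
    tibble::as_tibble(fit$samples$gamma) |>
      dplyr::mutate(.iteration = dplyr::row_number()) |>
      tidyr::pivot_longer(-".iteration", names_to = "term") |>
      dplyr::mutate(type = "threshold")
  )
  if (!fit$prior$fix_sigma_beta && !fit$prior$improper_beta) {
    blocks <- c(blocks, list(tibble::tibble(
      .iteration = seq_along(fit$samples$sigma2_beta),
      term = "sigma2_beta", value = fit$samples$sigma2_beta,
      type = "variance"
    )))
  }
  if (length(fit$samples$sigma2_b)) {
    blocks <- c(blocks, list(tibble::tibble(
      .iteration = seq_along(fit$samples$sigma2_b),
      term = "sigma2_b", value = fit$samples$sigma2_b, type = "variance"
    )))
  }
  dplyr::bind_rows(blocks)
}

#' Scale probit estimates onto the logit scale
#'
#' The classical approximation `logit(u) ~ k * qnorm(u)` maps probit-link
#' estimates to approximate logit-link estimates by multiplying coefficients
#' and thresholds by `k`; `k = 1.75` minimizes the Kullback-Leibler
#' divergence between the two links (1.702 is the common alternative).
#' Applied to a probit Bayesian fit this produces the BLOR* approximation;
#' applied to a probit maximum-likelihood fit, MLLOR*. Thresholds remain
#' strictly increasing for any `k > 0`.
#'
#' @param object a probit-link `blor_fit` or `clm_fit`, or a numeric vector
#'   of probit-scale parameters.
#' @param k positive scaling constant.
#' @param ... unused.
#' @return an object of the same class with all location parameters (draws
#'   included, for Bayesian fits) multiplied by `k`; predictions from the
#'   returned object use the logistic CDF.
#' @export
scale_probit_to_logit <- function(object, k = 1.75, ...) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0) {
    abort("`k` must be a single positive number.",
          class = "ordpg_invalid_parameter")
  }
  UseMethod("scale_probit_to_logit")
}

#' @export
scale_probit_to_logit.numeric <- function(object, k = 1.75, ...) k * object

#' @export
scale_probit_to_logit.blor_fit <- function(object, k = 1.75, ...) {
  if (object$link != "probit" || !is.null(object$k)) {
    abort("the k-scaling map applies to (unscaled) probit-link fits.",
          class = "ordpg_invalid_parameter")
  }
  object$samples$beta <- k * object$samples$beta
  object$samples$gamma <- k * object$samples$gamma
  if (length(object$samples$b)) object$samples$b <- k * object$samples$b
  object$k <- k
  object
}
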