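#' Category probabilities under a cumulative-link model
#'
#' For linear predictors `eta` and strictly increasing thresholds `gamma`,
#' returns `pi_c = F(gamma_c - eta) - F(gamma_{c-1} - eta)` with `F` the
#' logistic or standard-normal CDF and the sentinels `gamma_0 = -Inf`,
#' `gamma_C = +Inf`. Rows sum to one by construction.
#'
#' @param eta numeric vector of linear predictors `x'beta + b`.
#' @param gamma strictly increasing thresholds (length `C - 1`).
#' @param link `"logit"` or `"probit"`.
#' @return an `n x C` matrix of probabilities.
#' @examples
#' category_probabilities(0, c(-0.8416, -0.2533, 0.2533, 0.8416), "probit")
#' @export
category_probabilities <- function(eta, gamma, link = c("logit", "probit")) {
  link <- match.arg(link)
  if (length(gamma) < 1 || is.unsorted(gamma, strictly = TRUE)) {
    abort("`gamma` must be strictly increasing.",
          class = "ordpg_ordering_violation")
  }
  FF <- if (link == "logit") plogis else pnorm
  cuts <- c(-Inf, gamma, Inf)
  cdf <- vapply(cuts, function(g) FF(g - eta), numeric(length(eta)))
  if (length(eta) == 1) cdf <- matrix(cdf, nrow = 1)
  pr <- cdf[, -1, drop = FALSE] - cdf[, -ncol(cdf), drop = FALSE]
  colnames(pr) <- paste0("category", seq_len(ncol(pr)))
  pr
}

# Per-draw probabilities for a fit: returns the posterior mean matrix and,
# when `level` is given, equal-tailed lower/upper matrices. Computed one
# category at a time to keep memory linear in n.
posterior_prob_array <- function(fit, design, link, level = NULL) {
  beta <- fit$samples$beta
  gamma <- fit$samples$gamma
  S <- nrow(beta)
  eta <- beta %*% t(design$X) # S x n
  if (length(fit$samples$b) && !is.null(design$line)) {
    eta <- eta + fit$samples$b[, design$line, drop = FALSE]
  }
  FF <- if (link == "logit") plogis else pnorm
  n <- ncol(eta)
  C <- fit$C
  mean_m <- matrix(NA_real_, n, C)
  lo_m <- up_m <- if (is.null(level)) NULL else matrix(NA_real_, n, C)
  a <- if (is.null(level)) NULL else (1 - level) / 2
  lower_cdf <- matrix(0, S, n) # F(gamma_0 - eta) = 0
  for (cc in seq_len(C)) {
    upper_cdf <- if (cc == C) matrix(1, S, n) else FF(gamma[, cc] - eta)
    pc <- upper_cdf - lower_cdf
    mean_m[, cc] <- colMeans(pc)
    if (!is.null(level)) {
      qs <- apply(pc, 2, quantile, probs = c(a, 1 - a))
      lo_m[, cc] <- qs[1, ]
      up_m[, cc] <- qs[2, ]
    }
    lower_cdf <- upper_cdf
  }
  list(mean = mean_m, lower = lo_m, upper = up_m)
}

#' Posterior category probabilities with credible sets
#'
#' Computes per-draw category probabilities for every observation, then the
#' per-cell posterior mean and equal-tailed credible bounds. For a k-scaled
#' probit fit (the BLOR* approximation) the scaled draws are pushed through
#' the logistic CDF.
#'
#' @param fit a `blor_fit`.
#' @param newdata optional data frame or design matrix; defaults to the
#'   training data.
#' @param level credible level of the equal-tailed bounds.
#' @return a tibble with columns `.row`, `category`, `estimate`,
#'   `conf.low`, `conf.high`.
#' @seealso [category_probability_summary()] for the per-category average
#'   over observations.
#' @export
posterior_category_probabilities <- function(fit, newdata = NULL,
                                             level = 0.95) {
  stopifnot(inherits(fit, "blor_fit"))
  if (nrow(fit$samples$beta) < 1) abort("no stored draws.")
  design <- newdata_design(fit, newdata)
  arr <- posterior_prob_array(fit, design, prob_link(fit), level = level)
  n <- nrow(arr$mean)
  C <- ncol(arr$mean)
  tibble::tibble(
    .row = rep(seq_len(n), each = C),
    category = rep(seq_len(C), times = n),
    estimate = as.vector(t(arr$mean)),
    conf.low = as.vector(t(arr$lower)),
    conf.high = as.vector(t(arr$upper))
  )
}

#' Average per-category probability estimates
#'
#' Averages the posterior point estimates and credible bounds of
#' [posterior_category_probabilities()] over observations, giving one row
#' per category (the usual compact report for a whole data set).
#'
#' @inheritParams posterior_category_probabilities
#' @return a tibble with columns `category`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
category_probability_summary <- function(fit, newdata = NULL, level = 0.95) {
  posterior_category_probabilities(fit, newdata, level) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      estimate = mean(.data$estimate),
      conf.low = mean(.data$conf.low),
      conf.high = mean(.data$conf.high),
      .groups = "drop"
    )
}

#' Halved Brier score for ordinal predictions
#'
#' The multi-category Brier score `n^-1 sum_i sum_c (pi_ic - d_ic)^2`, with
#' `d_ic = 1` iff observation `i` falls in category `c`, ranges over
#' \[0, 2\]; it is divided by 2 here so the result lies in \[0, 1\]. Lower
#' is better; 0 is a perfect one-hot prediction and 1 a confident
#' prediction of a wrong category.
#'
#' @param prob an `n x C` matrix (or data frame, e.g. the output of
#'   [predict.blor_fit()]) of predicted category probabilities.
#' @param y observed categories in 1..C, aligned with the rows of `prob`.
#' @return a single number in \[0, 1\].
#' @export
brier_score <- function(prob, y) {
  prob <- as.matrix(prob)
  if (nrow(prob) != length(y)) {
    abort("`prob` must have one row per element of `y`.",
          class = "ordpg_alignment_error")
  }
  y <- as.integer(y)
  if (any(y < 1) || any(y > ncol(prob))) {
    abort("`y` contains categories outside the columns of `prob`.",
          class = "ordpg_alignment_error")
  }
  d <- matrix(0, nrow(prob), ncol(prob))
  d[cbind(seq_along(y), y)] <- 1
  mean(rowSums((prob - d)^2)) / 2
}

#' Deviance information criterion of a fitted ordinal model
#'
#' `DIC = 2 * mean_s D(theta_s) - D(theta_bar)` with the deviance
#' `D(theta) = -2 sum_i log pi_{i, y_i}(theta)` of the multinomial ordinal
#' likelihood, and `theta_bar` the posterior mean of (beta, b, gamma)
#' jointly (the classic plug-in form). Lower DIC indicates a better model.
#' Predicted probabilities below `eps` are floored with a warning before
#' taking logs.
#'
#' @param fit a `blor_fit`.
#' @param eps floor for predicted probabilities of observed categories.
#' @return a single number.
#' @export
dic <- function(fit, eps = 1e-12) {
  stopifnot(inherits(fit, "blor_fit"))
  link <- prob_link(fit)
  FF <- if (link == "logit") plogis else pnorm
  beta <- fit$samples$beta
  gamma <- fit$samples$gamma
  eta <- beta %*% t(fit$X) # S x n
  if (length(fit$samples$b)) {
    eta <- eta + fit$samples$b[, fit$line, drop = FALSE]
  }
  y <- fit$y
  gu <- cbind(gamma, Inf)[, y, drop = FALSE]   # S x n upper cutpoints
  gl <- cbind(-Inf, gamma)[, y, drop = FALSE]  # S x n lower cutpoints
  pobs <- FF(gu - eta) - FF(gl - eta)
  n_floored <- sum(pobs < eps)
  if (n_floored > 0) {
    warn(sprintf("floored %d predicted probabilities at %g in the deviance.",
                 n_floored, eps))
    pobs <- pmax(pobs, eps)
  }
  dev_draws <- -2 * rowSums(log(pobs))

  pe <- point_estimates(fit)
  eta_hat <- drop(fit$X %*% pe$beta)
  if (!is.null(pe$b)) eta_hat <- eta_hat + pe$b[fit$line]
  pr_hat <- category_probabilities(eta_hat, pe$gamma, link)
  p_hat <- pmax(pr_hat[cbind(seq_along(y), y)], eps)
  d_hat <- -2 * sum(log(p_hat))
  2 * mean(dev_draws) - d_hat
}

#' Replicated 90/10 cross-validation of prediction accuracy
#'
#' Splits the data into training and validation sets `n_splits` times
#' (by default 10 random 90/10 splits at the observation level, without
#' stratification), refits the model on each training set, predicts the
#' held-out category probabilities from the posterior-mean parameters, and
#' scores them with the halved Brier score.
#'
#' @inheritParams blor
#' @param n_splits number of independent random splits.
#' @param train_frac fraction of observations used for training; must leave
#'   a non-empty test set.
#' @param seed master seed; split `s` uses a sub-seed derived from
#'   (`seed`, `s`), so results are reproducible and independent of
#'   execution order.
#' @param k optional positive constant: fit with the probit link and score
#'   the k-scaled (approximate-logit) predictions instead.
#' @param average_draws predict by averaging probabilities over posterior
#'   draws rather than plugging in posterior means.
#' @return an object of class `blor_cv`: a list with `scores` (tibble of
#'   per-split halved Brier scores) and `summary` (mean, min, max).
#' @export
cross_validate <- function(data, formula, prior = blor_prior(),
                           chain = blor_chain(), n_splits = 10,
                           train_frac = 0.9, seed = 1, k = NULL,
                           average_draws = FALSE) {
  data <- as.data.frame(data)
  n <- nrow(data)
  n_test <- n - floor(train_frac * n)
  if (train_frac <= 0 || train_frac >= 1 || n_test < 1) {
    abort("`train_frac` must leave a non-empty test and training set.",
          class = "ordpg_invalid_parameter")
  }
  mf <- model.frame(formula, data)
  y_all <- as.integer(model.response(mf))
  C <- max(y_all)

  scores <- purrr::map_dbl(seq_len(n_splits), function(s) {
    set.seed(derive_seed(seed, s))
    for (try in 1:100) {
      test_idx <- sample.int(n, n_test)
      if (length(unique(y_all[-test_idx])) == C &&
          max(y_all[-test_idx]) == C) break
      if (try == 100) {
        abort("could not find a training split containing every category.")
      }
    }
    if (length(unique(y_all[test_idx])) < C) {
      warn(sprintf(
        "split %d: test fold does not contain every category; probabilities remain defined via the thresholds.",
        s
      ))
    }
    chain_s <- chain
    chain_s$seed <- derive_seed(seed, n_splits + s)
    if (!is.null(k)) chain_s$link <- "probit"
    fit <- blor(data[-test_idx, , drop = FALSE], formula,
                prior = prior, chain = chain_s)
    if (!is.null(k)) fit <- scale_probit_to_logit(fit, k)
    pr <- predict(fit, newdata = data[test_idx, , drop = FALSE],
                  average_draws = average_draws)
    brier_score(pr, y_all[test_idx])
  })

  structure(
    list(
      scores = tibble::tibble(split = seq_len(n_splits), brier = scores),
      summary = tibble::tibble(
        mean = mean(scores), min = min(scores), max = max(scores)
      ),
      n_splits = n_splits, train_frac = train_frac, seed = seed
    ),
    class = "blor_cv"
  )
}

#' @export
print.blor_cv <- function(x, ...) {
  cat(sprintf(
    "%d-fold random %d%%/%d%% cross-validation (halved Brier score)\n",
    x$n_splits, round(100 * x$train_frac), round(100 * (1 - x$train_frac))
  ))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.blor_cv <- function(x, ...) x$scores

#' @export
glance.blor_cv <- function(x, ...) x$summary
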