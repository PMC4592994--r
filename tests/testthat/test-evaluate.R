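test_that("category probabilities hit the closed forms at zero signal", {
  g <- quintile_gamma
  # the quintile thresholds split the standard normal into exact fifths
  p_probit <- category_probabilities(0, g, "probit")
  expect_equal(as.numeric(p_probit), rep(0.2, 5), tolerance = 1e-4)
  p_logit <- category_probabilities(0, g, "logit")
  expect_equal(as.numeric(p_logit),
               c(0.3012, 0.1358, 0.1260, 0.1358, 0.3012), tolerance = 1e-3)
  # limits: all mass escapes to the end categories
  expect_gt(category_probabilities(50, g, "logit")[1, 5], 1 - 1e-10)
  expect_gt(category_probabilities(-50, g, "probit")[1, 1], 1 - 1e-10)
})

test_that("probability rows always sum to one for both links", {
  set.seed(71)
  for (link in c("logit", "probit")) {
    for (rep in 1:20) {
      C <- sample(2:7, 1)
      gamma <- sort(rnorm(C - 1, sd = 2))
      eta <- rnorm(50, sd = 3)
      pr <- category_probabilities(eta, gamma, link)
      expect_equal(rowSums(pr), rep(1, 50), tolerance = 1e-10)
      expect_true(all(pr >= 0 & pr <= 1))
    }
  }
  expect_error(category_probabilities(0, c(1, 0.5), "logit"),
               class = "ordpg_ordering_violation")
})

test_that("halved Brier score matches hand-computed values and stays in [0, 1]", {
  # perfect one-hot prediction
  y <- c(1, 2, 3)
  one_hot <- diag(3)
  expect_equal(brier_score(one_hot, y), 0)
  # uniform 5-category predictor: (4 * 0.04 + 0.64) / 2 = 0.4 exactly
  expect_equal(brier_score(matrix(0.2, 7, 5), rep(3, 7)), 0.4)
  # confident wrong prediction attains the maximum
  wrong <- one_hot[c(2, 3, 1), ]
  expect_equal(brier_score(wrong, y), 1)
  # fuzz: any probability forecast scores inside [0, 1]
  set.seed(72)
  for (rep in 1:50) {
    n <- sample(5:200, 1); C <- sample(2:6, 1)
    pr <- matrix(rexp(n * C), n, C)
    pr <- pr / rowSums(pr)
    bs <- brier_score(pr, sample.int(C, n, replace = TRUE))
    expect_true(bs >= 0 && bs <= 1)
  }
  expect_error(brier_score(matrix(0.5, 4, 2), c(1, 2)),
               class = "ordpg_alignment_error")
  expect_error(brier_score(matrix(0.5, 2, 2), c(1, 3)),
               class = "ordpg_alignment_error")
})

test_that("posterior category probabilities carry coherent credible sets", {
  df <- make_model_data(n = 100, p = 2, C = 4, seed = 73)
  fit <- blor(df, y ~ x1 + x2, prior = sim_prior(), chain = fast_chain(seed = 1))
  pp95 <- posterior_category_probabilities(fit, level = 0.95)
  pp80 <- posterior_category_probabilities(fit, level = 0.80)
  expect_true(all(pp95$conf.low <= pp95$estimate + 1e-12))
  expect_true(all(pp95$estimate <= pp95$conf.high + 1e-12))
  # nested: the 95% set contains the 80% set cell by cell
  expect_true(all(pp95$conf.low <= pp80$conf.low + 1e-12))
  expect_true(all(pp95$conf.high >= pp80$conf.high - 1e-12))
  # rows sum to one
  tot <- dplyr::summarise(dplyr::group_by(pp95, .row),
                          s = sum(estimate))$s
  expect_equal(tot, rep(1, 100), tolerance = 1e-10)
  # degenerate posterior: bounds collapse onto the point value
  fit1 <- fit
  fit1$samples$beta <- fit$samples$beta[1, , drop = FALSE]
  fit1$samples$gamma <- fit$samples$gamma[1, , drop = FALSE]
  pp1 <- posterior_category_probabilities(fit1)
  expect_equal(pp1$conf.low, pp1$estimate, tolerance = 1e-12)
  expect_equal(pp1$conf.high, pp1$estimate, tolerance = 1e-12)
  # the per-category summary averages over observations
  cs <- category_probability_summary(fit)
  expect_equal(nrow(cs), 4)
  expect_equal(sum(cs$estimate), 1, tolerance = 1e-10)
})

test_that("the k-scaled probit map approximates logistic probabilities within 0.05", {
  g <- quintile_gamma
  for (eta in seq(-2, 2, by = 0.25)) {
    exact <- category_probabilities(eta, g, "probit")
    approx <- category_probabilities(1.75 * eta, 1.75 * g, "logit")
    expect_lt(max(abs(exact - approx)), 0.05)
  }
})

test_that("DIC is deterministic and collapses to the plug-in deviance for a point mass", {
  df <- make_model_data(n = 120, p = 2, C = 4, seed = 74)
  fit <- blor(df, y ~ x1 + x2, prior = sim_prior(), chain = fast_chain(seed = 2))
  expect_identical(dic(fit), dic(fit))
  # replicate one draw: posterior mass on a single point, pD -> 0
  fit_pt <- fit
  fit_pt$samples$beta <- fit$samples$beta[rep(5, 40), , drop = FALSE]
  fit_pt$samples$gamma <- fit$samples$gamma[rep(5, 40), , drop = FALSE]
  pe <- coef(fit_pt)
  pr <- category_probabilities(drop(fit$X %*% pe$beta), pe$gamma, "logit")
  d_hat <- -2 * sum(log(pr[cbind(seq_along(fit$y), fit$y)]))
  expect_equal(dic(fit_pt), d_hat, tolerance = 1e-8)
  # a logit fit evaluated as BLOR* uses the logistic CDF on scaled draws
  fitp <- blor(df, y ~ x1 + x2, prior = sim_prior(),
               chain = fast_chain(link = "probit", seed = 2))
  star <- scale_probit_to_logit(fitp, 1.75)
  expect_false(isTRUE(all.equal(dic(fitp), dic(star))))
})

test_that("cross-validation reports mean/min/max over reproducible splits", {
  df <- make_model_data(n = 150, p = 2, C = 3, seed = 75)
  cv1 <- cross_validate(df, y ~ x1 + x2, prior = sim_prior(),
                        chain = fast_chain(), n_splits = 4, seed = 42)
  cv2 <- cross_validate(df, y ~ x1 + x2, prior = sim_prior(),
                        chain = fast_chain(), n_splits = 4, seed = 42)
  expect_identical(cv1$scores, cv2$scores)
  expect_named(cv1$summary, c("mean", "min", "max"))
  expect_equal(nrow(cv1$scores), 4)
  expect_true(all(cv1$scores$brier >= 0 & cv1$scores$brier <= 1))
  expect_equal(cv1$summary$mean, mean(cv1$scores$brier))
  expect_lte(cv1$summary$min, cv1$summary$max)
  expect_error(cross_validate(df, y ~ x1 + x2, train_frac = 1),
               class = "ordpg_invalid_parameter")
  expect_identical(glance(cv1), cv1$summary)
})
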