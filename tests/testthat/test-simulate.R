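test_that("study-1 replicates have the declared shape and partition", {
  spec <- sim_spec(study = 1, n_i = 5, seed = 9)
  d <- simulate_ordinal(spec, rep = 1)
  expect_equal(nrow(d), 200)
  expect_setequal(unique(d$line), 1:40)
  expect_true(all(d$y %in% 1:5))
  expect_true(all(abs(d[, c("x1", "x2", "x3")]) <= 0.1))
  # exhaustive & exclusive partition: y is exactly the interval of liability
  cuts <- c(-Inf, spec$gamma_true, Inf)
  expect_identical(d$y, as.integer(cut(d$liability, cuts)))
  # covariates constant within line
  per_line <- dplyr::n_distinct(dplyr::distinct(d, line, x1, x2, x3)$line)
  expect_equal(per_line, 40)
})

test_that("replicates are reproducible and independent across indices", {
  spec <- sim_spec(study = 1, n_i = 10, seed = 30)
  expect_identical(simulate_ordinal(spec, 3), simulate_ordinal(spec, 3))
  expect_false(identical(simulate_ordinal(spec, 3)$liability,
                         simulate_ordinal(spec, 4)$liability))
  # per-replicate covariate redraw vs the shared-design mode
  expect_false(identical(simulate_ordinal(spec, 1)$x1[1],
                         simulate_ordinal(spec, 2)$x1[1]))
  shared <- sim_spec(study = 1, n_i = 10, seed = 30, shared_x = TRUE)
  d1 <- simulate_ordinal(shared, 1)
  d2 <- simulate_ordinal(shared, 2)
  expect_equal(dplyr::distinct(d1, line, x1, x2, x3),
               dplyr::distinct(d2, line, x1, x2, x3), ignore_attr = TRUE)
  expect_false(identical(d1$y, d2$y))
})

test_that("category frequencies at zero signal match logistic CDF differences", {
  spec <- sim_spec(study = 1, n_i = 25000, seed = 10, beta_true = c(0, 0, 0))
  d <- simulate_ordinal(spec, rep = 1)
  freq <- as.numeric(table(factor(d$y, levels = 1:5))) / nrow(d)
  target <- diff(plogis(c(-Inf, spec$gamma_true, Inf)))
  expect_equal(freq, target, tolerance = 0.015)
})

test_that("study-2 contamination touches exactly the prescribed share of residuals", {
  clean <- simulate_ordinal(sim_spec(study = 2, n_i = 40, po = 0, seed = 5), 1)
  dirty <- simulate_ordinal(sim_spec(study = 2, n_i = 40, po = 30, seed = 5), 1)
  # same seed: the logistic residuals coincide, only the contaminated
  # subset is replaced by t4 draws
  expect_equal(sum(clean$liability != dirty$liability), round(0.30 * 1600))
  # po = 0 study 2 is study 1 at n_i = 40
  s1 <- simulate_ordinal(sim_spec(study = 1, n_i = 40, seed = 5), 1)
  expect_identical(clean, s1, ignore_attr = TRUE)
})

test_that("full t4 contamination produces heavier extreme tails than the logistic", {
  # the polynomial t4 tail overtakes the exponential logistic tail only far
  # out (P(|t4| > 8) = 2.6e-3 vs P(|L| > 8) = 1.3e-3), so the exceedance
  # check sits at +/- 8
  spec_t <- sim_spec(study = 2, n_i = 40, po = 100, seed = 6,
                     beta_true = c(0, 0, 0))
  spec_l <- sim_spec(study = 2, n_i = 40, po = 0, seed = 6,
                     beta_true = c(0, 0, 0))
  exceed <- function(spec) {
    mean(purrr::map_dbl(1:100, function(r) {
      mean(abs(simulate_ordinal(spec, r)$liability) > 8)
    }))
  }
  expect_gt(exceed(spec_t), exceed(spec_l))
})

test_that("simulation specs validate their invariants", {
  expect_error(sim_spec(study = 1, po = 10), class = "ordpg_invalid_parameter")
  expect_error(sim_spec(study = 2, n_i = 5), class = "ordpg_invalid_parameter")
  expect_error(sim_spec(study = 2, n_i = 40, po = 130),
               class = "ordpg_invalid_parameter")
  expect_error(sim_spec(gamma_true = c(0.5, -0.5, 1, 2)),
               class = "ordpg_ordering_violation")
  expect_error(sim_spec(study = 3))
})

test_that("a smoke replication study has the seven-parameter-by-method layout", {
  spec <- sim_spec(study = 1, n_i = 5, n_reps = 2, seed = 60)
  summ <- run_replication_study(
    spec, methods = c("BLOR", "MLLOR", "MLLOR*"),
    chain = fast_chain(300, 100)
  )
  expect_s3_class(summ, "tbl_df")
  expect_equal(nrow(summ), 7 * 3) # beta1..3, gamma1..4 per method
  expect_setequal(as.character(unique(summ$parameter)),
                  c(paste0("beta", 1:3), paste0("gamma", 1:4)))
  expect_equal(unique(summ$n_used), 2)
  expect_true(all(summ$sd >= 0))
  expect_equal(summ$true_value[summ$parameter == "beta2" &
                                 summ$method == "BLOR"], -5)
  # MLLOR* is exactly 1.75 x the probit MLE, replicate by replicate
  est <- attr(summ, "estimates")
  d1 <- simulate_ordinal(spec, 1)
  probit <- fit_cumulative_link(d1, y ~ x1 + x2 + x3, link = "probit")
  star1 <- est[est$method == "MLLOR*" & est$rep == 1, ]
  expect_equal(star1$estimate, unname(1.75 * c(probit$beta, probit$gamma)),
               tolerance = 1e-8)
})

test_that("a single-replicate study flags the undefined SD", {
  spec <- sim_spec(study = 1, n_i = 5, n_reps = 1, seed = 61)
  summ <- run_replication_study(spec, methods = "MLLOR")
  expect_true(all(is.na(summ$sd)))
  est <- attr(summ, "estimates")
  expect_equal(summ$mean, est$estimate[match(summ$parameter, est$parameter)])
})

test_that("replication summaries are identical across runs (seed-derived order invariance)", {
  spec <- sim_spec(study = 1, n_i = 5, n_reps = 2, seed = 62)
  s1 <- run_replication_study(spec, methods = "MLLOR")
  s2 <- run_replication_study(spec, methods = "MLLOR")
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})
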