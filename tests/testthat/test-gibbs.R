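test_that("frozen-conditional coefficient draws match the conjugate closed form", {
  set.seed(21)
  n <- 30; p <- 2
  X <- matrix(runif(n * p, -1, 1), n, p)
  omega <- rexp(n) + 0.1
  l <- rnorm(n)
  beta0 <- c(0.5, -0.5)
  Sigma0inv <- solve(matrix(c(2, 0.3, 0.3, 1), 2))
  s2b <- 0.8
  ndraws <- 1e4
  draws <- ordpg:::cpp_beta_draws(ndraws, X, omega, l, beta0, Sigma0inv,
                                  s2b, FALSE, NA_real_, FALSE)
  P <- Sigma0inv / s2b + crossprod(X, X * omega)
  V <- solve(P)
  mu <- drop(V %*% (Sigma0inv %*% beta0 / s2b + crossprod(X, omega * l)))
  for (j in 1:p) {
    expect_lt(abs(mean(draws[, j]) - mu[j]), 3 * sqrt(V[j, j] / ndraws))
    expect_lt(abs(var(draws[, j]) - V[j, j]),
              3 * V[j, j] * sqrt(2 / (ndraws - 1)))
  }
})

test_that("improper-prior conditional mean reduces to weighted least squares", {
  set.seed(22)
  n <- 50; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  l <- rnorm(n)
  ndraws <- 2e4
  # omega = 1, flat prior: posterior mean is OLS of l on X
  draws <- ordpg:::cpp_beta_draws(ndraws, X, rep(1, n), l, rep(0, p),
                                  diag(p), 1, TRUE, NA_real_, FALSE)
  ols <- drop(solve(crossprod(X), crossprod(X, l)))
  V <- solve(crossprod(X))
  for (j in 1:p) {
    expect_lt(abs(mean(draws[, j]) - ols[j]), 3 * sqrt(V[j, j] / ndraws))
  }
})

test_that("n-dimensional ridge draw matches the direct p x p draw in two moments", {
  set.seed(23)
  n <- 20; p <- 60 # p > 2n triggers the auto switch in full fits
  X <- matrix(rnorm(n * p), n, p)
  omega <- rexp(n) + 0.2
  l <- rnorm(n)
  ndraws <- 8e3
  direct <- ordpg:::cpp_beta_draws(ndraws, X, omega, l, rep(0, p), diag(p),
                                   1, FALSE, 1, FALSE)
  wood <- ordpg:::cpp_beta_draws(ndraws, X, omega, l, rep(0, p), diag(p),
                                 1, FALSE, 1, TRUE)
  V <- solve(diag(p) + crossprod(X, X * omega))
  mu <- drop(V %*% crossprod(X, omega * l))
  se <- sqrt(diag(V) / ndraws)
  expect_true(all(abs(colMeans(direct) - mu) < 4 * se))
  expect_true(all(abs(colMeans(wood) - mu) < 4 * se))
  sd_ratio <- apply(direct, 2, sd) / apply(wood, 2, sd)
  expect_true(all(abs(sd_ratio - 1) < 0.15))
})

test_that("a p >> n marker fit runs through the ridge path end to end", {
  set.seed(24)
  I <- 30; p <- 80
  M <- matrix(rbinom(I * p, 2, 0.4) - 1, I, p) # centered-ish marker codes
  M <- scale(M, center = TRUE, scale = FALSE)
  keep <- apply(M, 2, function(col) diff(range(col)) > 0)
  M <- M[, keep]
  beta <- rnorm(ncol(M), 0, 0.15)
  y <- as.integer(cut(drop(M %*% beta) + rlogis(I),
                      c(-Inf, -0.5, 0.5, Inf)))
  while (length(unique(y)) < 3) {
    y <- as.integer(cut(drop(M %*% beta) + rlogis(I), c(-Inf, -0.5, 0.5, Inf)))
  }
  fit <- blor_matrix(y, M, prior = blor_prior(sigma0 = 1),
                     chain = fast_chain(seed = 5))
  expect_true(fit$used_woodbury)
  expect_equal(ncol(fit$samples$beta), ncol(M))
  pr <- predict(fit)
  expect_equal(rowSums(as.matrix(pr)), rep(1, I), tolerance = 1e-10)
})

test_that("pinned-omega logit chain reproduces the probit chain draw for draw", {
  df <- make_model_data(n = 100, p = 2, C = 4, seed = 31)
  ch_logit <- fast_chain(link = "logit", seed = 99, pin_omega = TRUE)
  ch_probit <- fast_chain(link = "probit", seed = 99)
  f1 <- blor(df, y ~ x1 + x2, prior = sim_prior(), chain = ch_logit)
  f2 <- blor(df, y ~ x1 + x2, prior = sim_prior(), chain = ch_probit)
  expect_identical(f1$samples$beta, f2$samples$beta)
  expect_identical(f1$samples$gamma, f2$samples$gamma)
})

test_that("thresholds stay ordered and liabilities stay in their category interval", {
  df <- make_model_data(n = 150, p = 2, C = 5, seed = 32)
  fit <- blor(df, y ~ x1 + x2, prior = sim_prior(),
              chain = fast_chain(600, 200, seed = 8, store_liabilities = TRUE))
  g <- fit$samples$gamma
  expect_true(all(g[, -1] - g[, -ncol(g)] > 0)) # strict monotonicity, all sweeps
  expect_true(all(g > fit$prior$gamma_min & g < fit$prior$gamma_max))
  l <- fit$samples$liabilities
  y <- fit$y
  lower <- cbind(-Inf, g)[, y, drop = FALSE]
  upper <- cbind(g, Inf)[, y, drop = FALSE]
  expect_true(all(l > lower & l < upper))
})

test_that("chains are exactly reproducible under a shared seed", {
  df <- make_model_data(n = 80, p = 2, C = 3, seed = 33)
  f1 <- blor(df, y ~ x1 + x2, prior = sim_prior(), chain = fast_chain(seed = 4))
  f2 <- blor(df, y ~ x1 + x2, prior = sim_prior(), chain = fast_chain(seed = 4))
  expect_identical(f1$samples, f2$samples)
})

test_that("polygenic effects are sampled only when requested and G validates", {
  set.seed(34)
  I <- 15; n_i <- 6
  line <- rep(seq_len(I), each = n_i)
  u <- rnorm(I, 0, 1)
  X <- matrix(runif(I * n_i * 2, -1, 1), I * n_i, 2)
  y <- as.integer(cut(drop(X %*% c(1, -1)) + u[line] + rlogis(I * n_i),
                      c(-Inf, -0.8, 0.8, Inf)))
  while (length(unique(y)) < 3) {
    y <- as.integer(cut(drop(X %*% c(1, -1)) + u[line] + rlogis(I * n_i),
                        c(-Inf, -0.8, 0.8, Inf)))
  }
  # no polygenic term requested: no b draws stored
  f0 <- blor_matrix(y, X, prior = sim_prior(), chain = fast_chain(seed = 2))
  expect_length(f0$samples$b, 0)
  expect_length(f0$samples$sigma2_b, 0)
  # with G = I: b and sigma2_b sampled, finite, sigma2_b > 0
  fG <- blor_matrix(y, X, line = line, G = diag(I), prior = sim_prior(),
                    chain = fast_chain(seed = 2))
  expect_equal(ncol(fG$samples$b), I)
  expect_true(all(is.finite(fG$samples$b)))
  expect_true(all(fG$samples$sigma2_b > 0))
  expect_true("sigma2_b" %in% tidy(fG)$term)
})

test_that("an overwhelming polygenic prior shrinks b to zero", {
  set.seed(35)
  I <- 10
  line <- rep(seq_len(I), each = 5)
  X <- matrix(runif(50 * 2, -1, 1), 50, 2)
  y <- as.integer(cut(rlogis(50), c(-Inf, -0.5, 0.5, Inf)))
  while (length(unique(y)) < 3) {
    y <- as.integer(cut(rlogis(50), c(-Inf, -0.5, 0.5, Inf)))
  }
  # sigma_b^2 pinned near zero by an enormous prior df: b ~ 0
  pr <- blor_prior(nu_b = 1e8, S_b = 1e-8, fix_sigma_beta = TRUE,
                   gamma_min = -4, gamma_max = 4)
  f <- blor_matrix(y, X, line = line, G = diag(I), prior = pr,
                   chain = fast_chain(seed = 3))
  expect_lt(max(abs(colMeans(f$samples$b))), 0.01)
})
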