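# Small fixtures generated in code; no stored data.

# Ordinal data drawn from the cumulative-link model itself.
make_model_data <- function(n = 120, p = 2, C = 4, beta = NULL,
                            gamma = NULL, link = "logit", seed = 1) {
  set.seed(seed)
  if (is.null(beta)) beta <- seq(-1, 1, length.out = p) * 2
  if (is.null(gamma)) gamma <- qnorm(seq_len(C - 1) / C)
  X <- matrix(runif(n * p, -1, 1), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  eps <- if (link == "logit") rlogis(n) else rnorm(n)
  l <- drop(X %*% beta) + eps
  y <- as.integer(cut(l, c(-Inf, gamma, Inf)))
  # retry until every category occurs (tiny n can miss one)
  while (length(unique(y)) < C) {
    eps <- if (link == "logit") rlogis(n) else rnorm(n)
    l <- drop(X %*% beta) + eps
    y <- as.integer(cut(l, c(-Inf, gamma, Inf)))
  }
  df <- data.frame(y = y, X)
  attr(df, "beta") <- beta
  attr(df, "gamma") <- gamma
  df
}

quintile_gamma <- c(-0.8416, -0.2533, 0.2533, 0.8416)

fast_chain <- function(n_iter = 400, burn_in = 100, ...) {
  blor_chain(n_iter = n_iter, burn_in = burn_in, ...)
}
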