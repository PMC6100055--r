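# Independent oracles and small fixture builders shared across test files.

# Observed-data log-likelihood computed the slow way: one dense marginal
# normal density per row, via solve()/determinant().  Deliberately shares no
# code with the package's grouped, Cholesky-based evaluation.
dense_loglik_oracle <- function(m, mu, sigma) {
  ll <- 0
  for (i in seq_len(nrow(m))) {
    o <- which(!is.na(m[i, ]))
    S <- sigma[o, o, drop = FALSE]
    y <- m[i, o] - mu[o]
    ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
    ll <- ll - 0.5 * (length(o) * log(2 * pi) + ld + drop(y %*% solve(S, y)))
  }
  ll
}

# Conditional mean of the missing block of one row, dense formula.
dense_cond_mean_oracle <- function(y, mu, sigma) {
  o <- which(!is.na(y))
  mis <- setdiff(seq_along(y), o)
  mu[mis] + sigma[mis, o, drop = FALSE] %*%
    solve(sigma[o, o, drop = FALSE], y[o] - mu[o])
}

# Random well-conditioned covariance matrix.
rand_cov <- function(p) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(0.5, p)
}

# Small random incomplete dataset satisfying the fitting preconditions.
rand_incomplete <- function(n, p, rate = 0.25, seed) {
  sim <- simulate_mvn_missing(
    mvn_missing_spec(n, p, mu_true = rnorm(p, sd = 2),
                     sigma_true = rand_cov(p),
                     complete_fraction = 0.3,
                     cell_missing_rate = rate),
    seed = seed)
  sim
}

# Tiny raw-space CSV of the five endpoint descriptors.
endpoint_schema <- function() {
  solvent_schema(c("oral_ld50", "inhalation_lc50", "fish_lc50",
                   "bod_half_life", "log_bcf"))
}

write_endpoint_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}
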