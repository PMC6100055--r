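test_that("pattern_groups partitions rows by observed-column set", {
  # all observed -> one group
  m <- matrix(rnorm(12), 4, 3)
  g <- pattern_groups(m)
  expect_length(g, 1L)
  expect_equal(g[[1]]$n, 4L)
  expect_equal(g[[1]]$obs, 1:3)

  # exhaustive small case: {1,2},{1,2},{1},{2} -> G = 3, sizes 2,1,1
  m2 <- rbind(c(1, 2), c(3, 4), c(5, NA), c(NA, 6))
  g2 <- pattern_groups(m2)
  expect_length(g2, 3L)
  # lexicographic order of observed sets: {1} < {1,2} < {2}
  expect_equal(vapply(g2, `[[`, 0L, "n"), c(1L, 2L, 1L),
               ignore_attr = TRUE)
  expect_equal(lapply(g2, `[[`, "obs"), list(1L, 1:2, 2L),
               ignore_attr = TRUE)
  # groups partition the rows
  expect_setequal(unlist(lapply(g2, `[[`, "rows")), 1:4)

  expect_error(pattern_groups(rbind(c(1, 2), c(NA, NA))), "no observed")
})

test_that("study-shaped draws have a complete-pattern group of 85 rows", {
  sim <- simulate_mvn_missing(study_shaped_spec(), seed = 11)
  g <- pattern_groups(sim$data)
  full <- Filter(function(x) length(x$obs) == 13L, g)
  expect_length(full, 1L)
  expect_gte(full[[1]]$n, 85L)  # 85 guaranteed + chance undeleted rows
})

test_that("initialization uses available-case moments with zero correlations", {
  m <- rbind(c(0, 5), c(2, 6), c(NA, 7))
  init <- em_init(m)
  expect_equal(unname(init$mu), c(1, 6))
  expect_equal(unname(diag(init$sigma)), c(2, 1))  # n-1 denominators
  expect_equal(init$sigma[1, 2], 0)
  # complete matrix: means are plain column means
  mc <- matrix(rnorm(30), 10, 3)
  expect_equal(unname(em_init(mc)$mu), unname(colMeans(mc)))
  expect_true(all(em_init(mc)$sigma[upper.tri(diag(3))] == 0))
  expect_error(em_init(rbind(c(1, 2), c(NA, 3))), "fewer than 2")
})

test_that("observed-data log-likelihood matches the dense per-row oracle", {
  # standardized univariate density at its mode
  expect_equal(mvn_loglik(matrix(0.7), mu = 0.7, sigma = matrix(1)),
               -0.5 * log(2 * pi))
  set.seed(101)
  for (k in 1:20) {
    p <- sample(2:3, 1)
    n <- sample(5:20, 1)
    sim <- rand_incomplete(n, p, rate = 0.35, seed = 1000 + k)
    mu <- rnorm(p)
    sigma <- rand_cov(p)
    expect_equal(mvn_loglik(sim$data, mu, sigma),
                 dense_loglik_oracle(sim$data, mu, sigma),
                 tolerance = 1e-8)
  }
  # additivity: duplicating every row doubles the log-likelihood
  sim <- rand_incomplete(8, 3, seed = 77)
  mu <- rnorm(3); sigma <- rand_cov(3)
  m2 <- rbind(sim$data, sim$data)
  rownames(m2) <- NULL
  expect_equal(mvn_loglik(m2, mu, sigma),
               2 * mvn_loglik(sim$data, mu, sigma), tolerance = 1e-10)
})

test_that("E-step reduces to raw sums on complete data", {
  set.seed(5)
  m <- matrix(rnorm(40), 10, 4)
  st <- em_estep(m, rnorm(4), rand_cov(4))
  expect_equal(unname(st$T1), unname(colSums(m)))
  expect_equal(unname(st$T2), unname(crossprod(m)))
  expect_equal(st$n, 10L)
})

test_that("E-step matches the bivariate conditional normal closed form", {
  for (rho in c(-0.8, 0, 0.5, 0.95)) {
    sigma <- matrix(c(1, rho, rho, 1), 2)
    x1 <- 1.3
    st <- em_estep(matrix(c(x1, NA), 1, 2), mu = c(0, 0), sigma = sigma)
    expect_equal(unname(st$T1), c(x1, rho * x1), tolerance = 1e-12)
    expect_equal(st$T2[2, 2], (rho * x1)^2 + (1 - rho^2), tolerance = 1e-12)
    expect_equal(st$T2[1, 2], x1 * rho * x1, tolerance = 1e-12)
  }
})

test_that("M-step returns the complete-data MLE", {
  set.seed(6)
  m <- matrix(rnorm(60), 20, 3)
  up <- em_mstep(list(T1 = colSums(m), T2 = crossprod(m), n = 20L))
  expect_equal(unname(up$mu), unname(colMeans(m)))
  expect_equal(unname(up$sigma), unname(cov(m) * 19 / 20), tolerance = 1e-12)
  # two 1-D points {0, 2}: mu = 1, sigma = 1 (n denominator)
  up1 <- em_mstep(list(T1 = 2, T2 = matrix(4), n = 2L))
  expect_equal(up1$mu, 1)
  expect_equal(up1$sigma, matrix(1))
  # n identical rows: point mass, zero covariance
  xi <- c(1, -2)
  upd <- em_mstep(list(T1 = 5 * xi, T2 = 5 * tcrossprod(xi), n = 5L))
  expect_equal(unname(upd$mu), xi)
  expect_equal(max(abs(upd$sigma)), 0, tolerance = 1e-12)
})

test_that("EM on complete data stops at the closed-form MLE immediately", {
  set.seed(9)
  m <- matrix(rnorm(100), 25, 4)
  fit <- em_mvn(m)
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 2L)  # first convergence check
  expect_equal(unname(fit$mu), unname(colMeans(m)), tolerance = 1e-8)
  expect_equal(unname(fit$sigma), unname(cov(m) * 24 / 25), tolerance = 1e-8)
})

test_that("log-likelihood trace is monotone and the fit is self-consistent", {
  sim <- rand_incomplete(60, 4, rate = 0.3, seed = 21)
  fit <- em_mvn(sim$data)
  expect_true(fit$converged)
  d <- diff(fit$loglik)
  expect_true(all(d >= -1e-8 * pmax(1, abs(fit$loglik[-1]))))
  # one extra EM cycle barely moves the means
  st <- em_estep(sim$data, fit$mu, fit$sigma)
  up <- em_mstep(st)
  expect_lt(max(abs(up$mu - fit$mu)), 10 * fit$tol)
})

test_that("fits are invariant to row permutation and equivariant to column permutation", {
  sim <- rand_incomplete(50, 3, seed = 31)
  m <- sim$data
  fit <- em_mvn(m)
  pr <- sample(nrow(m))
  mr <- m[pr, ]; rownames(mr) <- NULL
  fit_r <- em_mvn(mr)
  expect_equal(fit_r$mu, fit$mu, tolerance = 1e-6)
  expect_equal(fit_r$sigma, fit$sigma, tolerance = 1e-6)
  pc <- c(3, 1, 2)
  fit_c <- em_mvn(m[, pc])
  expect_equal(unname(fit_c$mu), unname(fit$mu[pc]), tolerance = 1e-6)
  expect_equal(unname(fit_c$sigma), unname(fit$sigma[pc, pc]),
               tolerance = 1e-6)
})

test_that("singular observed blocks fail loudly unless ridged", {
  set.seed(41)
  base <- rnorm(30)
  m <- cbind(base, base, rnorm(30))  # two identical columns
  expect_error(em_mvn(m), "near-singular")
  expect_error(mvn_loglik(m, colMeans(m), cov(m) * 29 / 30), "near-singular")
  fit <- suppressWarnings(em_mvn(m, ridge = TRUE))
  expect_s3_class(fit, "em_mvn")
  expect_true(all(is.finite(fit$mu)))
})

test_that("em_mvn accepts a model-space prop_table and refuses a raw one", {
  sch <- endpoint_schema()
  set.seed(51)
  vals <- matrix(exp(rnorm(50)), 10, 5, dimnames = list(NULL, sch$name))
  vals[cbind(c(2, 5, 9), c(1, 3, 4))] <- NA
  pt <- prop_table(vals, sch, space = "raw")
  expect_error(em_mvn(pt), "raw space")
  fit <- em_mvn(to_model_space(pt), tol = 1e-6)
  expect_true(fit$converged)
  expect_identical(fit$schema$name, sch$name)
})

test_that("em_mvn methods expose the fit in the usual R idioms", {
  sim <- rand_incomplete(40, 3, seed = 61)
  fit <- em_mvn(sim$data)
  expect_equal(coef(fit), fit$mu)
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "df"), 3 + 6)
  expect_output(print(fit), "Converged")
  expect_output(print(summary(fit)), "n_missing|log-likelihood")
  r <- residuals(fit, type = "pearson")
  expect_equal(dim(r), dim(sim$data))
  expect_true(all(is.na(r) == is.na(sim$data)))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]), dim(sim$data))
  # same seed -> identical draws
  expect_identical(sims, simulate(fit, nsim = 2, seed = 1))
})
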