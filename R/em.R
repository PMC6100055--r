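# EM core: observed-data likelihood over missingness-pattern groups,
# E-step by partitioned (Schur-complement) conditional-normal formulas,
# M-step = complete-data MLE of (mu, Sigma).

# Coerce input to a numeric matrix with NA = missing.  prop_table input must
# already be in model space so that the normal model is fitted on the scale
# the log transforms define.
.as_model_matrix <- function(x) {
  if (inherits(x, "prop_table")) {
    if (x$space != "model")
      stop("table is in raw space; call to_model_space() first")
    return(as.matrix(x))
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix, data frame or prop_table")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

# Cholesky factorization of the observed block Sigma[o,o], computed on the
# correlation-scaled matrix so that the conditioning check is invariant to
# the (very different) units of the variables.  Returns the scale d, the
# upper-triangular factor R of the scaled block, and log det Sigma[o,o].
.factor_block <- function(sigma, o, ridge = 0, what = "observed block") {
  S <- sigma[o, o, drop = FALSE]
  if (ridge > 0) diag(S) <- diag(S) + ridge
  d <- sqrt(diag(S))
  if (any(!is.finite(d)) || any(d <= 0))
    stop("non-positive variance in ", what)
  C <- S / tcrossprod(d)
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R) || (max(diag(R)) / min(diag(R)))^2 > 1e12)
    stop("near-singular ", what,
         " (condition number of the scaled block exceeds 1e12); ",
         "consider ridge = TRUE")
  list(R = R, d = d, logdet = 2 * sum(log(diag(R))) + 2 * sum(log(d)))
}

# Solve Sigma[o,o] X = B given a .factor_block() factorization.
.solve_block <- function(f, B) {
  B <- B / f$d
  X <- backsolve(f$R, backsolve(f$R, B, transpose = TRUE))
  X / f$d
}

#' Group rows by missingness pattern
#'
#' Rows sharing the same set of observed columns form one likelihood group;
#' the observed-data log-likelihood factors over these groups, each
#' contributing a normal density on its own margin of (mu, Sigma).
#'
#' @param x numeric matrix with `NA` for missing cells, or a model-space
#'   [prop_table()].
#' @return A list of groups, ordered lexicographically by observed-column
#'   set; each element has `obs` (sorted observed column indices), `rows`
#'   (row indices) and `n` (group size).  A row with no observed cell is an
#'   error: such rows carry no information and must be dropped by the caller.
#' @examples
#' m <- rbind(c(1, 2), c(3, 4), c(5, NA), c(NA, 6))
#' length(pattern_groups(m))  # 3 distinct patterns
#' @export
pattern_groups <- function(x) {
  m <- .as_model_matrix(x)
  obs <- !is.na(m)
  empty <- which(rowSums(obs) == 0L)
  if (length(empty))
    stop("row(s) with no observed values: ",
         paste(utils::head(empty, 5L), collapse = ", "),
         "; drop or flag them before fitting")
  key <- apply(obs, 1L, function(r) paste(sprintf("%05d", which(r)),
                                          collapse = "."))
  idx <- split(seq_len(nrow(m)), key)
  idx <- idx[order(names(idx), method = "radix")]
  lapply(idx, function(rows) {
    list(obs = unname(which(obs[rows[1L], ])), rows = rows,
         n = length(rows))
  })
}

#' Starting values for the EM iteration
#'
#' Available-case initialization: per-column means and standard deviations
#' over the observed cells of each column, with all correlations set to
#' zero, so the starting covariance is diagonal.  The available-case
#' variances use the usual n-1 denominator of a sample standard deviation
#' (the EM M-step itself uses the maximum-likelihood denominator n).
#'
#' @inheritParams pattern_groups
#' @return A list with `mu` (p-vector) and `sigma` (diagonal p x p matrix).
#' @export
em_init <- function(x) {
  m <- .as_model_matrix(x)
  nobs <- colSums(!is.na(m))
  if (any(nobs < 2L))
    stop("column(s) with fewer than 2 observed values: ",
         paste(colnames(m)[nobs < 2L], collapse = ", "))
  mu <- colMeans(m, na.rm = TRUE)
  v <- apply(m, 2L, stats::var, na.rm = TRUE)
  if (any(v <= 0))
    stop("column(s) with zero available-case variance: ",
         paste(colnames(m)[v <= 0], collapse = ", "))
  sigma <- diag(v, ncol(m))
  dimnames(sigma) <- list(colnames(m), colnames(m))
  list(mu = mu, sigma = sigma)
}

#' Observed-data log-likelihood of a multivariate normal with missing cells
#'
#' Evaluates sum_g log L_g(mu, Sigma), where group g collects the rows with
#' a common observed-column set and contributes the multivariate normal
#' density of its observed sub-vectors under the corresponding margin
#' (mu_g, Sigma_g).  The (2*pi) normalization constant is included, so the
#' value is the exact log-density of the observed data.
#'
#' @inheritParams pattern_groups
#' @param mu mean vector.
#' @param sigma covariance matrix.
#' @param groups optional precomputed [pattern_groups()] result.
#' @param ridge non-negative ridge added to the diagonal of each observed
#'   block before factorization (0 = none).
#' @return A single number.
#' @export
mvn_loglik <- function(x, mu, sigma, groups = NULL, ridge = 0) {
  m <- .as_model_matrix(x)
  if (is.null(groups)) groups <- pattern_groups(m)
  ll <- 0
  for (g in groups) {
    o <- g$obs
    f <- .factor_block(sigma, o, ridge = ridge,
                       what = paste0("observed block of pattern {",
                                     paste(o, collapse = ","), "}"))
    yc <- t(m[g$rows, o, drop = FALSE]) - mu[o]
    z <- backsolve(f$R, yc / f$d, transpose = TRUE)
    ll <- ll - 0.5 * (g$n * (length(o) * log(2 * pi) + f$logdet) +
                        sum(z * z))
  }
  ll
}

#' One E-step: expected complete-data sufficient statistics
#'
#' For each row, missing components are replaced by their conditional mean
#' `mu_mis + Sigma_mis,obs Sigma_obs,obs^-1 (y_obs - mu_obs)` and the
#' conditional covariance (the Schur complement
#' `Sigma_mis,mis - Sigma_mis,obs Sigma_obs,obs^-1 Sigma_obs,mis`) is added
#' to the second-moment accumulator on the missing-missing block.  One
#' factorization per missingness pattern is shared by all rows of the
#' pattern.
#'
#' @inheritParams mvn_loglik
#' @return A list with `T1` (p-vector of expected sums), `T2` (p x p matrix
#'   of expected cross-product sums) and `n`.
#' @export
em_estep <- function(x, mu, sigma, groups = NULL, ridge = 0) {
  m <- .as_model_matrix(x)
  if (is.null(groups)) groups <- pattern_groups(m)
  p <- ncol(m)
  T1 <- numeric(p)
  T2 <- matrix(0, p, p)
  for (g in groups) {
    o <- g$obs
    mis <- setdiff(seq_len(p), o)
    Y <- m[g$rows, o, drop = FALSE]
    if (!length(mis)) {
      T1[o] <- T1[o] + colSums(Y)
      T2[o, o] <- T2[o, o] + crossprod(Y)
      next
    }
    f <- .factor_block(sigma, o, ridge = ridge,
                       what = paste0("observed block of pattern {",
                                     paste(o, collapse = ","), "}"))
    W <- .solve_block(f, t(Y) - mu[o])            # |o| x n_g
    M <- mu[mis] + sigma[mis, o, drop = FALSE] %*% W  # |mis| x n_g
    Cc <- sigma[mis, mis, drop = FALSE] -
      sigma[mis, o, drop = FALSE] %*%
      .solve_block(f, sigma[o, mis, drop = FALSE])
    Cc <- (Cc + t(Cc)) / 2
    X <- matrix(0, g$n, p)
    X[, o] <- Y
    X[, mis] <- t(M)
    T1 <- T1 + colSums(X)
    T2 <- T2 + crossprod(X)
    T2[mis, mis] <- T2[mis, mis] + g$n * Cc
  }
  names(T1) <- colnames(m)
  dimnames(T2) <- list(colnames(m), colnames(m))
  list(T1 = T1, T2 = T2, n = nrow(m))
}

#' One M-step: complete-data maximum-likelihood update
#'
#' Given expected sufficient statistics, returns `mu = T1/n` and
#' `sigma = T2/n - mu mu^T` (maximum-likelihood denominator n), symmetrized.
#'
#' @param stats list produced by [em_estep()].
#' @return A list with `mu` and `sigma`.
#' @export
em_mstep <- function(stats) {
  if (stats$n < 2L) stop("need at least 2 rows")
  mu <- stats$T1 / stats$n
  sigma <- stats$T2 / stats$n - tcrossprod(mu)
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("updated covariance is not positive semi-definite ",
         "(min eigenvalue ", format(min(ev)), "); consider ridge = TRUE")
  list(mu = mu, sigma = sigma)
}

#' Fit a multivariate normal to incomplete data by EM
#'
#' Maximum-likelihood estimation of the mean vector and covariance matrix of
#' a multivariate normal distribution from a data matrix with missing cells,
#' assuming an ignorable (MCAR/MAR) missingness mechanism.  The algorithm
#' alternates an E-step (conditional expectation of the complete-data
#' sufficient statistics given the observed cells and current parameters,
#' computed per missingness-pattern group) with an M-step (complete-data
#' MLE), starting from available-case means and standard deviations with
#' correlations set to zero, and stops when the increase of the observed-data
#' log-likelihood between consecutive iterations falls below `tol`.
#'
#' @param x numeric matrix or data frame with `NA` for missing cells, or a
#'   model-space [prop_table()].  Every row must have at least one observed
#'   cell and every column at least two.
#' @param tol convergence threshold on the log-likelihood increase
#'   (default `1e-4`).
#' @param max_iter maximum number of EM iterations.
#' @param ridge if `TRUE`, add a small ridge `1e-8 * tr(Sigma)/p` to
#'   near-singular observed blocks instead of failing.
#' @return An object of class `em_mvn` with components `mu`, `sigma`,
#'   `loglik` (the observed-data log-likelihood trace, one value per
#'   iteration), `n_iter`, `converged`, `tol`, `data` (the model-space input
#'   matrix), `schema` (if the input carried one) and `call`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' x[sample(300, 45)] <- NA
#' x <- x[rowSums(!is.na(x)) > 0, ]  # drop uninformative rows
#' fit <- em_mvn(x)
#' fit
#' coef(fit)
#' @seealso [predict.em_mvn()] for conditional-mean imputation,
#'   [bootstrap_means()] for resampling standard errors.
#' @export
em_mvn <- function(x, tol = 1e-4, max_iter = 500L, ridge = FALSE) {
  cl <- match.call()
  schema <- if (inherits(x, "prop_table")) x$schema else NULL
  m <- .as_model_matrix(x)
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be positive")
  groups <- pattern_groups(m)
  init <- em_init(m)
  mu <- init$mu
  sigma <- init$sigma
  lam <- 0
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    if (ridge) lam <- 1e-8 * sum(diag(sigma)) / ncol(m)
    st <- em_estep(m, mu, sigma, groups, ridge = lam)
    up <- em_mstep(st)
    mu <- up$mu
    sigma <- up$sigma
    trace[it] <- mvn_loglik(m, mu, sigma, groups, ridge = lam)
    if (it > 1L && trace[it] - trace[it - 1L] < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations ",
            "(last increase ", format(trace[it] - trace[it - 1L]), ")")
  structure(list(mu = mu, sigma = sigma, loglik = trace, n_iter = it,
                 converged = converged, tol = tol, max_iter = max_iter,
                 data = m, schema = schema, ridge = ridge, call = cl),
            class = "em_mvn")
}
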