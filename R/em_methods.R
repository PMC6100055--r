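#' @export
print.em_mvn <- function(x, digits = 4L, ...) {
  cat("Multivariate normal fitted by EM on incomplete data\n\n")
  cat("Call:\n  ", deparse(x$call), "\n\n", sep = "")
  n <- nrow(x$data); p <- ncol(x$data)
  cat(sprintf("n = %d rows, p = %d variables, %d missing cells (%.1f%%)\n",
              n, p, sum(is.na(x$data)),
              100 * mean(is.na(x$data))))
  cat(sprintf("%s after %d iterations (tol = %g); log-likelihood %.4f\n",
              if (x$converged) "Converged" else "NOT converged",
              x$n_iter, x$tol, x$loglik[x$n_iter]))
  cat("\nMeans:\n")
  print(round(x$mu, digits))
  invisible(x)
}

#' Summarize an EM fit
#'
#' Tabulates, per variable, the number of observed and missing cells, the
#' fitted mean and standard deviation, and reports the convergence record.
#'
#' @param object an [em_mvn()] fit.
#' @param ... unused.
#' @export
summary.em_mvn <- function(object, ...) {
  tab <- data.frame(
    variable = colnames(object$data),
    n_obs = colSums(!is.na(object$data)),
    n_missing = colSums(is.na(object$data)),
    mean = object$mu,
    sd = sqrt(diag(object$sigma)),
    row.names = NULL
  )
  structure(list(table = tab, n_iter = object$n_iter,
                 converged = object$converged, tol = object$tol,
                 loglik = object$loglik[object$n_iter],
                 n = nrow(object$data)),
            class = "summary.em_mvn")
}

#' @export
print.summary.em_mvn <- function(x, digits = 4L, ...) {
  cat(sprintf("EM fit on %d rows; %s after %d iterations (tol = %g)\n",
              x$n, if (x$converged) "converged" else "not converged",
              x$n_iter, x$tol))
  cat(sprintf("Observed-data log-likelihood: %.4f\n\n", x$loglik))
  tab <- x$table
  tab$mean <- signif(tab$mean, digits)
  tab$sd <- signif(tab$sd, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.em_mvn <- function(object, ...) object$mu

#' @export
logLik.em_mvn <- function(object, ...) {
  p <- ncol(object$data)
  structure(object$loglik[object$n_iter],
            df = p + p * (p + 1) / 2,
            nobs = nrow(object$data),
            class = "logLik")
}

#' Conditional-mean completion from an EM fit
#'
#' Replaces every missing cell of `newdata` (by default, the data the model
#' was fitted to) by its conditional expectation under the fitted normal
#' given the row's observed cells — single imputation, no noise draw.
#'
#' @param object an [em_mvn()] fit.
#' @param newdata optional matrix / [prop_table()] in model space with the
#'   same columns as the training data.
#' @param ... unused.
#' @return A [completed_table()] in model space.
#' @export
predict.em_mvn <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data else newdata
  conditional_impute(x, object$mu, object$sigma,
                     schema = if (is.null(newdata)) object$schema else NULL)
}

#' Residuals of an EM fit
#'
#' Observed cells minus fitted means (`type = "response"`), optionally
#' scaled by the fitted standard deviations (`type = "pearson"`).  Missing
#' cells are `NA`.
#'
#' @param object an [em_mvn()] fit.
#' @param type `"response"` or `"pearson"`.
#' @param ... unused.
#' @export
residuals.em_mvn <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- sweep(object$data, 2L, object$mu)
  if (type == "pearson") r <- sweep(r, 2L, sqrt(diag(object$sigma)), "/")
  r
}

#' Simulate complete datasets from a fitted normal
#'
#' @param object an [em_mvn()] fit.
#' @param nsim number of datasets.
#' @param seed optional integer passed to [set.seed()].
#' @param n rows per dataset (default: the training sample size).
#' @param ... unused.
#' @return A list of `nsim` numeric matrices.
#' @export
simulate.em_mvn <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- nrow(object$data)
  lapply(seq_len(nsim), function(i) .rmvn(n, object$mu, object$sigma))
}

#' Plot the log-likelihood trace of an EM fit
#'
#' The observed-data log-likelihood is non-decreasing over EM iterations;
#' this plot is the standard convergence diagnostic.
#'
#' @param x an [em_mvn()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.em_mvn <- function(x, ...) {
  graphics::plot(seq_along(x$loglik), x$loglik, type = "b", pch = 16,
                 xlab = "EM iteration",
                 ylab = "observed-data log-likelihood", ...)
  invisible(x)
}

# Draw n rows from N(mu, sigma) by the Cholesky factor of sigma (with a tiny
# jitter retry for numerically semi-definite fits).
.rmvn <- function(n, mu, sigma) {
  p <- length(mu)
  R <- tryCatch(chol(sigma), error = function(e) {
    chol(sigma + diag(1e-10 * max(diag(sigma)), p))
  })
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% R, 2L, mu, "+")
}
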