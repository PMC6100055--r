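#' Principal component analysis of a completed table
#'
#' Eigendecomposition of the sample correlation matrix (default) of the
#' completed data.  Working on correlations rather than covariances puts
#' descriptors spanning many orders of magnitude on a common footing, which
#' is what makes the loadings comparable across variables.  The sign of each
#' component is fixed so that its largest-magnitude loading is positive.
#'
#' @param x a model-space [completed_table()], or a complete numeric matrix.
#' @param q number of components to retain (default 3).
#' @param use `"correlation"` (default) or `"covariance"`.
#' @return An object of class `pca_completed`: `loadings` (p x q orthonormal
#'   eigenvectors), `explained` (q proportions of total variance),
#'   `eigenvalues` (all p), `q` and `use`.
#' @examples
#' set.seed(42)
#' x <- matrix(rnorm(300), 50, 6)
#' run <- pca_completed(x, q = 3)
#' sum(run$eigenvalues) / ncol(x)  # 1 for correlation PCA
#' @export
pca_completed <- function(x, q = 3L, use = c("correlation", "covariance")) {
  use <- match.arg(use)
  v <- .as_complete_matrix(x)
  n <- nrow(v); p <- ncol(v)
  if (n <= p) stop("need more rows than variables (n = ", n, ", p = ", p, ")")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(v)[sds == 0], collapse = ", "))
  if (q < 1L || q > p) stop("'q' must be in 1..", p)
  Cm <- if (use == "correlation") stats::cor(v) else stats::cov(v)
  e <- eigen(Cm, symmetric = TRUE)
  L <- e$vectors
  for (j in seq_len(p)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(v)
  colnames(L) <- paste0("PC", seq_len(p))
  structure(list(loadings = L[, seq_len(q), drop = FALSE],
                 explained = e$values[seq_len(q)] / sum(e$values),
                 eigenvalues = e$values, q = q, use = use),
            class = "pca_completed")
}

#' @export
print.pca_completed <- function(x, digits = 4L, ...) {
  cat(sprintf("PCA of the %s matrix: first %d of %d components explain %.1f%%\n",
              x$use, x$q, length(x$eigenvalues), 100 * sum(x$explained)))
  cat("Per-component: ",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n\n")
  print(round(x$loadings, digits))
  invisible(x)
}

#' Mardia's multivariate kurtosis test
#'
#' Computes the multivariate kurtosis statistic
#' `b2p = mean(d_i^2)` with `d_i = (x_i - xbar)' S^-1 (x_i - xbar)` and `S`
#' the maximum-likelihood (denominator n) covariance.  Under multivariate
#' normality `b2p` is asymptotically normal with mean `p(p+2)` and variance
#' `8 p (p+2) / n`; the reported p-value is the two-sided standard-normal
#' tail of the standardized statistic.  Mahalanobis distances are invariant
#' to rescaling, so columns are standardized internally for numerical
#' stability when variables live on very different scales.
#'
#' When applied after conditional-mean imputation the test is approximate:
#' imputed cells sit on the fitted regression surface and shrink the tails,
#' so rejection is, if anything, conservative evidence against normality of
#' the underlying data.
#'
#' @inheritParams pca_completed
#' @return An object of class `htest` with the kurtosis statistic
#'   (`estimate`), the standardized statistic (`statistic`, named `z`) and
#'   the p-value.
#' @examples
#' set.seed(7)
#' mardia_kurtosis(matrix(rnorm(400), 100, 4))
#' @export
mardia_kurtosis <- function(x) {
  v <- .as_complete_matrix(x)
  n <- nrow(v); p <- ncol(v)
  if (n <= p) stop("need more rows than variables")
  v <- scale(v)  # affine invariance of d_i
  S <- crossprod(v) / n
  d <- tryCatch(stats::mahalanobis(v, rep(0, p), S),
                error = function(e) stop("singular covariance matrix"))
  b2p <- mean(d^2)
  z <- (b2p - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  structure(list(statistic = c(z = z),
                 parameter = c(n = n, p = p),
                 estimate = c(b2p = b2p, expected = p * (p + 2)),
                 p.value = 2 * stats::pnorm(-abs(z)),
                 method = "Mardia's multivariate kurtosis test",
                 alternative = "kurtosis differs from the multivariate normal value",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

# completed_table (model space) or complete numeric matrix -> matrix
.as_complete_matrix <- function(x) {
  if (inherits(x, "completed_table")) {
    if (x$space != "model")
      stop("expected a model-space completed table")
    return(x$values)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix")
  if (anyNA(x)) stop("matrix contains missing cells; impute first")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}
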