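#' Bootstrap standard errors of the EM-fitted means
#'
#' Resamples rows (cases) with replacement, reruns the full EM fit on each
#' resample and summarizes the fitted mean vectors: the bootstrap mean, its
#' deviation from the full-data point estimate (`mean_error`, a bias
#' estimate) and the bootstrap standard error per variable.  All quantities
#' are reported on the model scale, i.e. log-transformed variables on the
#' log scale and the remaining variables in their native units.
#'
#' Resamples on which the fit is infeasible (e.g. a column left with fewer
#' than two observed values) are redrawn; the redraw count is returned, and
#' more than `10 * B` redraws abort.
#'
#' @param x numeric matrix with `NA`s or a model-space [prop_table()].
#' @param B number of bootstrap resamples.
#' @param seed integer RNG seed (required: the result is a pure function of
#'   `(x, B, seed, tol, max_iter)`).
#' @param tol,max_iter,ridge passed to [em_mvn()].
#' @return An object of class `boot_means`: a data frame `table` with
#'   columns `variable`, `em_mean`, `boot_mean`, `mean_error`, `se`, plus
#'   `B`, `seed` and `redraws`.
#' @examples
#' x <- matrix(rnorm(160), 80, 2)
#' x[sample(80, 20), 2] <- NA  # gaps confined to the second column
#' bootstrap_means(x, B = 50, seed = 1)
#' @export
bootstrap_means <- function(x, B = 1000L, seed, tol = 1e-4, max_iter = 500L,
                            ridge = FALSE) {
  if (missing(seed)) stop("'seed' is required for a reproducible bootstrap")
  m <- .as_model_matrix(x)
  if (B < 1L) stop("'B' must be at least 1")
  fit <- em_mvn(m, tol = tol, max_iter = max_iter, ridge = ridge)
  n <- nrow(m)
  set.seed(seed)
  mus <- matrix(NA_real_, B, ncol(m), dimnames = list(NULL, colnames(m)))
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      mb <- m[idx, , drop = FALSE]
      rownames(mb) <- NULL
      fb <- tryCatch(
        suppressWarnings(em_mvn(mb, tol = tol, max_iter = max_iter,
                                ridge = ridge)),
        error = function(e) NULL)
      if (!is.null(fb)) break
      redraws <- redraws + 1L
      if (redraws > 10L * B)
        stop("bootstrap aborted: more than ", 10L * B,
             " resamples failed to fit")
    }
    mus[b, ] <- fb$mu
  }
  boot_mean <- colMeans(mus)
  tab <- data.frame(variable = colnames(m),
                    em_mean = fit$mu,
                    boot_mean = boot_mean,
                    mean_error = boot_mean - fit$mu,
                    se = apply(mus, 2L, stats::sd),
                    row.names = NULL)
  structure(list(table = tab, B = B, seed = seed, redraws = redraws,
                 fit = fit),
            class = "boot_means")
}

#' @export
print.boot_means <- function(x, digits = 4L, ...) {
  cat(sprintf("Bootstrap of EM-fitted means: B = %d (seed %d, %d redraws)\n",
              x$B, x$seed, x$redraws))
  cat("mean_error = bootstrap mean - full-data estimate (bias estimate)\n\n")
  tab <- x$table
  for (cn in c("em_mean", "boot_mean", "mean_error", "se"))
    tab[[cn]] <- signif(tab[[cn]], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
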