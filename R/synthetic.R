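# Synthetic multivariate-normal datasets with study-shaped missingness:
# known truth for every pipeline stage, no external data needed.

#' Specify a synthetic incomplete multivariate normal dataset
#'
#' @param n number of rows (compounds).
#' @param p number of columns (descriptors).
#' @param mu_true true mean vector (model space).
#' @param sigma_true true covariance matrix (PSD).
#' @param complete_fraction fraction of rows kept fully observed.
#' @param missing_cols columns eligible for cell deletion (indices or names).
#' @param cell_missing_rate per-eligible-cell deletion probability; a scalar
#'   or one rate per entry of `missing_cols`.
#' @return An object of class `mvn_missing_spec`.
#' @seealso [study_shaped_spec()], [simulate_mvn_missing()]
#' @export
mvn_missing_spec <- function(n, p, mu_true = rep(0, p),
                             sigma_true = diag(p),
                             complete_fraction = 0,
                             missing_cols = seq_len(p),
                             cell_missing_rate = 0.2) {
  if (is.character(missing_cols)) {
    missing_cols <- match(missing_cols, names(mu_true))
    if (anyNA(missing_cols)) stop("unknown column name in 'missing_cols'")
  }
  stopifnot(n >= 1, p >= 1, length(mu_true) == p,
            all(dim(sigma_true) == c(p, p)),
            complete_fraction >= 0, complete_fraction <= 1,
            all(missing_cols %in% seq_len(p)),
            all(cell_missing_rate >= 0), all(cell_missing_rate <= 1))
  if (!length(cell_missing_rate) %in% c(1L, length(missing_cols)))
    stop("'cell_missing_rate' must be scalar or match 'missing_cols'")
  if (max(abs(sigma_true - t(sigma_true))) > 1e-10)
    stop("'sigma_true' must be symmetric")
  ev <- eigen(sigma_true, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) stop("'sigma_true' must be PSD")
  rate <- rep_len(unname(cell_missing_rate), length(missing_cols))
  names(rate) <- names(mu_true)[missing_cols]
  structure(list(n = as.integer(n), p = as.integer(p), mu_true = mu_true,
                 sigma_true = sigma_true,
                 complete_fraction = complete_fraction,
                 missing_cols = as.integer(missing_cols),
                 cell_missing_rate = rate),
            class = "mvn_missing_spec")
}

#' Study-shaped synthetic specification
#'
#' A canned [mvn_missing_spec()] emulating the structure of the solvent
#' study dataset: 155 rows, the 13 schema descriptors, 85 fully observed
#' rows, and MCAR deletion concentrated in the gap-prone columns (the five
#' endpoint variables, plus small rates for melting point, Henry's law
#' constant and log KOA).  Per-column deletion rates are the study's
#' missing-value counts divided by the 70 incomplete rows, so expected
#' missing counts match those counts.  Means and standard deviations are
#' set to the study's reported magnitudes, log-flagged variables on the
#' natural-log scale; the correlation structure is a single common factor
#' with loadings 0.5 (pairwise correlation 0.25), informative for
#' imputation yet well conditioned.
#'
#' @return An `mvn_missing_spec` for `n = 155`, `p = 13`.
#' @export
study_shaped_spec <- function() {
  sch <- solvent_schema()
  mu <- c(-43.9, 142.4, 0.952, 116797, 11902,
          2.47, 2.23, 4.43, 7.61, 8.27, 4.22, 2.24, 1.15)
  sd <- c(48.7, 68.6, 0.214, 244340, 28632,
          3.6, 2.35, 2.0, 1.2, 1.5, 2.0, 1.2, 1.02)
  names(mu) <- names(sd) <- sch$name
  R <- matrix(0.25, 13, 13)
  diag(R) <- 1
  sigma <- R * tcrossprod(sd)
  dimnames(sigma) <- list(sch$name, sch$name)
  n_missing <- c(melting_point = 3, henry_law_constant = 2, log_koa = 3,
                 oral_ld50 = 35, inhalation_lc50 = 46, fish_lc50 = 57,
                 bod_half_life = 62, log_bcf = 4)
  mvn_missing_spec(n = 155L, p = 13L, mu_true = mu, sigma_true = sigma,
                   complete_fraction = 85 / 155,
                   missing_cols = names(n_missing),
                   cell_missing_rate = n_missing / 70)
}

#' Draw a synthetic incomplete dataset
#'
#' Samples `n` rows from `N(mu_true, sigma_true)`, keeps
#' `ceiling(complete_fraction * n)` randomly chosen rows fully observed, and
#' deletes each eligible cell of the remaining rows independently with its
#' column's rate (missing completely at random).  The deletion mask is
#' redrawn (at most 1000 times) until every row keeps at least one observed
#' cell and every column at least two, the preconditions of [em_mvn()].
#'
#' @param spec an [mvn_missing_spec()].
#' @param seed integer RNG seed; the output is a pure function of
#'   `(spec, seed)`.
#' @return A list with `data` (n x p matrix with `NA`s, model space),
#'   `full` (the unmasked draws), `truth` (list `mu`, `sigma`) and `spec`.
#' @examples
#' sim <- simulate_mvn_missing(mvn_missing_spec(50, 3), seed = 1)
#' sum(is.na(sim$data))
#' @export
simulate_mvn_missing <- function(spec, seed) {
  stopifnot(inherits(spec, "mvn_missing_spec"))
  if (missing(seed)) stop("'seed' is required")
  set.seed(seed)
  full <- .rmvn(spec$n, spec$mu_true, spec$sigma_true)
  colnames(full) <- names(spec$mu_true) %||% paste0("V", seq_len(spec$p))
  n_complete <- ceiling(spec$complete_fraction * spec$n)
  complete_rows <- if (n_complete > 0) sample.int(spec$n, n_complete)
                   else integer(0)
  eligible_rows <- setdiff(seq_len(spec$n), complete_rows)
  dat <- full
  if (length(eligible_rows) && length(spec$missing_cols)) {
    draw_rows <- function(rows) {
      d <- matrix(FALSE, length(rows), spec$p)
      for (k in seq_along(spec$missing_cols))
        d[, spec$missing_cols[k]] <-
          stats::runif(length(rows)) < spec$cell_missing_rate[k]
      d
    }
    for (try in seq_len(1000L)) {
      drop <- matrix(FALSE, spec$n, spec$p)
      drop[eligible_rows, ] <- draw_rows(eligible_rows)
      # rows left with no observed cell: redraw their deletions only
      for (rtry in seq_len(1000L)) {
        bad <- eligible_rows[rowSums(!drop[eligible_rows, , drop = FALSE])
                             == 0L]
        if (!length(bad)) break
        if (rtry == 1000L)
          stop("could not satisfy row/column observability in 1000 ",
               "redraws; lower the deletion rates")
        drop[bad, ] <- draw_rows(bad)
      }
      if (all(colSums(!drop) >= 2L)) break
      if (try == 1000L)
        stop("could not satisfy row/column observability in 1000 redraws; ",
             "lower the deletion rates")
    }
    dat[drop] <- NA_real_
  }
  rownames(dat) <- rownames(full) <- paste0("row_", seq_len(spec$n))
  list(data = dat, full = full,
       truth = list(mu = spec$mu_true, sigma = spec$sigma_true),
       spec = spec)
}

#' Parameter- and imputation-recovery metrics
#'
#' Compares a fit (and optionally a completed table) against the known truth
#' of a synthetic draw: maximum absolute error of the fitted means, relative
#' Frobenius error of the fitted covariance, and bias/RMSE of the imputed
#' cells against the held-out true values (model space).
#'
#' @param truth list with `mu` and `sigma` (as returned in
#'   `simulate_mvn_missing()$truth`).
#' @param fit an [em_mvn()] fit on the masked data.
#' @param full the unmasked value matrix.
#' @param completed optional [completed_table()] from the same fit.
#' @return A list with `mu_max_abs_error`, `mu_errors`,
#'   `sigma_rel_frobenius`, and (when `completed` has imputed cells)
#'   `imputation_rmse`, `imputation_bias` and `n_imputed`
#'   (`NA` / 0 when nothing was imputed).
#' @export
recovery_report <- function(truth, fit, full, completed = NULL) {
  stopifnot(inherits(fit, "em_mvn"))
  if (length(truth$mu) != length(fit$mu) ||
      !all(dim(truth$sigma) == dim(fit$sigma)))
    stop("shape mismatch between truth and fit")
  out <- list(
    mu_errors = fit$mu - truth$mu,
    mu_max_abs_error = max(abs(fit$mu - truth$mu)),
    sigma_rel_frobenius = norm(fit$sigma - truth$sigma, "F") /
      norm(truth$sigma, "F"))
  if (!is.null(completed)) {
    if (!all(dim(completed$values) == dim(full)))
      stop("shape mismatch between completed table and full values")
    imp <- completed$provenance == "imputed"
    if (any(imp)) {
      err <- completed$values[imp] - full[imp]
      out$imputation_rmse <- sqrt(mean(err^2))
      out$imputation_bias <- mean(err)
      out$n_imputed <- sum(imp)
    } else {
      out$imputation_rmse <- NA_real_
      out$imputation_bias <- NA_real_
      out$n_imputed <- 0L
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
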