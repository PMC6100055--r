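#' Completed table with per-cell provenance
#'
#' Container for a fully imputed matrix: no missing cells remain, and a
#' parallel character matrix records for every cell whether it was
#' `"observed"` in the input or `"imputed"` by the model.
#'
#' @param values numeric matrix without `NA`s.
#' @param provenance character matrix of the same shape with entries
#'   `"observed"` / `"imputed"`.
#' @param space `"raw"` or `"model"`.
#' @param schema optional variable schema (needed for space conversion).
#' @return An object of class `completed_table`.
#' @export
completed_table <- function(values, provenance, space = c("model", "raw"),
                            schema = NULL) {
  space <- match.arg(space)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (anyNA(values)) stop("a completed table may not contain missing cells")
  if (!identical(dim(values), dim(provenance)))
    stop("'values' and 'provenance' must have the same shape")
  if (!all(provenance %in% c("observed", "imputed")))
    stop("provenance entries must be 'observed' or 'imputed'")
  provenance <- matrix(provenance, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  if (!is.null(schema)) .check_schema(schema)
  structure(list(values = values, provenance = provenance, space = space,
                 schema = schema),
            class = "completed_table")
}

#' Impute missing cells by their conditional means
#'
#' Fills every missing cell with its expectation under `N(mu, sigma)` given
#' the row's observed cells: for a row with observed set `obs` and missing
#' set `mis`, the fill is
#' `mu_mis + Sigma_mis,obs Sigma_obs,obs^-1 (y_obs - mu_obs)`.
#' Observed cells are copied through unchanged.  This is single
#' (deterministic) imputation; no residual noise is added, so imputed values
#' sit exactly on the fitted regression surface.
#'
#' @inheritParams mvn_loglik
#' @param schema optional schema attached to the result (taken from `x`
#'   when `x` is a [prop_table()]).
#' @return A [completed_table()] in model space.
#' @seealso [predict.em_mvn()], which calls this with the fitted parameters.
#' @export
conditional_impute <- function(x, mu, sigma, ridge = 0, schema = NULL) {
  if (inherits(x, "prop_table") && is.null(schema)) schema <- x$schema
  m <- .as_model_matrix(x)
  groups <- pattern_groups(m)
  vals <- m
  prov <- matrix(ifelse(is.na(m), "imputed", "observed"),
                 nrow(m), ncol(m), dimnames = dimnames(m))
  p <- ncol(m)
  for (g in groups) {
    o <- g$obs
    mis <- setdiff(seq_len(p), o)
    if (!length(mis)) next
    f <- .factor_block(sigma, o, ridge = ridge,
                       what = paste0("observed block for row '",
                                     rownames(m)[g$rows[1L]], "'"))
    W <- .solve_block(f, t(m[g$rows, o, drop = FALSE]) - mu[o])
    vals[g$rows, mis] <- t(mu[mis] + sigma[mis, o, drop = FALSE] %*% W)
  }
  completed_table(vals, prov, space = "model", schema = schema)
}

#' @export
from_model_space.completed_table <- function(x) {
  if (x$space != "model") stop("table is already in raw space")
  if (is.null(x$schema))
    stop("completed table carries no schema; cannot back-transform")
  vals <- x$values
  for (j in which(x$schema$log_transform)) vals[, j] <- exp(vals[, j])
  completed_table(vals, x$provenance, space = "raw", schema = x$schema)
}

#' Mean of a cell selection of a completed table
#'
#' Arithmetic mean of one variable over a set of rows, optionally restricted
#' by provenance — the summary used to report, e.g., the mean predicted
#' inhalation LC50 of a solvent family.
#'
#' @param t a [completed_table()].
#' @param rows integer row indices or character row ids.
#' @param variable column name.
#' @param cells `"all"`, `"imputed_only"` or `"observed_only"`.
#' @return The mean (a single number).
#' @examples
#' t3 <- table3_fixture()
#' group_mean_summary(t3, 64:66, "inhalation_lc50")  # chloroalkanes
#' @export
group_mean_summary <- function(t, rows, variable,
                               cells = c("all", "imputed_only",
                                         "observed_only")) {
  stopifnot(inherits(t, "completed_table"))
  cells <- match.arg(cells)
  if (!variable %in% colnames(t$values))
    stop("unknown variable '", variable, "'")
  if (is.character(rows)) {
    bad <- setdiff(rows, rownames(t$values))
    if (length(bad)) stop("unknown row id(s): ", paste(bad, collapse = ", "))
    rows <- match(rows, rownames(t$values))
  } else if (any(rows < 1L | rows > nrow(t$values))) {
    stop("row index out of range")
  }
  v <- t$values[rows, variable]
  pr <- t$provenance[rows, variable]
  keep <- switch(cells,
                 all = rep(TRUE, length(v)),
                 imputed_only = pr == "imputed",
                 observed_only = pr == "observed")
  if (!any(keep)) stop("empty cell selection (cells = '", cells, "')")
  mean(v[keep])
}

#' Write / read a completed table
#'
#' `write_completed()` serializes the values and the provenance mask as two
#' CSV files (full double precision); `read_completed()` restores them.
#'
#' @param t a [completed_table()].
#' @param path destination CSV for the values.
#' @param provenance_path destination CSV for the provenance mask.
#' @param schema,space passed through when reading back.
#' @return `write_completed()` returns `t` invisibly; `read_completed()`
#'   returns a [completed_table()].
#' @export
write_completed <- function(t, path, provenance_path) {
  stopifnot(inherits(t, "completed_table"))
  utils::write.csv(as.data.frame(t$values), path, row.names = TRUE)
  utils::write.csv(as.data.frame(t$provenance), provenance_path,
                   row.names = TRUE)
  invisible(t)
}

#' @rdname write_completed
#' @export
read_completed <- function(path, provenance_path, schema = NULL,
                           space = "raw") {
  v <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  pr <- utils::read.csv(provenance_path, row.names = 1L, check.names = FALSE,
                        colClasses = "character")
  vm <- as.matrix(v)
  storage.mode(vm) <- "double"
  completed_table(vm, as.matrix(pr), space = space, schema = schema)
}

#' @export
print.completed_table <- function(x, ...) {
  cat(sprintf("Completed table: %d rows x %d variables (%s space)\n",
              nrow(x$values), ncol(x$values), x$space))
  cat(sprintf("Imputed cells: %d (%.1f%%)\n",
              sum(x$provenance == "imputed"),
              100 * mean(x$provenance == "imputed")))
  invisible(x)
}

#' @export
dim.completed_table <- function(x) dim(x$values)

#' @export
as.matrix.completed_table <- function(x, ...) x$values
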