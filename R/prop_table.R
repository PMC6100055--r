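#' Property table with explicit missingness
#'
#' A `prop_table` is the package's rectangular data container: an n x p
#' numeric matrix of compound-by-descriptor values with `NA` marking missing
#' cells, a parallel logical mask (`TRUE` = observed), the space the values
#' live in (`"raw"` reporting units or `"model"`, i.e. after the schema's
#' log transforms), and the variable schema.
#'
#' @param values numeric matrix (or data frame) of property values; `NA`
#'   marks a missing cell.  Columns must match `schema$name`.
#' @param schema variable schema, see [solvent_schema()].
#' @param space `"raw"` or `"model"`.
#' @param row_ids optional character vector of unique row identifiers;
#'   defaults to existing rownames or `row_1 ... row_n`.
#' @return An object of class `prop_table`.
#' @seealso [read_prop_table()], [to_model_space()], [apply_sentinels()]
#' @export
prop_table <- function(values, schema = solvent_schema(),
                       space = c("raw", "model"), row_ids = NULL) {
  space <- match.arg(space)
  .check_schema(schema)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(colnames(values))) {
    if (ncol(values) != nrow(schema))
      stop("ncol(values) = ", ncol(values), " does not match the schema (",
           nrow(schema), " variables)")
    colnames(values) <- schema$name
  }
  extra <- setdiff(colnames(values), schema$name)
  if (length(extra))
    stop("column(s) not in schema: ", paste(extra, collapse = ", "))
  absent <- setdiff(schema$name, colnames(values))
  if (length(absent))
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  values <- values[, schema$name, drop = FALSE]
  if (nrow(values) < 1L) stop("need at least one row")
  if (is.null(row_ids)) {
    row_ids <- rownames(values)
    if (is.null(row_ids)) row_ids <- paste0("row_", seq_len(nrow(values)))
  }
  row_ids <- as.character(row_ids)
  if (length(row_ids) != nrow(values)) stop("length(row_ids) != nrow(values)")
  if (anyDuplicated(row_ids))
    stop("duplicate row_ids: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  rownames(values) <- row_ids
  mask <- !is.na(values)
  if (any(!is.finite(values[mask])))
    stop("non-finite observed value(s) present")
  structure(list(values = values, mask = mask, space = space,
                 schema = schema),
            class = "prop_table")
}

#' Read a property table from a delimited file
#'
#' Reads a header-ed CSV whose columns are exactly the schema variables plus,
#' optionally, identifier columns named in `id_cols`.  Empty cells, `NA`,
#' `NaN` (case-insensitive) denote missing values.  Any other non-numeric
#' token is a parse error reported with its row and column.
#'
#' @param path path to a CSV file (RFC-4180, header row).
#' @param schema variable schema; see [solvent_schema()].
#' @param id_cols character vector of permitted non-numeric identifier
#'   columns; the first one present is used for row ids.
#' @param sep field separator.
#' @return A [prop_table()] in raw space.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(oral_ld50 = c(10, NA, 30), fish_lc50 = c(1, 2, 3)),
#'           f, row.names = FALSE)
#' pt <- read_prop_table(f, solvent_schema(c("oral_ld50", "fish_lc50")))
#' pt$mask
#' @export
read_prop_table <- function(path, schema = solvent_schema(),
                            id_cols = c("id", "solvent", "cas"), sep = ",") {
  .check_schema(schema)
  raw <- utils::read.csv(path, colClasses = "character", sep = sep,
                         check.names = FALSE, strip.white = TRUE)
  if (!nrow(raw)) stop("no data rows in ", path)
  extra <- setdiff(names(raw), c(schema$name, id_cols))
  if (length(extra))
    stop("unknown column(s) in ", path, ": ", paste(extra, collapse = ", "))
  absent <- setdiff(schema$name[schema$required], names(raw))
  if (length(absent))
    stop("missing required column(s) in ", path, ": ",
         paste(absent, collapse = ", "))
  ids <- intersect(id_cols, names(raw))
  row_ids <- if (length(ids)) raw[[ids[1L]]] else NULL
  vals <- matrix(NA_real_, nrow(raw), nrow(schema),
                 dimnames = list(NULL, schema$name))
  na_tokens <- c("", "na", "nan")
  for (v in schema$name) {
    tok <- raw[[v]]
    tok <- gsub(",", "", tok, fixed = TRUE)  # thousands separators
    is_na <- tolower(trimws(tok)) %in% na_tokens | is.na(tok)
    num <- suppressWarnings(as.numeric(tok))
    bad <- which(!is_na & is.na(num))
    if (length(bad))
      stop("non-numeric value '", raw[[v]][bad[1L]], "' at row ", bad[1L],
           ", column '", v, "' of ", path)
    vals[, v] <- ifelse(is_na, NA_real_, num)
  }
  prop_table(vals, schema = schema, space = "raw", row_ids = row_ids)
}

#' Apply the non-volatile sentinel rule
#'
#' For every row flagged non-volatile whose sentinel column (by default
#' inhalation LC50) is missing, the cell is filled with the sentinel value
#' (5001 ppm) and marked observed.  This encodes the expert judgment that a
#' compound too involatile to pose an inhalation hazard sits just above the
#' 5000 ppm "harmful if inhaled" classification threshold.  All other cells
#' are untouched; the input is not modified.
#'
#' @param x a [prop_table()] in raw space.
#' @param nonvolatile logical vector of length `nrow(x)`; `TRUE` flags a
#'   non-volatile compound.
#' @return A new `prop_table` with the sentinel cells filled.
#' @export
apply_sentinels <- function(x, nonvolatile) {
  stopifnot(inherits(x, "prop_table"))
  if (x$space != "raw") stop("apply_sentinels() expects a raw-space table")
  sen <- attr(x$schema, "sentinel")
  if (is.null(sen)) stop("schema declares no sentinel rule")
  if (length(nonvolatile) != nrow(x$values) || !is.logical(nonvolatile))
    stop("'nonvolatile' must be a logical vector of length ", nrow(x$values))
  fill <- nonvolatile & !x$mask[, sen$column]
  vals <- x$values
  vals[fill, sen$column] <- sen$value
  prop_table(vals, schema = x$schema, space = "raw",
             row_ids = rownames(x$values))
}

#' Map a property table between raw and model space
#'
#' `to_model_space()` replaces each log-flagged column by its natural
#' logarithm; `from_model_space()` inverts the transform.  Variables whose
#' schema flag is `FALSE` (including those already reported as log10 values)
#' are copied unchanged.  The mask is untouched in both directions and the
#' round trip reproduces observed cells to machine precision.
#'
#' @param x a [prop_table()] (or, for `from_model_space`, a
#'   [completed_table()]).
#' @return The transformed object, with its `space` field updated.
#' @export
to_model_space <- function(x) {
  stopifnot(inherits(x, "prop_table"))
  if (x$space != "raw") stop("table is already in model space")
  vals <- x$values
  for (j in which(x$schema$log_transform)) {
    obs <- x$mask[, j]
    bad <- which(obs & vals[, j] <= 0)
    if (length(bad))
      stop("non-positive value in log-transformed column '",
           x$schema$name[j], "' at row '", rownames(vals)[bad[1L]], "'")
    vals[obs, j] <- log(vals[obs, j])
  }
  out <- prop_table(vals, schema = x$schema, space = "model",
                    row_ids = rownames(x$values))
  out
}

#' @rdname to_model_space
#' @export
from_model_space <- function(x) UseMethod("from_model_space")

#' @export
from_model_space.prop_table <- function(x) {
  if (x$space != "model") stop("table is already in raw space")
  vals <- x$values
  for (j in which(x$schema$log_transform)) {
    obs <- x$mask[, j]
    vals[obs, j] <- exp(vals[obs, j])
  }
  prop_table(vals, schema = x$schema, space = "raw",
             row_ids = rownames(x$values))
}

#' @export
print.prop_table <- function(x, ...) {
  n <- nrow(x$values); p <- ncol(x$values)
  nmiss <- sum(!x$mask)
  cat(sprintf("Property table: %d compounds x %d variables (%s space)\n",
              n, p, x$space))
  cat(sprintf("Missing cells: %d (%.1f%%); complete rows: %d\n",
              nmiss, 100 * nmiss / (n * p), sum(rowSums(!x$mask) == 0)))
  invisible(x)
}

#' @export
dim.prop_table <- function(x) dim(x$values)

#' @export
as.matrix.prop_table <- function(x, ...) {
  v <- x$values
  v[!x$mask] <- NA_real_
  v
}
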