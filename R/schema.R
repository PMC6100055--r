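#' Default variable schema for the solvent descriptor table
#'
#' Returns the schema of the 13 environmental/health/safety descriptors used
#' throughout the package: physicochemical properties (melting point, boiling
#' point, density, water solubility, vapor pressure, Henry's law constant,
#' log KOW, log KOA) and endpoint variables (oral LD50, inhalation LC50, fish
#' LC50, biodegradation half-life, log BCF).
#'
#' Five variables are flagged for a natural-log transform before model
#' fitting: Henry's law constant, oral LD50, inhalation LC50, fish LC50 and
#' BOD half-life.  Variables already reported on a log10 scale (log KOW,
#' log KOA, log BCF) are not transformed again.  The schema also carries the
#' sentinel rule for non-volatile compounds: a missing inhalation LC50 of a
#' compound flagged non-volatile is set to 5001 ppm, just above the 5000 ppm
#' "harmful if inhaled" classification cut-off, and treated as observed.
#'
#' @param vars optional character vector selecting a subset of variables
#'   (in schema order).
#' @return A data frame with columns `name`, `units`, `log_transform`,
#'   `required`, carrying the sentinel rule as attribute `"sentinel"`
#'   (a list with `column`, `value` and `flag`).
#' @examples
#' solvent_schema()
#' solvent_schema(c("oral_ld50", "fish_lc50"))
#' @export
solvent_schema <- function(vars = NULL) {
  sch <- data.frame(
    name = c("melting_point", "boiling_point", "density", "water_solubility",
             "vapor_pressure", "henry_law_constant", "log_kow", "log_koa",
             "oral_ld50", "inhalation_lc50", "fish_lc50", "bod_half_life",
             "log_bcf"),
    units = c("degC", "degC", "g cm^-3", "mg dm^-3", "Pa", "Pa m^3 mol^-1",
              "log10", "log10", "mg kg^-1", "ppm", "mg dm^-3", "days",
              "log10"),
    log_transform = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                      TRUE, TRUE, TRUE, TRUE, FALSE),
    required = TRUE,
    stringsAsFactors = FALSE
  )
  attr(sch, "sentinel") <- list(column = "inhalation_lc50", value = 5001,
                                flag = "nonvolatile")
  if (!is.null(vars)) {
    miss <- setdiff(vars, sch$name)
    if (length(miss))
      stop("unknown schema variable(s): ", paste(miss, collapse = ", "))
    sen <- attr(sch, "sentinel")
    sch <- sch[match(vars, sch$name), , drop = FALSE]
    rownames(sch) <- NULL
    attr(sch, "sentinel") <- if (sen$column %in% vars) sen else NULL
  }
  sch
}

.check_schema <- function(schema) {
  if (!is.data.frame(schema) ||
      !all(c("name", "log_transform") %in% names(schema)))
    stop("'schema' must be a data frame with at least columns 'name' and ",
         "'log_transform' (see solvent_schema())")
  if (anyDuplicated(schema$name))
    stop("duplicate variable names in schema")
  invisible(schema)
}
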