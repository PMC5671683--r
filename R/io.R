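# Cohort CSV dialect: UTF-8, comma separated, quoted strings, header row
# naming every schema field, one row per woman/delivery, empty cell = missing.

.coerce_cohort_types <- function(df) {
  schema <- cohort_schema()
  for (i in seq_len(nrow(schema))) {
    f <- schema$field[i]
    df[[f]] <- switch(schema$type[i],
      integer = {
        v <- suppressWarnings(as.integer(df[[f]]))
        bad <- !is.na(df[[f]]) & is.na(v)
        if (any(bad)) stop("non-integer value in column '", f, "'")
        v
      },
      numeric = {
        v <- suppressWarnings(as.numeric(df[[f]]))
        bad <- !is.na(df[[f]]) & is.na(v)
        if (any(bad)) stop("non-numeric value in column '", f, "'")
        v
      },
      as.character(df[[f]]))
  }
  df[schema$field]
}

#' Read a cohort from CSV
#'
#' Reads a cohort file in the documented dialect (UTF-8, comma separated,
#' header naming every schema field, empty cell = unrecorded). Empty cells
#' become \code{NA}, which for tri-state condition flags is the
#' \emph{missing} state -- distinct from \code{"absent"} and preserved on a
#' round trip through \code{\link{write_cohort}}. After reading, the cohort
#' is validated; in strict mode any invariant violation aborts, otherwise
#' violations are reported as a warning and attached as the
#' \code{"validation"} attribute.
#'
#' @param path Path to a cohort CSV file.
#' @param strict Abort on invariant violations? Default \code{FALSE}.
#' @return A cohort data frame (columns in schema order) with attribute
#'   \code{"validation"} holding the violation table.
#' @seealso [write_cohort()], [validate_cohort()], [cohort_schema()]
#' @export
read_cohort <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("cannot read cohort file: ", path)
  df <- utils::read.csv(path, colClasses = "character", na.strings = "",
                        check.names = FALSE, fileEncoding = "UTF-8")
  unknown <- setdiff(names(df), .schema_fields())
  if (length(unknown))
    stop("unknown column(s) in ", path, ": ", paste(unknown, collapse = ", "))
  missing_cols <- setdiff(.schema_fields(), names(df))
  if (length(missing_cols))
    stop("column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  df <- .coerce_cohort_types(df)
  issues <- validate_cohort(df, strict = strict)
  if (nrow(issues))
    warning(nrow(issues), " invariant violation(s); see attr(, 'validation')")
  attr(df, "validation") <- issues
  df
}

#' Write a cohort to CSV
#'
#' Writes the documented dialect; unrecorded values (\code{NA}) become empty
#' cells so that \code{read_cohort(write_cohort(c))} reproduces \code{c}
#' field for field, including flag missingness.
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(.schema_fields(), names(cohort))
  if (length(missing_cols))
    stop("cohort is missing schema column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- cohort[.schema_fields()]
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write cohort file ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
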