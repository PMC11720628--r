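#' Define the column schema of a claims table
#'
#' A claims table is long-format: one row per medical act, keyed by a
#' pseudonymous entity (practitioner) identifier, with categorical columns
#' (discipline, location, billing code, ...) treated as opaque tokens and
#' numerical columns (billed amount, ...) treated as real values. The order of
#' `categorical` and `numerical` is meaningful: it fixes the column layout of
#' downstream profile matrices and attribution reports.
#'
#' @param entity_id Name of the entity identifier column.
#' @param categorical Character vector of categorical column names (may be
#'   empty). Order is preserved downstream.
#' @param numerical Character vector of numerical column names (may be empty).
#'   Order is preserved downstream.
#' @param period Optional name of a period column (e.g. the year of the act),
#'   used by the per-period activity filter.
#' @return An object of class `claims_schema`.
#' @examples
#' claims_schema("gp_id", categorical = c("discipline", "code"),
#'               numerical = "amount")
#' @export
claims_schema <- function(entity_id, categorical = character(), numerical = character(),
                          period = NULL) {
  stopifnot(is.character(entity_id), length(entity_id) == 1L)
  categorical <- as.character(categorical)
  numerical <- as.character(numerical)
  all_cols <- c(entity_id, categorical, numerical, period)
  if (anyDuplicated(all_cols)) {
    abort("schema column roles must be disjoint (a column name is used twice)")
  }
  if (length(categorical) + length(numerical) == 0L) {
    abort("schema needs at least one categorical or numerical column")
  }
  structure(
    list(entity_id = entity_id, categorical = categorical,
         numerical = numerical, period = period),
    class = "claims_schema"
  )
}

#' @export
print.claims_schema <- function(x, ...) {
  cat("<claims_schema>\n")
  cat("  entity id :", x$entity_id, "\n")
  cat("  categorical (", length(x$categorical), "): ",
      paste(utils::head(x$categorical, 8), collapse = ", "),
      if (length(x$categorical) > 8) ", ..." else "", "\n", sep = "")
  cat("  numerical (", length(x$numerical), "): ",
      paste(utils::head(x$numerical, 8), collapse = ", "),
      if (length(x$numerical) > 8) ", ..." else "", "\n", sep = "")
  if (!is.null(x$period)) cat("  period    :", x$period, "\n")
  invisible(x)
}

#' Validate a data frame as a claims table
#'
#' Checks a long-format data frame against a [claims_schema()]: all schema
#' columns present, entity IDs non-empty, numerical cells numeric (missing
#' values stay `NA`, they are never imputed as zero), categorical cells
#' coerced to character with missing values mapped to the reserved token
#' `"__missing__"` so that every action keeps a value in every categorical
#' column.
#'
#' @param data A data frame with one row per action.
#' @param schema A [claims_schema()].
#' @return A `claims_tbl`: a tibble restricted to the schema columns, carrying
#'   the schema as an attribute.
#' @export
as_claims <- function(data, schema) {
  stopifnot(inherits(schema, "claims_schema"))
  needed <- c(schema$entity_id, schema$categorical, schema$numerical, schema$period)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("claims table is missing schema column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "claimscope_schema_error")
  }
  out <- as_tibble(data)[needed]
  ids <- as.character(out[[schema$entity_id]])
  if (anyNA(ids) || any(!nzchar(ids))) {
    abort("entity IDs must be non-empty", class = "claimscope_schema_error")
  }
  out[[schema$entity_id]] <- ids
  for (col in schema$categorical) {
    v <- as.character(out[[col]])
    v[is.na(v)] <- "__missing__"
    out[[col]] <- v
  }
  for (col in schema$numerical) {
    v <- out[[col]]
    if (!is.numeric(v)) {
      abort(paste0("numerical column '", col, "' is not numeric"),
            class = "claimscope_schema_error")
    }
    if (any(is.infinite(v))) {
      abort(paste0("numerical column '", col, "' contains non-finite values"),
            class = "claimscope_schema_error")
    }
    out[[col]] <- as.numeric(v)
  }
  structure(out, schema = schema, class = c("claims_tbl", class(out)))
}

#' Read a delimited claims file
#'
#' Thin wrapper around [readr::read_delim()] that validates the result against
#' a schema. The dialect (delimiter, quote, decimal mark) is configurable so
#' that e.g. semicolon-separated files with decimal commas parse correctly.
#' Unparseable numeric cells are a row-level error reporting the offending
#' line; missing cells are recorded as missing, not zero.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema A [claims_schema()].
#' @param delim Field delimiter (default `","`).
#' @param quote Quote character.
#' @param decimal_mark Decimal mark for numeric parsing (default `"."`).
#' @return A validated `claims_tbl` with row order preserved.
#' @export
read_claims <- function(path, schema, delim = ",", quote = "\"", decimal_mark = ".") {
  if (!file.exists(path)) {
    abort(paste0("claims file not found: ", path))
  }
  grouping_mark <- if (identical(decimal_mark, ",")) "." else ","
  loc <- readr::locale(decimal_mark = decimal_mark, grouping_mark = grouping_mark)
  col_types <- do.call(readr::cols, c(
    setNames(rep(list(readr::col_character()),
                 length(c(schema$entity_id, schema$categorical, schema$period))),
             c(schema$entity_id, schema$categorical, schema$period)),
    setNames(rep(list(readr::col_double()), length(schema$numerical)),
             schema$numerical),
    list(.default = readr::col_character())
  ))
  raw <- suppressWarnings(
    readr::read_delim(path, delim = delim, quote = quote, locale = loc,
                      col_types = col_types, progress = FALSE,
                      show_col_types = FALSE)
  )
  header <- names(raw)
  missing_cols <- setdiff(c(schema$entity_id, schema$categorical,
                            schema$numerical, schema$period), header)
  if (length(missing_cols) > 0L) {
    abort(paste0("claims file is missing schema column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "claimscope_schema_error")
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    p <- probs[1, ]
    abort(paste0("unparseable value in '", path, "' at line ", p$row,
                 ": expected ", p$expected, ", got '", p$actual, "'"),
          class = "claimscope_parse_error")
  }
  as_claims(raw, schema)
}

#' Retrieve the schema attached to a claims table
#' @param claims A `claims_tbl`.
#' @return The [claims_schema()] the table was validated against.
#' @export
claims_schema_of <- function(claims) {
  sc <- attr(claims, "schema")
  if (is.null(sc)) abort("not a claims table: no schema attribute")
  sc
}

#' Drop low-activity entities
#'
#' Retains only entities with strictly more than `min_actions` recorded
#' actions. The strict inequality mirrors the convention of keeping providers
#' with "more than" a threshold number of entries: an entity with exactly
#' `min_actions` rows is removed. With `per_period = TRUE` (requires a period
#' column in the schema) every period in which the entity appears must exceed
#' the threshold.
#'
#' @param claims A `claims_tbl`.
#' @param min_actions Threshold (default 50); entities must have `>` this many
#'   rows. `0` keeps everyone.
#' @param per_period Apply the threshold within every covered period instead of
#'   overall.
#' @return The filtered `claims_tbl` (schema preserved).
#' @export
filter_min_actions <- function(claims, min_actions = 50, per_period = FALSE) {
  schema <- claims_schema_of(claims)
  stopifnot(min_actions >= 0)
  ids <- claims[[schema$entity_id]]
  if (per_period) {
    if (is.null(schema$period)) {
      abort("per_period filtering requires a period column in the schema",
            class = "claimscope_config_error")
    }
    tab <- table(ids, claims[[schema$period]])
    # every covered (nonzero) period must exceed the threshold
    ok <- apply(tab, 1, function(r) all(r[r > 0] > min_actions))
    keep_ids <- rownames(tab)[ok]
  } else {
    tab <- table(ids)
    keep_ids <- names(tab)[tab > min_actions]
  }
  out <- claims[ids %in% keep_ids, , drop = FALSE]
  structure(out, schema = schema, class = class(claims))
}
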