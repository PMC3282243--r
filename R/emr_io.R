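#' Write an EMR database to disk
#'
#' The on-disk representation is one RFC-4180 CSV file per module
#' (`patients.csv`, `contacts.csv`, ...) plus a `manifest.json` carrying the
#' store period, per-module row counts and a schema version. Dates are
#' ISO-8601, booleans the lowercase literals `true`/`false`, everything
#' UTF-8. The format is diffable and language neutral; soft-deleted entries
#' are written like any other row so that persistence never drops them.
#'
#' @param db An `emr_database`.
#' @param path Directory to write into (created if absent).
#' @return `path`, invisibly.
#' @seealso [load_database()]
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "emr_database"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (m in EMR_MODULES) {
    tab <- db[[m]]
    out <- as.data.frame(tab)
    for (col in names(out)) {
      if (is.logical(out[[col]])) {
        out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                             ifelse(out[[col]], "true", "false"))
      }
    }
    readr::write_csv(out, file.path(path, paste0(m, ".csv")), na = "")
  }
  manifest <- list(
    format = "registerforge-emr",
    schema_version = 1L,
    period = as.character(db$period),
    counts = lapply(db[EMR_MODULES], nrow)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load an EMR database from disk
#'
#' Reads the directory layout produced by [write_database()].
#' `load_database(write_database(db, p))` is the identity field-for-field,
#' including `deleted` flags. A missing module file is an error naming the
#' module; an unparseable value is an error naming the file and row.
#'
#' @param path Directory containing the module CSV files and
#'   `manifest.json`.
#' @return An `emr_database`.
#' @export
load_database <- function(path) {
  manifest_file <- file.path(path, "manifest.json")
  if (!file.exists(manifest_file)) {
    stopf("no manifest.json in '%s'; not an EMR database directory", path)
  }
  manifest <- jsonlite::read_json(manifest_file)
  schema <- emr_schema()
  tabs <- list()
  for (m in EMR_MODULES) {
    f <- file.path(path, paste0(m, ".csv"))
    if (!file.exists(f)) {
      stopf("module file missing: '%s' (module '%s')", f, m)
    }
    proto <- schema[[m]]
    spec <- lapply(proto, function(col) {
      if (inherits(col, "Date")) {
        readr::col_date(format = "%Y-%m-%d")
      } else if (is.integer(col)) {
        readr::col_integer()
      } else if (is.double(col)) {
        readr::col_double()
      } else if (is.logical(col)) {
        readr::col_logical()
      } else {
        readr::col_character()
      }
    })
    tab <- readr::read_csv(f, col_types = do.call(readr::cols, spec),
                           na = "", progress = FALSE,
                           show_col_types = FALSE)
    probs <- readr::problems(tab)
    if (nrow(probs) > 0) {
      stopf("parse error in '%s': row %d, column %d (%s)",
            f, probs$row[1], probs$col[1], probs$expected[1])
    }
    missing_cols <- setdiff(names(proto), names(tab))
    if (length(missing_cols) > 0) {
      stopf("module '%s' lacks column(s): %s", m,
            paste(missing_cols, collapse = ", "))
    }
    tabs[[m]] <- tab[, names(proto)]
  }
  period <- as.Date(unlist(manifest$period))
  do.call(emr_database, c(tabs, list(period = period)))
}
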