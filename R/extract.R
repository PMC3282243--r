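#' Extraction specification for the nine-table register
#'
#' Declares what step 2 of the extraction materializes: which of the nine
#' register tables, which narrative subheadings, an optional date window,
#' and whether soft-deleted entries are emitted. `include_deleted = TRUE`
#' reproduces the behaviour of an extraction tool reading the physical
#' store (deleted entries come out like any others, marked only in
#' provenance); `FALSE` reproduces the normal record view.
#'
#' @param tables Character vector of register table names; defaults to all
#'   nine (`Contacts`, `Diagnosis`, `Biometrics`, `Documents`, `Drugs`,
#'   `Biochemical analysis`, `Measurement`, `Patients`, `Terminology`).
#' @param subheadings Narrative subheadings to extract into `Terminology`;
#'   `"*"` selects every subheading present. Must be non-empty when
#'   `Terminology` is selected.
#' @param date_range Optional length-2 Date vector restricting dated rows.
#' @param include_deleted Emit soft-deleted entries?
#' @return An `extraction_spec` object.
#' @export
extraction_spec <- function(tables = unname(REGISTER_TABLES),
                            subheadings = "*",
                            date_range = NULL,
                            include_deleted = TRUE) {
  unknown <- setdiff(tables, REGISTER_TABLES)
  if (length(unknown) > 0) {
    stopf("unknown register table(s): %s", paste(unknown, collapse = ", "))
  }
  if ("Terminology" %in% tables && length(subheadings) == 0) {
    stopf("subheadings must be non-empty when Terminology is selected")
  }
  if (!is.null(date_range)) {
    date_range <- as.Date(date_range)
    stopifnot(length(date_range) == 2, date_range[1] <= date_range[2])
  }
  structure(list(tables = tables, subheadings = subheadings,
                 date_range = date_range,
                 include_deleted = isTRUE(include_deleted)),
            class = "extraction_spec")
}

#' Materialize the nine-table register (step 2)
#'
#' Extracts the spec-selected data for exactly the PINs of a caseset into
#' the nine register tables. Rows are date-sorted within each table with
#' ties keeping source order; every row carries its PIN, a stable item
#' identifier (module, PIN, date, within-day ordinal) and a `deleted`
#' provenance flag. The caseset must have been computed on the same
#' database (content fingerprints are compared), otherwise a stale-caseset
#' error is raised.
#'
#' @param db An `emr_database`.
#' @param caseset A `case_set` from [find_cases()] (or a character vector
#'   of PINs, in which case no fingerprint check is possible).
#' @param spec An [extraction_spec()].
#' @return A `register`: named list of tibbles, one per selected table
#'   (always all nine names present; unselected tables are empty).
#' @export
extract_register <- function(db, caseset, spec = extraction_spec()) {
  stopifnot(inherits(db, "emr_database"), inherits(spec, "extraction_spec"))
  if (inherits(caseset, "case_set")) {
    fp <- attr(caseset, "fingerprint")
    if (!is.null(fp) && !identical(fp, db_fingerprint(db))) {
      stopf("stale caseset: it was not derived from this database")
    }
  }
  pins <- case_pins(caseset)
  out <- stats::setNames(vector("list", length(REGISTER_TABLES)),
                         unname(REGISTER_TABLES))
  for (m in EMR_MODULES) {
    tname <- REGISTER_TABLES[[m]]
    src <- db[[m]]
    ids <- item_ids(m, src)
    keep <- src$pin %in% pins
    if (!(tname %in% spec$tables)) {
      keep <- rep(FALSE, nrow(src))
    }
    if (m != "patients") {
      if (!spec$include_deleted) {
        keep <- keep & !src$deleted
      }
      if (!is.null(spec$date_range)) {
        keep <- keep & src$date >= spec$date_range[1] &
          src$date <= spec$date_range[2]
      }
      if (m == "narrative" && !identical(spec$subheadings, "*")) {
        keep <- keep & src$subheading %in% spec$subheadings
      }
    }
    tab <- src[keep, , drop = FALSE]
    tab <- tibble::add_column(tab, item_id = ids[keep], .before = 1)
    if (m == "patients") {
      tab <- tab[order(tab$pin), , drop = FALSE]
      tab$deleted <- rep(FALSE, nrow(tab))
    } else {
      tab <- tab[order(tab$date, seq_len(nrow(tab))), , drop = FALSE]
    }
    out[[tname]] <- tab
  }
  structure(out,
            pins = sort(unique(pins)),
            spec = spec,
            fingerprint = db_fingerprint(db),
            class = "register")
}

#' Extract narrative journal text by subheading
#'
#' Returns the `Terminology` register table: the narrative entries of the
#' caseset's PINs whose subheading is among those selected, date-sorted.
#'
#' @inheritParams extract_register
#' @param subheadings Non-empty character vector of subheadings, or `"*"`
#'   for all.
#' @return A tibble (the `Terminology` table).
#' @export
extract_narrative <- function(db, caseset, subheadings) {
  if (length(subheadings) == 0) {
    stopf("subheadings must be non-empty")
  }
  reg <- extract_register(db, caseset,
                          extraction_spec(tables = "Terminology",
                                          subheadings = subheadings))
  reg[["Terminology"]]
}

#' @export
print.register <- function(x, ...) {
  cat(sprintf("<register> %d PIN(s)\n", length(attr(x, "pins"))))
  for (tname in names(x)) {
    cat(sprintf("  %-21s %6d rows\n", tname, nrow(x[[tname]])))
  }
  invisible(x)
}

#' Total number of items (rows) in a register
#' @param register A `register`.
#' @return Integer row count over all nine tables.
#' @export
register_item_count <- function(register) {
  sum(vapply(register, nrow, integer(1)))
}

#' Write a register to disk
#'
#' One CSV per register table (named exactly as the table) plus a
#' `provenance.json` sidecar mapping every item identifier to its source
#' module and deleted flag.
#'
#' @param register A `register`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_register <- function(register, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  prov <- list()
  for (tname in names(register)) {
    tab <- as.data.frame(register[[tname]])
    for (col in names(tab)) {
      if (is.logical(tab[[col]])) {
        tab[[col]] <- ifelse(tab[[col]], "true", "false")
      }
    }
    readr::write_csv(tab, file.path(path, paste0(tname, ".csv")), na = "")
    prov[[tname]] <- list(
      items = register[[tname]]$item_id,
      deleted = register[[tname]]$deleted
    )
  }
  jsonlite::write_json(prov, file.path(path, "provenance.json"),
                       auto_unbox = FALSE)
  invisible(path)
}
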