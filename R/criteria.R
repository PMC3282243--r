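#' Laboratory threshold rule
#'
#' One rule of the laboratory inclusion criterion: an entry qualifies when
#' the analyte, specimen, unit and (if required) fasting status match and
#' the measured value satisfies `comparator threshold`.
#'
#' @param analyte Analyte name (matched case-insensitively).
#' @param specimen `"blood"` or `"plasma"`.
#' @param comparator `">="` or `">"`.
#' @param threshold Positive decimal threshold.
#' @param unit Unit string the entry must carry (e.g. `"mmol/L"`); entries
#'   in a different unit are skipped with a warning rather than compared.
#' @param require_fasting Must the entry be flagged as fasting?
#' @return A one-row tibble usable in [inclusion_criteria()].
#' @export
lab_rule <- function(analyte, specimen, comparator = ">=", threshold,
                     unit = "mmol/L", require_fasting = TRUE) {
  stopifnot(specimen %in% c("blood", "plasma"),
            comparator %in% c(">=", ">"))
  if (!is.numeric(threshold) || threshold <= 0) {
    stopf("lab rule threshold must be > 0")
  }
  tibble::tibble(
    analyte = analyte, specimen = specimen, comparator = comparator,
    threshold = as.double(threshold), unit = unit,
    require_fasting = isTRUE(require_fasting)
  )
}

#' Declarative case definition
#'
#' Bundles the three criterion families of rule-based case finding --
#' version-qualified ICD code prefixes, ATC code prefixes, and laboratory
#' threshold rules -- together with the deletion-handling mode. Under
#' `"deletion_blind"` soft-deleted entries still count towards inclusion
#' (the behaviour of an extraction tool reading the physical store); under
#' `"deletion_aware"` they are ignored (the behaviour of the EMR's own
#' search engine, which respects caregiver deletions).
#'
#' @param icd_patterns Data frame with columns `version` (9 or 10) and
#'   `prefix`, or `NULL` to skip the criterion.
#' @param atc_prefixes Character vector of ATC code prefixes, or `NULL`.
#' @param lab_rules Tibble of rules from [lab_rule()], or `NULL`.
#' @param deletion_mode `"deletion_blind"` or `"deletion_aware"`.
#' @return An `inclusion_criteria` object.
#' @export
inclusion_criteria <- function(icd_patterns = NULL, atc_prefixes = NULL,
                               lab_rules = NULL,
                               deletion_mode = c("deletion_blind",
                                                 "deletion_aware")) {
  deletion_mode <- match.arg(deletion_mode)
  if (!is.null(icd_patterns)) {
    icd_patterns <- tibble::as_tibble(icd_patterns)
    stopifnot(all(c("version", "prefix") %in% names(icd_patterns)))
    icd_patterns$version <- as.integer(icd_patterns$version)
    stopifnot(all(icd_patterns$version %in% c(9L, 10L)))
    if (nrow(icd_patterns) == 0) icd_patterns <- NULL
  }
  if (!is.null(atc_prefixes) && length(atc_prefixes) == 0) atc_prefixes <- NULL
  if (!is.null(lab_rules)) {
    lab_rules <- tibble::as_tibble(lab_rules)
    if (nrow(lab_rules) == 0) lab_rules <- NULL
  }
  if (is.null(icd_patterns) && is.null(atc_prefixes) && is.null(lab_rules)) {
    stopf("at least one criterion family must be non-empty")
  }
  structure(
    list(icd_patterns = icd_patterns, atc_prefixes = atc_prefixes,
         lab_rules = lab_rules, deletion_mode = deletion_mode),
    class = "inclusion_criteria"
  )
}

#' Default type 2 diabetes case definition
#'
#' ICD-10 prefix E11 and ICD-9 prefix 250 for the diagnosis criterion, ATC
#' prefix A10B (oral blood-glucose-lowering drugs) for the prescription
#' criterion, and the WHO 1999 fasting glucose thresholds for the
#' laboratory criterion: fasting plasma glucose >= 7.0 mmol/L or fasting
#' whole-blood glucose >= 6.1 mmol/L. All parts are ordinary data and can
#' be replaced for other phenotypes.
#'
#' @param deletion_mode Passed to [inclusion_criteria()].
#' @return An `inclusion_criteria` object.
#' @export
t2dm_criteria <- function(deletion_mode = c("deletion_blind",
                                            "deletion_aware")) {
  inclusion_criteria(
    icd_patterns = tibble::tibble(version = c(10L, 9L),
                                  prefix = c("E11", "250")),
    atc_prefixes = "A10B",
    lab_rules = dplyr::bind_rows(
      lab_rule("glucose", "plasma", ">=", 7.0, "mmol/L", TRUE),
      lab_rule("glucose", "blood", ">=", 6.1, "mmol/L", TRUE)
    ),
    deletion_mode = match.arg(deletion_mode)
  )
}

#' @export
print.inclusion_criteria <- function(x, ...) {
  cat("<inclusion_criteria> mode:", x$deletion_mode, "\n")
  if (!is.null(x$icd_patterns)) {
    cat("  ICD:", paste(sprintf("ICD-%d %s", x$icd_patterns$version,
                                x$icd_patterns$prefix), collapse = ", "), "\n")
  }
  if (!is.null(x$atc_prefixes)) {
    cat("  ATC:", paste(x$atc_prefixes, collapse = ", "), "\n")
  }
  if (!is.null(x$lab_rules)) {
    cat(sprintf("  Lab: %d rule(s)\n", nrow(x$lab_rules)))
  }
  invisible(x)
}
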