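# Rows of a deletable module that count for case finding under the
# criteria's deletion mode: deletion_blind sees everything physically
# stored, deletion_aware only what survives caregiver deletion.
visible_rows <- function(tab, deletion_mode) {
  if (deletion_mode == "deletion_blind") {
    rep(TRUE, nrow(tab))
  } else {
    !tab$deleted
  }
}

match_prefix <- function(codes, prefixes) {
  codes <- norm_code(codes)
  hit <- rep(FALSE, length(codes))
  for (p in norm_code(prefixes)) {
    hit <- hit | startsWith(codes, p)
  }
  hit
}

# Logical vector over diagnosis rows matching any version-qualified prefix.
diagnosis_matches <- function(diagnoses, icd_patterns) {
  hit <- rep(FALSE, nrow(diagnoses))
  for (i in seq_len(nrow(icd_patterns))) {
    hit <- hit | (diagnoses$icd_version == icd_patterns$version[i] &
                    match_prefix(diagnoses$code, icd_patterns$prefix[i]))
  }
  hit
}

lab_matches <- function(labs, lab_rules, warn_units = TRUE) {
  hit <- rep(FALSE, nrow(labs))
  for (i in seq_len(nrow(lab_rules))) {
    r <- lab_rules[i, ]
    candidate <- tolower(trimws(labs$analyte)) == tolower(trimws(r$analyte)) &
      labs$specimen == r$specimen &
      (!r$require_fasting | labs$fasting)
    unit_ok <- tolower(trimws(labs$unit)) == tolower(trimws(r$unit))
    skipped <- candidate & !unit_ok
    if (warn_units && any(skipped)) {
      warnf("%d lab entr%s skipped: unit differs from rule unit '%s'",
            sum(skipped), if (sum(skipped) == 1) "y" else "ies", r$unit)
    }
    ok <- if (r$comparator == ">=") {
      labs$value >= r$threshold
    } else {
      labs$value > r$threshold
    }
    hit <- hit | (candidate & unit_ok & ok)
  }
  hit
}

#' Evaluate one inclusion criterion
#'
#' Each evaluator returns the set of PINs with at least one qualifying
#' entry, honouring the criteria's deletion mode: soft-deleted entries
#' count only under `deletion_blind`. Code matching is by
#' version-qualified prefix, case-insensitive and whitespace-trimmed; a
#' laboratory entry qualifies when analyte, specimen, unit and fasting
#' status match a rule and the value satisfies the rule's comparator.
#'
#' @param db An `emr_database`.
#' @param criteria An [inclusion_criteria()] object.
#' @return Character vector of PINs (empty, with a message, when the
#'   criterion family is not configured).
#' @name criterion-evaluators
NULL

#' @rdname criterion-evaluators
#' @export
evaluate_icd_criterion <- function(db, criteria) {
  if (is.null(criteria$icd_patterns)) {
    message("ICD criterion not configured; skipped")
    return(character())
  }
  x <- db$diagnoses
  keep <- visible_rows(x, criteria$deletion_mode) &
    diagnosis_matches(x, criteria$icd_patterns)
  unique(x$pin[keep])
}

#' @rdname criterion-evaluators
#' @export
evaluate_atc_criterion <- function(db, criteria) {
  if (is.null(criteria$atc_prefixes)) {
    message("ATC criterion not configured; skipped")
    return(character())
  }
  x <- db$drugs
  keep <- visible_rows(x, criteria$deletion_mode) &
    match_prefix(x$atc_code, criteria$atc_prefixes)
  unique(x$pin[keep])
}

#' @rdname criterion-evaluators
#' @export
evaluate_lab_criterion <- function(db, criteria) {
  if (is.null(criteria$lab_rules)) {
    message("laboratory criterion not configured; skipped")
    return(character())
  }
  x <- db$labs
  keep <- visible_rows(x, criteria$deletion_mode) &
    lab_matches(x, criteria$lab_rules)
  unique(x$pin[keep])
}

#' Find cases: step 1 of the extraction process
#'
#' Identifies the PINs meeting at least one inclusion criterion and records,
#' per PIN, which of the three criterion families matched. The result is
#' the substrate for the register extraction (step 2), for the Venn
#' partition of overlapping criteria, and for diagnostic accuracy
#' comparisons between deletion-handling modes.
#'
#' @param db An `emr_database`.
#' @param criteria An [inclusion_criteria()] object.
#' @return A `case_set`: a tibble with columns `pin`, `by_icd`, `by_atc`,
#'   `by_lab` (one row per included PIN), carrying the criteria and a
#'   fingerprint of `db` as attributes.
#' @examples
#' db <- emr_database(
#'   patients = data.frame(pin = "P1", gender = "male", birth_year = 1940L,
#'                         alive = TRUE, record_opened = as.Date("1994-05-01")),
#'   diagnoses = data.frame(pin = "P1", date = as.Date("2001-02-03"),
#'                          icd_version = 10L, code = "E11.9",
#'                          name = "T2DM", deleted = FALSE)
#' )
#' find_cases(db, t2dm_criteria())
#' @export
find_cases <- function(db, criteria) {
  stopifnot(inherits(db, "emr_database"), inherits(criteria, "inclusion_criteria"))
  by_icd <- if (is.null(criteria$icd_patterns)) character() else
    evaluate_icd_criterion(db, criteria)
  by_atc <- if (is.null(criteria$atc_prefixes)) character() else
    evaluate_atc_criterion(db, criteria)
  by_lab <- if (is.null(criteria$lab_rules)) character() else
    evaluate_lab_criterion(db, criteria)
  pins <- sort(unique(c(by_icd, by_atc, by_lab)))
  cs <- tibble::tibble(
    pin = pins,
    by_icd = pins %in% by_icd,
    by_atc = pins %in% by_atc,
    by_lab = pins %in% by_lab
  )
  structure(cs,
            criteria = criteria,
            fingerprint = db_fingerprint(db),
            class = c("case_set", class(cs)))
}

#' @export
print.case_set <- function(x, ...) {
  crit <- attr(x, "criteria")
  cat(sprintf("<case_set> %d PIN(s), mode %s\n", nrow(x),
              if (is.null(crit)) "?" else crit$deletion_mode))
  cat(sprintf("  by ICD %d | by ATC %d | by lab %d\n",
              sum(x$by_icd), sum(x$by_atc), sum(x$by_lab)))
  invisible(x)
}

case_pins <- function(x) {
  if (inherits(x, "case_set") || is.data.frame(x)) x$pin else as.character(x)
}
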