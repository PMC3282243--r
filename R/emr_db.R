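# The nine source modules of the EMR store, and the register table each one
# feeds. "labs" holds biochemical analyses; "narrative" the free text filed
# under subheadings in the core journal.
EMR_MODULES <- c(
  "patients", "contacts", "diagnoses", "drugs", "labs",
  "biometrics", "documents", "measurements", "narrative"
)

REGISTER_TABLES <- c(
  patients = "Patients",
  contacts = "Contacts",
  diagnoses = "Diagnosis",
  drugs = "Drugs",
  labs = "Biochemical analysis",
  biometrics = "Biometrics",
  documents = "Documents",
  measurements = "Measurement",
  narrative = "Terminology"
)

GENDERS <- c("female", "male", "unknown")
CONTACT_TYPES <- c("doctor", "nurse", "telephone", "administrative")
SPECIMENS <- c("blood", "plasma", "other")

# Column templates: prototypes with zero rows define both the schema and the
# CSV column types.
emr_schema <- function() {
  list(
    patients = tibble::tibble(
      pin = character(), gender = character(), birth_year = integer(),
      alive = logical(), record_opened = as.Date(character())
    ),
    contacts = tibble::tibble(
      pin = character(), date = as.Date(character()), contact_type = character(),
      user_id = character(), deleted = logical()
    ),
    diagnoses = tibble::tibble(
      pin = character(), date = as.Date(character()), icd_version = integer(),
      code = character(), name = character(), deleted = logical()
    ),
    drugs = tibble::tibble(
      pin = character(), date = as.Date(character()), drug_name = character(),
      atc_code = character(), iteration = integer(), dosage = character(),
      deleted = logical()
    ),
    labs = tibble::tibble(
      pin = character(), date = as.Date(character()), analyte = character(),
      value = double(), unit = character(), fasting = logical(),
      specimen = character(), deleted = logical()
    ),
    biometrics = tibble::tibble(
      pin = character(), date = as.Date(character()), weight = double(),
      height = double(), bmi = double(), deleted = logical()
    ),
    documents = tibble::tibble(
      pin = character(), date = as.Date(character()), doc_type = character(),
      text = character(), deleted = logical()
    ),
    measurements = tibble::tibble(
      pin = character(), date = as.Date(character()), name = character(),
      value = double(), unit = character(), deleted = logical()
    ),
    narrative = tibble::tibble(
      pin = character(), date = as.Date(character()), subheading = character(),
      text = character(), deleted = logical()
    )
  )
}

#' Assemble an EMR database
#'
#' An `emr_database` is the in-memory form of a multi-module patient record
#' store: one `patients` table plus one table per clinical module (contacts,
#' diagnoses, drug prescriptions, biochemical analyses, biometrics,
#' documents, measurements, and narrative journal text filed under
#' subheadings). Every clinical entry carries a `deleted` flag implementing
#' soft deletion: a caregiver-deleted entry stays physically present but is
#' hidden from the normal record view.
#'
#' Missing modules are filled with empty tables of the correct schema;
#' supplied tables are coerced column-by-column to the schema types.
#'
#' @param ... Named data frames, one per module; any of `patients`,
#'   `contacts`, `diagnoses`, `drugs`, `labs`, `biometrics`, `documents`,
#'   `measurements`, `narrative`.
#' @param period Length-2 Date vector (start, end) of the record-keeping
#'   period the store covers.
#' @return An object of class `emr_database`: a named list of tibbles plus a
#'   `period`.
#' @examples
#' db <- emr_database(
#'   patients = data.frame(
#'     pin = "P1", gender = "female", birth_year = 1950L,
#'     alive = TRUE, record_opened = as.Date("1995-03-01")
#'   ),
#'   period = as.Date(c("1993-01-01", "2005-12-31"))
#' )
#' validate_database(db)
#' @export
emr_database <- function(..., period = as.Date(c("1993-01-01", "2005-12-31"))) {
  supplied <- list(...)
  schema <- emr_schema()
  bad <- setdiff(names(supplied), EMR_MODULES)
  if (length(bad) > 0) {
    stopf("unknown EMR module(s): %s", paste(bad, collapse = ", "))
  }
  period <- as.Date(period)
  if (length(period) != 2 || anyNA(period) || period[1] > period[2]) {
    stopf("period must be two ordered dates")
  }
  db <- lapply(EMR_MODULES, function(m) {
    proto <- schema[[m]]
    x <- supplied[[m]]
    if (is.null(x)) {
      return(proto)
    }
    x <- tibble::as_tibble(x)
    missing_cols <- setdiff(names(proto), names(x))
    if (length(missing_cols) > 0) {
      stopf("module '%s' is missing column(s): %s", m,
            paste(missing_cols, collapse = ", "))
    }
    x <- x[, names(proto)]
    for (col in names(proto)) {
      x[[col]] <- coerce_like(x[[col]], proto[[col]], m, col)
    }
    x
  })
  names(db) <- EMR_MODULES
  structure(list2env_as_list(db, period), class = "emr_database")
}

list2env_as_list <- function(db, period) {
  c(db, list(period = period))
}

coerce_like <- function(x, proto, module, col) {
  if (inherits(proto, "Date")) {
    as.Date(x)
  } else if (is.integer(proto)) {
    as.integer(x)
  } else if (is.double(proto)) {
    as.double(x)
  } else if (is.logical(proto)) {
    as.logical(x)
  } else {
    as.character(x)
  }
}

#' @export
print.emr_database <- function(x, ...) {
  cat(sprintf(
    "<emr_database> %s .. %s\n",
    format(x$period[1]), format(x$period[2])
  ))
  for (m in EMR_MODULES) {
    cat(sprintf("  %-13s %6d rows\n", m, nrow(x[[m]])))
  }
  invisible(x)
}

#' Number of patients in a database
#' @param db An `emr_database`.
#' @return Integer count of patient records.
#' @export
n_patients <- function(db) nrow(db$patients)

event_modules <- function() setdiff(EMR_MODULES, "patients")

#' Check an EMR database against its schema invariants
#'
#' Violations are returned as data, not raised as errors: an audit of a
#' record store should enumerate every problem, not stop at the first.
#' Checked rules: PIN uniqueness in `patients`; referential integrity of
#' every clinical entry's PIN; all dates (including `record_opened`) within
#' the store period; enumerated fields (`gender`, `contact_type`,
#' `specimen`) drawn from their allowed values; diagnosis codes non-empty
#' with `icd_version` consistent with code syntax (leading digit = ICD-9,
#' leading letter = ICD-10); lab values finite and non-negative;
#' prescription iteration non-negative; and BMI consistent with
#' weight/height to within 0.1 kg/m2 when all three are recorded.
#'
#' @param db An `emr_database`.
#' @return A tibble with one row per violation (`module`, `row`, `pin`,
#'   `field`, `rule`); zero rows when the database is well formed.
#' @export
validate_database <- function(db) {
  stopifnot(inherits(db, "emr_database"))
  out <- list()
  add <- function(module, rows, pins, field, rule) {
    if (length(rows) == 0) {
      return()
    }
    out[[length(out) + 1]] <<- tibble::tibble(
      module = module, row = as.integer(rows), pin = as.character(pins),
      field = field, rule = rule
    )
  }

  p <- db$patients
  dup <- which(duplicated(p$pin) | duplicated(p$pin, fromLast = TRUE))
  add("patients", dup, p$pin[dup], "pin", "pin must be unique")
  bad <- which(!(p$gender %in% GENDERS))
  add("patients", bad, p$pin[bad], "gender",
      "gender must be one of female/male/unknown")
  bad <- which(is.na(p$record_opened) | p$record_opened < db$period[1] |
                 p$record_opened > db$period[2])
  add("patients", bad, p$pin[bad], "record_opened",
      "record_opened must lie within the store period")

  known <- unique(p$pin)
  for (m in event_modules()) {
    x <- db[[m]]
    if (nrow(x) == 0) {
      next
    }
    bad <- which(!(x$pin %in% known))
    add(m, bad, x$pin[bad], "pin", "entry pin not present in patients")
    bad <- which(is.na(x$date) | x$date < db$period[1] | x$date > db$period[2])
    add(m, bad, x$pin[bad], "date", "entry date outside the store period")
  }

  x <- db$contacts
  bad <- which(!(x$contact_type %in% CONTACT_TYPES))
  add("contacts", bad, x$pin[bad], "contact_type",
      "contact_type must be doctor/nurse/telephone/administrative")

  x <- db$diagnoses
  bad <- which(is.na(x$code) | trimws(x$code) == "")
  add("diagnoses", bad, x$pin[bad], "code", "diagnosis code must be non-empty")
  bad <- which(!(x$icd_version %in% c(9L, 10L)))
  add("diagnoses", bad, x$pin[bad], "icd_version", "icd_version must be 9 or 10")
  lead <- substr(trimws(x$code), 1, 1)
  bad <- which(
    (grepl("^[0-9]$", lead) & x$icd_version != 9L) |
      (grepl("^[A-Za-z]$", lead) & x$icd_version != 10L)
  )
  add("diagnoses", bad, x$pin[bad], "icd_version",
      "icd_version inconsistent with code syntax")

  x <- db$drugs
  bad <- which(is.na(x$iteration) | x$iteration < 0L)
  add("drugs", bad, x$pin[bad], "iteration", "iteration must be non-negative")

  x <- db$labs
  bad <- which(!is.finite(x$value) | x$value < 0)
  add("labs", bad, x$pin[bad], "value",
      "lab value must be finite and non-negative")
  bad <- which(!(x$specimen %in% SPECIMENS))
  add("labs", bad, x$pin[bad], "specimen",
      "specimen must be blood/plasma/other")

  x <- db$biometrics
  if (nrow(x) > 0) {
    full <- !is.na(x$weight) & !is.na(x$height) & !is.na(x$bmi)
    expected <- x$weight / (x$height / 100)^2
    bad <- which(full & abs(x$bmi - expected) > 0.1)
    add("biometrics", bad, x$pin[bad], "bmi",
        "bmi inconsistent with weight/height (tolerance 0.1)")
  }

  if (length(out) == 0) {
    return(tibble::tibble(
      module = character(), row = integer(), pin = character(),
      field = character(), rule = character()
    ))
  }
  dplyr::bind_rows(out)
}

# Content fingerprint used to detect stale casesets (a caseset must be
# evaluated against the same database it is later extracted from).
db_fingerprint <- function(db) {
  rlang::hash(list(
    period = as.character(db$period),
    tables = lapply(db[EMR_MODULES], as.data.frame)
  ))
}

# Deterministic per-entry identifiers: (module, pin, date, ordinal within
# that pin and day, in source order). Stable join key between a register row
# and its source entry.
item_ids <- function(module, tab) {
  if (nrow(tab) == 0) {
    return(character())
  }
  if (module == "patients") {
    return(sprintf("patients:%s", tab$pin))
  }
  key <- paste(tab$pin, format(tab$date), sep = "|")
  ord <- stats::ave(seq_len(nrow(tab)), key, FUN = seq_along)
  sprintf("%s:%s:%s:%03d", module, tab$pin, format(tab$date), ord)
}
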