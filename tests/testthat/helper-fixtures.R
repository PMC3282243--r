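# Hand-built three-patient database: one diagnosis case, one prescription
# case, one criterion-free patient.
tiny_db <- function() {
  emr_database(
    patients = data.frame(
      pin = c("T1", "T2", "T3"),
      gender = c("female", "male", "female"),
      birth_year = c(1940L, 1955L, 1972L),
      alive = c(TRUE, TRUE, FALSE),
      record_opened = as.Date(c("1994-02-01", "1998-07-15", "2003-11-30"))
    ),
    contacts = data.frame(
      pin = c("T1", "T1", "T2"),
      date = as.Date(c("1995-01-10", "1999-06-01", "2000-03-05")),
      contact_type = c("doctor", "nurse", "telephone"),
      user_id = c("U01", "U02", "U01"),
      deleted = FALSE
    ),
    diagnoses = data.frame(
      pin = c("T1", "T2"),
      date = as.Date(c("1995-01-10", "2000-03-05")),
      icd_version = c(10L, 10L),
      code = c("E11.9", "I10"),
      name = c("Type 2 diabetes mellitus", "Essential hypertension"),
      deleted = FALSE
    ),
    drugs = data.frame(
      pin = "T2", date = as.Date("2000-03-05"), drug_name = "Metformin",
      atc_code = "A10BA02", iteration = 1L, dosage = "500 mg 1x2",
      deleted = FALSE
    ),
    labs = data.frame(
      pin = c("T1", "T3"),
      date = as.Date(c("1995-01-10", "2004-02-02")),
      analyte = "glucose", value = c(6.2, 5.1), unit = "mmol/L",
      fasting = c(TRUE, TRUE), specimen = c("plasma", "plasma"),
      deleted = FALSE
    ),
    narrative = data.frame(
      pin = c("T1", "T1", "T2"),
      date = as.Date(c("1995-01-10", "1996-04-20", "2000-03-05")),
      subheading = c("heritage", "smoking habit", "heritage"),
      text = c("Mother had diabetes.", "Non-smoker.", "No heredity."),
      deleted = FALSE
    )
  )
}

# Small randomized database with overlapping criteria and soft deletions,
# built directly (independent of the synthetic generator) for oracle and
# property tests.
random_small_db <- function(seed, n_pat = 8) {
  set.seed(seed)
  pins <- sprintf("R%02d", seq_len(n_pat))
  rdate <- function(k) as.Date("1993-01-01") + sample(0:4700, k, replace = TRUE)
  nd <- sample(5:15, 1)
  nr <- sample(5:15, 1)
  nl <- sample(5:15, 1)
  emr_database(
    patients = data.frame(
      pin = pins, gender = sample(c("female", "male"), n_pat, TRUE),
      birth_year = sample(1910:1990, n_pat, TRUE), alive = TRUE,
      record_opened = rdate(n_pat)
    ),
    diagnoses = data.frame(
      pin = sample(pins, nd, TRUE), date = rdate(nd),
      icd_version = 10L,
      code = sample(c("E11.9", "E11", "I10", "J06.9"), nd, TRUE),
      name = "dx", deleted = runif(nd) < 0.3
    ),
    drugs = data.frame(
      pin = sample(pins, nr, TRUE), date = rdate(nr), drug_name = "rx",
      atc_code = sample(c("A10BA02", "A10BB01", "C07AB02", "N02BE01"),
                        nr, TRUE),
      iteration = 1L, dosage = "1x1", deleted = runif(nr) < 0.3
    ),
    labs = data.frame(
      pin = sample(pins, nl, TRUE), date = rdate(nl), analyte = "glucose",
      value = round(runif(nl, 4, 10), 1), unit = "mmol/L",
      fasting = runif(nl) < 0.5,
      specimen = sample(c("plasma", "blood"), nl, TRUE),
      deleted = runif(nl) < 0.2
    )
  )
}

# Independent per-patient linear-scan oracle for the case finder: loops
# over patients and entries, no shared code with find_cases().
brute_force_cases <- function(db, criteria) {
  blind <- criteria$deletion_mode == "deletion_blind"
  res <- list()
  for (pin in db$patients$pin) {
    by_icd <- FALSE
    if (!is.null(criteria$icd_patterns)) {
      d <- db$diagnoses[db$diagnoses$pin == pin, ]
      for (i in seq_len(nrow(d))) {
        if (!blind && d$deleted[i]) next
        for (j in seq_len(nrow(criteria$icd_patterns))) {
          if (d$icd_version[i] == criteria$icd_patterns$version[j] &&
              startsWith(toupper(trimws(d$code[i])),
                         toupper(criteria$icd_patterns$prefix[j]))) {
            by_icd <- TRUE
          }
        }
      }
    }
    by_atc <- FALSE
    if (!is.null(criteria$atc_prefixes)) {
      d <- db$drugs[db$drugs$pin == pin, ]
      for (i in seq_len(nrow(d))) {
        if (!blind && d$deleted[i]) next
        for (p in criteria$atc_prefixes) {
          if (startsWith(toupper(trimws(d$atc_code[i])), toupper(p))) {
            by_atc <- TRUE
          }
        }
      }
    }
    by_lab <- FALSE
    if (!is.null(criteria$lab_rules)) {
      d <- db$labs[db$labs$pin == pin, ]
      for (i in seq_len(nrow(d))) {
        if (!blind && d$deleted[i]) next
        for (j in seq_len(nrow(criteria$lab_rules))) {
          r <- criteria$lab_rules[j, ]
          if (tolower(d$analyte[i]) != tolower(r$analyte)) next
          if (d$specimen[i] != r$specimen) next
          if (d$unit[i] != r$unit) next
          if (r$require_fasting && !d$fasting[i]) next
          ok <- if (r$comparator == ">=") d$value[i] >= r$threshold
                else d$value[i] > r$threshold
          if (ok) by_lab <- TRUE
        }
      }
    }
    if (by_icd || by_atc || by_lab) {
      res[[pin]] <- c(by_icd = by_icd, by_atc = by_atc, by_lab = by_lab)
    }
  }
  out <- tibble::tibble(
    pin = names(res),
    by_icd = vapply(res, `[[`, logical(1), "by_icd"),
    by_atc = vapply(res, `[[`, logical(1), "by_atc"),
    by_lab = vapply(res, `[[`, logical(1), "by_lab")
  )
  out[order(out$pin), ]
}

expect_same_caseset <- function(cs, oracle) {
  expect_equal(cs$pin, oracle$pin)
  expect_equal(cs$by_icd, oracle$by_icd, ignore_attr = TRUE)
  expect_equal(cs$by_atc, oracle$by_atc, ignore_attr = TRUE)
  expect_equal(cs$by_lab, oracle$by_lab, ignore_attr = TRUE)
}
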