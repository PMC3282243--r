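#' Configuration for the synthetic EMR generator
#'
#' The generator emulates a primary-care EMR store of the shape used to
#' validate register extraction: a patient panel opened over a 13-year
#' period, a background stream of contacts, diagnoses, prescriptions,
#' laboratory analyses, biometrics, documents, measurements and narrative
#' notes, a true type 2 diabetes (T2DM) subpopulation whose members carry
#' criterion signatures (diagnosis code, oral antidiabetic prescription,
#' elevated fasting glucose) with configurable documentation
#' probabilities, plus two soft-deletion phenomena: inaccurate oral
#' antidiabetic prescriptions on non-cases that a caregiver later deleted
#' (the source of deletion-blind false inclusions) and deleted contact
#' entries (the source of extraction-only audit discrepancies).
#'
#' Documentation probability defaults are calibrated with
#' [calibrate_documentation_probs()] so that, among detected cases, the
#' expected fraction carrying each signature is 53% (diagnosis), 38%
#' (prescription) and 91% (laboratory).
#'
#' @param n_patients Number of patient records to open.
#' @param period Length-2 Date vector; record-keeping period.
#' @param prevalence Probability that a patient is a true T2DM case.
#' @param p_icd_documented,p_atc_documented,p_lab_documented Per-case
#'   probabilities that each criterion signature is documented.
#' @param p_deleted_rx_noncase Probability that a non-case carries an oral
#'   antidiabetic prescription destined for soft deletion.
#' @param quota_deleted_rx Optional exact number of such non-cases
#'   (overrides the probability; used to reproduce known deletion counts).
#' @param p_deleted_contact Probability that any contact entry is soft
#'   deleted.
#' @param quota_deleted_contacts Optional exact number of deleted contacts.
#' @param rates Named list of background event rates per patient-year.
#' @param seed Integer RNG seed; one derived stream per generation stage.
#' @return A `synth_config` object (validated list).
#' @export
synth_config <- function(n_patients = 10753,
                         period = as.Date(c("1993-01-01", "2005-12-31")),
                         prevalence = 0.04,
                         p_icd_documented = NULL,
                         p_atc_documented = NULL,
                         p_lab_documented = NULL,
                         p_deleted_rx_noncase = 0.0012,
                         quota_deleted_rx = NULL,
                         p_deleted_contact = 0.01,
                         quota_deleted_contacts = NULL,
                         rates = list(contacts = 1.0, diagnoses = 0.35,
                                      drugs = 0.40, labs = 0.35,
                                      biometrics = 0.12, documents = 0.08,
                                      measurements = 0.10, narrative = 0.40),
                         seed = 1L) {
  doc <- calibrate_documentation_probs()
  p_icd_documented <- p_icd_documented %||% doc[["icd"]]
  p_atc_documented <- p_atc_documented %||% doc[["atc"]]
  p_lab_documented <- p_lab_documented %||% doc[["lab"]]
  cfg <- list(
    n_patients = as.integer(n_patients), period = as.Date(period),
    prevalence = prevalence,
    p_icd_documented = p_icd_documented,
    p_atc_documented = p_atc_documented,
    p_lab_documented = p_lab_documented,
    p_deleted_rx_noncase = p_deleted_rx_noncase,
    quota_deleted_rx = quota_deleted_rx,
    p_deleted_contact = p_deleted_contact,
    quota_deleted_contacts = quota_deleted_contacts,
    rates = rates, seed = as.integer(seed)
  )
  probs <- c(prevalence, p_icd_documented, p_atc_documented, p_lab_documented,
             p_deleted_rx_noncase, p_deleted_contact)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stopf("configuration error: probabilities must lie in [0, 1]")
  }
  if (cfg$n_patients < 0) {
    stopf("configuration error: n_patients must be >= 0")
  }
  if (length(cfg$period) != 2 || cfg$period[1] >= cfg$period[2]) {
    stopf("configuration error: period start must precede end")
  }
  structure(cfg, class = "synth_config")
}

#' Calibrate per-case documentation probabilities to target marginals
#'
#' With independent per-case signature documentation, a case is detected
#' when at least one signature is present, so the expected fraction of
#' *detected* cases carrying signature i is p_i / (1 - q) with
#' q = prod(1 - p_i). Given target marginal fractions m_i this solves the
#' fixed point p_i = m_i (1 - q) by iteration.
#'
#' @param marginals Named fractions among detected cases
#'   (`icd`, `atc`, `lab`).
#' @return Named probabilities (`icd`, `atc`, `lab`).
#' @export
calibrate_documentation_probs <- function(marginals = c(icd = 0.53,
                                                        atc = 0.38,
                                                        lab = 0.91)) {
  q <- 0
  for (i in 1:200) {
    p <- marginals * (1 - q)
    q_new <- prod(1 - p)
    if (abs(q_new - q) < 1e-12) {
      q <- q_new
      break
    }
    q <- q_new
  }
  marginals * (1 - q)
}

# Glucose model: detected hyperglycaemia is drawn lognormal with median
# 9 mmol/L (plasma); normoglycaemic values centre at 5 mmol/L plasma /
# 4.5 mmol/L whole blood with sdlog 0.09, which keeps threshold exceedance
# among non-cases below 0.1%.
GLUCOSE <- list(
  case_meanlog = log(9), case_sdlog = 0.30,
  noncase_plasma_meanlog = log(5), noncase_blood_meanlog = log(4.5),
  noncase_sdlog = 0.09,
  thr_plasma = 7.0, thr_blood = 6.1
)

rnoncase_glucose <- function(n, specimen) {
  meanlog <- ifelse(specimen == "blood",
                    GLUCOSE$noncase_blood_meanlog,
                    GLUCOSE$noncase_plasma_meanlog)
  round(exp(meanlog + GLUCOSE$noncase_sdlog * stats::rnorm(n)), 1)
}

# Qualifying fasting plasma glucose for planted laboratory signatures:
# lognormal truncated above the plasma threshold.
rqualifying_glucose <- function(n) {
  lo <- plnorm(GLUCOSE$thr_plasma, GLUCOSE$case_meanlog, GLUCOSE$case_sdlog)
  v <- qlnorm(runif(n, lo, 1), GLUCOSE$case_meanlog, GLUCOSE$case_sdlog)
  pmax(GLUCOSE$thr_plasma, round(v, 1))
}

BACKGROUND_DX <- data.frame(
  code = c("I10", "J06.9", "M54.5", "E78.5", "401", "724.2"),
  icd_version = c(10L, 10L, 10L, 10L, 9L, 9L),
  name = c("Essential hypertension", "Acute upper respiratory infection",
           "Low back pain", "Hyperlipidaemia", "Essential hypertension",
           "Lumbago"),
  stringsAsFactors = FALSE
)

BACKGROUND_RX <- data.frame(
  atc_code = c("C07AB02", "N02BE01", "C10AA01", "A02BC01"),
  drug_name = c("Metoprolol", "Paracetamol", "Simvastatin", "Omeprazole"),
  dosage = c("50 mg 1x1", "500 mg 1x3", "20 mg 1x1", "20 mg 1x1"),
  stringsAsFactors = FALSE
)

SUBHEADINGS <- c("current disease", "heritage", "physical status",
                 "blood pressure", "weight", "smoking habit")

#' Generate a synthetic EMR population
#'
#' Draws the patient panel, the true-case indicator, per-case criterion
#' signatures and the background event stream, and assembles a validated
#' [emr_database()] together with its ground truth. Output is bit-identical
#' for identical configuration (including seed). Prescriptions destined for
#' soft deletion are created here as active entries; [inject_soft_deletions()]
#' flips their flags without adding or removing rows, so the two stages are
#' count-conserving by construction.
#'
#' @param config A [synth_config()].
#' @return A list with elements `db` (`emr_database`) and `truth` (tibble
#'   with per-PIN case status, planted signatures, and deletion bookkeeping).
#' @export
generate_population <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_patients
  period <- config$period
  years <- as.numeric(period[2] - period[1] + 1) / 365.25
  pins <- sprintf("P%06d", seq_len(n))

  patients <- with_stream_seed(config$seed, "patients", {
    tibble::tibble(
      pin = pins,
      gender = sample(c("female", "male"), n, replace = TRUE),
      birth_year = sample(1908:1992, n, replace = TRUE),
      alive = runif(n) > 0.08,
      record_opened = runif_date(n, period[1], period[2])
    )
  })

  truth <- with_stream_seed(config$seed, "truth", {
    is_case <- rbinom(n, 1, config$prevalence) == 1
    sig_icd <- is_case & rbinom(n, 1, config$p_icd_documented) == 1
    sig_atc <- is_case & rbinom(n, 1, config$p_atc_documented) == 1
    sig_lab <- is_case & rbinom(n, 1, config$p_lab_documented) == 1
    noncase_idx <- which(!is_case)
    stray_rx <- rep(FALSE, n)
    if (!is.null(config$quota_deleted_rx)) {
      k <- min(config$quota_deleted_rx, length(noncase_idx))
      if (k < config$quota_deleted_rx) {
        warnf("only %d non-cases available for the deleted-prescription quota", k)
      }
      stray_rx[sample(noncase_idx, k)] <- TRUE
    } else if (config$p_deleted_rx_noncase > 0 && length(noncase_idx) > 0) {
      stray_rx[noncase_idx] <-
        rbinom(length(noncase_idx), 1, config$p_deleted_rx_noncase) == 1
    }
    tibble::tibble(pin = pins, is_case = is_case, sig_icd = sig_icd,
                   sig_atc = sig_atc, sig_lab = sig_lab, stray_rx = stray_rx,
                   deleted_rx = FALSE, n_deleted_contacts = 0L)
  })

  ev <- with_stream_seed(config$seed, "events", {
    generate_background_events(pins, truth$is_case, config, years)
  })

  sig <- with_stream_seed(config$seed, "signatures", {
    generate_signature_entries(truth, period)
  })

  db <- emr_database(
    patients = patients,
    contacts = ev$contacts,
    diagnoses = dplyr::bind_rows(ev$diagnoses, sig$diagnoses),
    drugs = dplyr::bind_rows(ev$drugs, sig$drugs),
    labs = dplyr::bind_rows(ev$labs, sig$labs),
    biometrics = ev$biometrics,
    documents = ev$documents,
    measurements = ev$measurements,
    narrative = ev$narrative,
    period = period
  )
  list(db = db, truth = truth)
}

generate_background_events <- function(pins, is_case, config, years) {
  n <- length(pins)
  period <- config$period
  draw <- function(rate) {
    counts <- rpois(n, rate * years)
    list(pin = rep(pins, counts), case = rep(is_case, counts),
         m = sum(counts))
  }

  e <- draw(config$rates$contacts)
  contacts <- tibble::tibble(
    pin = e$pin,
    date = runif_date(e$m, period[1], period[2]),
    contact_type = sample(CONTACT_TYPES, e$m, replace = TRUE,
                          prob = c(0.45, 0.30, 0.15, 0.10)),
    user_id = sprintf("U%02d", sample(25, e$m, replace = TRUE)),
    deleted = FALSE
  )

  e <- draw(config$rates$diagnoses)
  pick <- sample(nrow(BACKGROUND_DX), e$m, replace = TRUE)
  diagnoses <- tibble::tibble(
    pin = e$pin, date = runif_date(e$m, period[1], period[2]),
    icd_version = BACKGROUND_DX$icd_version[pick],
    code = BACKGROUND_DX$code[pick], name = BACKGROUND_DX$name[pick],
    deleted = FALSE
  )

  e <- draw(config$rates$drugs)
  pick <- sample(nrow(BACKGROUND_RX), e$m, replace = TRUE)
  drugs <- tibble::tibble(
    pin = e$pin, date = runif_date(e$m, period[1], period[2]),
    drug_name = BACKGROUND_RX$drug_name[pick],
    atc_code = BACKGROUND_RX$atc_code[pick],
    iteration = sample(0:3, e$m, replace = TRUE),
    dosage = BACKGROUND_RX$dosage[pick],
    deleted = FALSE
  )

  e <- draw(config$rates$labs)
  analyte <- sample(c("glucose", "cholesterol", "creatinine"), e$m,
                    replace = TRUE, prob = c(0.5, 0.3, 0.2))
  specimen <- as.character(ifelse(analyte == "glucose",
                                  sample(c("plasma", "blood"), e$m,
                                         replace = TRUE, prob = c(0.7, 0.3)),
                                  "plasma"))
  fasting <- analyte == "glucose" & runif(e$m) < 0.5
  value <- numeric(e$m)
  g <- analyte == "glucose"
  # cases' routine glucose runs high (untruncated); non-cases normoglycaemic
  value[g & e$case] <- round(exp(GLUCOSE$case_meanlog - 0.1 +
                                   GLUCOSE$case_sdlog * stats::rnorm(sum(g & e$case))), 1)
  value[g & !e$case] <- rnoncase_glucose(sum(g & !e$case),
                                         specimen[g & !e$case])
  ch <- analyte == "cholesterol"
  value[ch] <- round(exp(log(5.2) + 0.15 * stats::rnorm(sum(ch))), 1)
  cr <- analyte == "creatinine"
  value[cr] <- round(exp(log(80) + 0.2 * stats::rnorm(sum(cr))))
  unit <- as.character(ifelse(analyte == "creatinine", "umol/L", "mmol/L"))
  labs <- tibble::tibble(
    pin = e$pin, date = runif_date(e$m, period[1], period[2]),
    analyte = analyte, value = value, unit = unit, fasting = fasting,
    specimen = specimen, deleted = FALSE
  )

  e <- draw(config$rates$biometrics)
  weight <- round(runif(e$m, 50, 110), 1)
  height <- round(runif(e$m, 150, 195))
  biometrics <- tibble::tibble(
    pin = e$pin, date = runif_date(e$m, period[1], period[2]),
    weight = weight, height = height,
    bmi = round(weight / (height / 100)^2, 1), deleted = FALSE
  )

  e <- draw(config$rates$documents)
  documents <- tibble::tibble(
    pin = e$pin, date = runif_date(e$m, period[1], period[2]),
    doc_type = sample(c("referral", "other"), e$m, replace = TRUE,
                      prob = c(0.4, 0.6)),
    text = "Referral note.", deleted = FALSE
  )

  e <- draw(config$rates$measurements)
  name <- sample(c("waist circumference", "pulse"), e$m, replace = TRUE)
  measurements <- tibble::tibble(
    pin = e$pin, date = runif_date(e$m, period[1], period[2]),
    name = name,
    value = ifelse(name == "pulse", round(runif(e$m, 55, 95)),
                   round(runif(e$m, 70, 120))),
    unit = ifelse(name == "pulse", "bpm", "cm"), deleted = FALSE
  )

  e <- draw(config$rates$narrative)
  narrative <- tibble::tibble(
    pin = e$pin, date = runif_date(e$m, period[1], period[2]),
    subheading = sample(SUBHEADINGS, e$m, replace = TRUE),
    text = "Documented in journal text.", deleted = FALSE
  )

  list(contacts = contacts, diagnoses = diagnoses, drugs = drugs,
       labs = labs, biometrics = biometrics, documents = documents,
       measurements = measurements, narrative = narrative)
}

generate_signature_entries <- function(truth, period) {
  dx_pins <- truth$pin[truth$sig_icd]
  diagnoses <- tibble::tibble(
    pin = dx_pins, date = runif_date(length(dx_pins), period[1], period[2]),
    icd_version = 10L, code = "E11.9",
    name = "Type 2 diabetes mellitus without complications", deleted = FALSE
  )
  rx_pins <- c(truth$pin[truth$sig_atc], truth$pin[truth$stray_rx])
  drugs <- tibble::tibble(
    pin = rx_pins, date = runif_date(length(rx_pins), period[1], period[2]),
    drug_name = "Metformin", atc_code = "A10BA02",
    iteration = sample(0:3, length(rx_pins), replace = TRUE),
    dosage = "500 mg 1x2", deleted = FALSE
  )
  lab_pins <- truth$pin[truth$sig_lab]
  labs <- tibble::tibble(
    pin = lab_pins, date = runif_date(length(lab_pins), period[1], period[2]),
    analyte = "glucose", value = rqualifying_glucose(length(lab_pins)),
    unit = "mmol/L", fasting = TRUE, specimen = "plasma", deleted = FALSE
  )
  list(diagnoses = diagnoses, drugs = drugs, labs = labs)
}

#' Apply soft-deletion events to a generated population
#'
#' Marks `deleted = TRUE` on the oral antidiabetic prescriptions of the
#' non-cases selected at generation time, and on a random subset of contact
#' entries (probability `p_deleted_contact`, or exactly
#' `quota_deleted_contacts` when set). No entry is added or removed: only
#' flags are toggled, mirroring how soft deletion works in the source
#' system.
#'
#' @param db,truth Output of [generate_population()].
#' @param config The same [synth_config()] used for generation.
#' @return A list with updated `db` and `truth` (deletion bookkeeping
#'   filled in).
#' @export
inject_soft_deletions <- function(db, truth, config) {
  stopifnot(inherits(db, "emr_database"), inherits(config, "synth_config"))
  with_stream_seed(config$seed, "deletions", {
    stray_pins <- truth$pin[truth$stray_rx]
    flag <- db$drugs$pin %in% stray_pins &
      startsWith(norm_code(db$drugs$atc_code), "A10B")
    db$drugs$deleted <- db$drugs$deleted | flag
    truth$deleted_rx <- truth$stray_rx

    nc <- nrow(db$contacts)
    if (!is.null(config$quota_deleted_contacts)) {
      k <- min(config$quota_deleted_contacts, nc)
      if (k < config$quota_deleted_contacts) {
        warnf("only %d contacts available for the deleted-contact quota", k)
      }
      if (k > 0) db$contacts$deleted[sample(nc, k)] <- TRUE
    } else if (config$p_deleted_contact > 0 && nc > 0) {
      db$contacts$deleted <- db$contacts$deleted |
        rbinom(nc, 1, config$p_deleted_contact) == 1
    }
    del_counts <- table(db$contacts$pin[db$contacts$deleted])
    idx <- match(truth$pin, names(del_counts))
    truth$n_deleted_contacts <- ifelse(is.na(idx), 0L,
                                       as.integer(del_counts[idx]))
    list(db = db, truth = truth)
  })
}

#' Generate a fully assembled synthetic population
#'
#' Convenience wrapper: [generate_population()] followed by
#' [inject_soft_deletions()].
#'
#' @param config A [synth_config()].
#' @return A list with `db` and `truth`.
#' @export
generate_emr <- function(config = synth_config()) {
  pop <- generate_population(config)
  inject_soft_deletions(pop$db, pop$truth, config)
}
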