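#' Solve three-set Venn region counts for given marginals
#'
#' Given a union size and the per-criterion marginal counts, constructs a
#' deterministic non-negative assignment of the seven Venn regions
#' reproducing them exactly. Feasibility requires each marginal to be at
#' most the union and the marginal sum to be at least the union (every
#' member must carry at least one criterion). Construction: each member
#' first receives a single membership (criteria filled in order up to their
#' marginals), then the remaining memberships are stacked onto members
#' lacking that criterion.
#'
#' @param total Union size.
#' @param n_icd,n_atc,n_lab Marginal counts.
#' @return A list with `regions` (named 7-vector: `icd_only`, `atc_only`,
#'   `lab_only`, `icd_atc`, `icd_lab`, `atc_lab`, `all_three`) and
#'   `membership` (`total` x 3 logical matrix).
#' @export
solve_venn_regions <- function(total, n_icd, n_atc, n_lab) {
  m <- c(icd = n_icd, atc = n_atc, lab = n_lab)
  if (total < 0 || any(m < 0) || any(m > total) ||
      (total > 0 && sum(m) < total) || (total == 0 && sum(m) > 0)) {
    stopf("infeasible marginals: union %d with marginals %d/%d/%d",
          total, n_icd, n_atc, n_lab)
  }
  M <- matrix(FALSE, nrow = total, ncol = 3,
              dimnames = list(NULL, c("icd", "atc", "lab")))
  # phase 1: one membership each
  s <- integer(3)
  left <- total
  for (i in 1:3) {
    s[i] <- min(m[i], left)
    left <- left - s[i]
  }
  start <- cumsum(c(0, s[-3]))
  for (i in 1:3) {
    if (s[i] > 0) M[(start[i] + 1):(start[i] + s[i]), i] <- TRUE
  }
  # phase 2: stack the remaining memberships onto members lacking them
  r <- m - s
  for (i in 1:3) {
    if (r[i] > 0) {
      lack <- which(!M[, i])
      M[lack[seq_len(r[i])], i] <- TRUE
    }
  }
  stopifnot(colSums(M) == m, all(rowSums(M) >= 1) || total == 0)
  regions <- c(
    icd_only = sum(M[, 1] & !M[, 2] & !M[, 3]),
    atc_only = sum(!M[, 1] & M[, 2] & !M[, 3]),
    lab_only = sum(!M[, 1] & !M[, 2] & M[, 3]),
    icd_atc = sum(M[, 1] & M[, 2] & !M[, 3]),
    icd_lab = sum(M[, 1] & !M[, 2] & M[, 3]),
    atc_lab = sum(!M[, 1] & M[, 2] & M[, 3]),
    all_three = sum(M[, 1] & M[, 2] & M[, 3])
  )
  list(regions = regions, membership = M)
}

qualifying_entries <- function(pins, membership, period, deleted = FALSE,
                               pin_dates = NULL) {
  dates <- pin_dates %||% runif_date(length(pins), period[1], period[2])
  list(
    diagnoses = {
      k <- membership[, "icd"]
      tibble::tibble(
        pin = pins[k], date = dates[k], icd_version = 10L, code = "E11.9",
        name = "Type 2 diabetes mellitus without complications",
        deleted = deleted
      )
    },
    drugs = {
      k <- membership[, "atc"]
      tibble::tibble(
        pin = pins[k], date = dates[k], drug_name = "Metformin",
        atc_code = "A10BA02", iteration = 1L, dosage = "500 mg 1x2",
        deleted = deleted
      )
    },
    labs = {
      k <- membership[, "lab"]
      tibble::tibble(
        pin = pins[k], date = dates[k], analyte = "glucose",
        value = rqualifying_glucose(sum(k)), unit = "mmol/L",
        fasting = TRUE, specimen = "plasma", deleted = deleted
      )
    }
  )
}

#' Build a database reproducing exact criterion marginals
#'
#' Constructs a minimal synthetic database on which [find_cases()] returns
#' exactly the requested union size and per-criterion marginal counts.
#' Criterion overlap is solved exactly with [solve_venn_regions()] (or
#' taken verbatim from `region_counts` when supplied); each case patient
#' receives precisely the qualifying entries its Venn region dictates.
#' Optional additional criterion-free patients pad the population to a
#' target size for accuracy/prevalence denominators.
#'
#' @param total Union size (number of case patients).
#' @param n_icd,n_atc,n_lab Marginal counts per criterion.
#' @param region_counts Optional 7-vector of region counts in the order
#'   `icd_only`, `atc_only`, `lab_only`, `icd_atc`, `icd_lab`, `atc_lab`,
#'   `all_three`; must sum to `total` and reproduce the marginals.
#' @param n_noncases Number of padding patients without qualifying entries.
#' @param period Store period.
#' @param seed RNG seed (entry dates, demographics).
#' @return A list with `db`, `truth`, and `regions`.
#' @export
generate_fixture_from_marginals <- function(total, n_icd, n_atc, n_lab,
                                            region_counts = NULL,
                                            n_noncases = 0,
                                            period = as.Date(c("1993-01-01",
                                                               "2005-12-31")),
                                            seed = 1L) {
  if (!is.null(region_counts)) {
    stopifnot(length(region_counts) == 7)
    r <- as.integer(region_counts)
    ok <- sum(r) == total &&
      r[1] + r[4] + r[5] + r[7] == n_icd &&
      r[2] + r[4] + r[6] + r[7] == n_atc &&
      r[3] + r[5] + r[6] + r[7] == n_lab
    if (!ok || any(r < 0)) {
      stopf("region_counts do not reproduce the requested marginals")
    }
    reg <- c("icd_only", "atc_only", "lab_only", "icd_atc", "icd_lab",
             "atc_lab", "all_three")
    pattern <- matrix(c(
      TRUE, FALSE, FALSE,
      FALSE, TRUE, FALSE,
      FALSE, FALSE, TRUE,
      TRUE, TRUE, FALSE,
      TRUE, FALSE, TRUE,
      FALSE, TRUE, TRUE,
      TRUE, TRUE, TRUE
    ), ncol = 3, byrow = TRUE, dimnames = list(reg, c("icd", "atc", "lab")))
    M <- pattern[rep(seq_len(7), r), , drop = FALSE]
    rownames(M) <- NULL
    solved <- list(regions = stats::setNames(r, reg), membership = M)
  } else {
    solved <- solve_venn_regions(total, n_icd, n_atc, n_lab)
  }
  with_stream_seed(seed, "fixture", {
    n_all <- total + n_noncases
    pins <- sprintf("P%06d", seq_len(n_all))
    case_pins <- pins[seq_len(total)]
    patients <- tibble::tibble(
      pin = pins,
      gender = sample(c("female", "male"), n_all, replace = TRUE),
      birth_year = sample(1908:1992, n_all, replace = TRUE),
      alive = TRUE,
      record_opened = runif_date(n_all, period[1], period[2])
    )
    q <- qualifying_entries(case_pins, solved$membership, period)
    db <- emr_database(
      patients = patients, diagnoses = q$diagnoses, drugs = q$drugs,
      labs = q$labs, period = period
    )
    truth <- tibble::tibble(
      pin = pins,
      is_case = pins %in% case_pins,
      sig_icd = pins %in% case_pins[solved$membership[, "icd"]],
      sig_atc = pins %in% case_pins[solved$membership[, "atc"]],
      sig_lab = pins %in% case_pins[solved$membership[, "lab"]]
    )
    list(db = db, truth = truth, regions = solved$regions)
  })
}

#' Study-shaped case-finding fixture with deletion-driven excess cases
#'
#' Builds a population of `n_total` patients in which a deletion-aware
#' search finds exactly the reference caseset (`aware` marginals) while a
#' deletion-blind search additionally picks up `n_extra` patients whose
#' only qualifying entries are soft-deleted. The defaults mirror a
#' validated T2DM extraction at a single primary-care centre: 433
#' reference cases with marginals 231/161/404, plus 12 deletion-only
#' patients split 3 (deleted diagnosis) / 8 (deleted prescription) /
#' 1 (deleted laboratory value), giving blind-mode marginals 234/169/405
#' and a blind caseset of 445.
#'
#' @param n_total Population size (accuracy/prevalence denominator).
#' @param aware Named list: union and marginals of the reference caseset.
#' @param extra Named integer vector: deletion-only patients per criterion.
#' @param period Store period.
#' @param seed RNG seed.
#' @return A list with `db` and `truth` (`role` column distinguishes
#'   reference cases, deletion-only cases, and non-cases).
#' @export
generate_study_fixture <- function(n_total = 10753,
                                   aware = list(total = 433, icd = 231,
                                                atc = 161, lab = 404),
                                   extra = c(icd = 3, atc = 8, lab = 1),
                                   period = as.Date(c("1993-01-01",
                                                      "2005-12-31")),
                                   seed = 1L) {
  n_extra <- sum(extra)
  stopifnot(n_total >= aware$total + n_extra)
  solved <- solve_venn_regions(aware$total, aware$icd, aware$atc, aware$lab)
  with_stream_seed(seed, "study-fixture", {
    pins <- sprintf("P%06d", seq_len(n_total))
    ref_pins <- pins[seq_len(aware$total)]
    extra_pins <- pins[aware$total + seq_len(n_extra)]
    patients <- tibble::tibble(
      pin = pins,
      gender = sample(c("female", "male"), n_total, replace = TRUE),
      birth_year = sample(1908:1992, n_total, replace = TRUE),
      alive = TRUE,
      record_opened = runif_date(n_total, period[1], period[2])
    )
    q <- qualifying_entries(ref_pins, solved$membership, period)
    extra_M <- matrix(FALSE, n_extra, 3,
                      dimnames = list(NULL, c("icd", "atc", "lab")))
    extra_M[seq_len(extra[["icd"]]), "icd"] <- TRUE
    extra_M[extra[["icd"]] + seq_len(extra[["atc"]]), "atc"] <- TRUE
    extra_M[extra[["icd"]] + extra[["atc"]] + seq_len(extra[["lab"]]),
            "lab"] <- TRUE
    qx <- qualifying_entries(extra_pins, extra_M, period, deleted = TRUE)
    db <- emr_database(
      patients = patients,
      diagnoses = dplyr::bind_rows(q$diagnoses, qx$diagnoses),
      drugs = dplyr::bind_rows(q$drugs, qx$drugs),
      labs = dplyr::bind_rows(q$labs, qx$labs),
      period = period
    )
    truth <- tibble::tibble(
      pin = pins,
      role = c(rep("reference_case", aware$total),
               rep("deletion_only", n_extra),
               rep("non_case", n_total - aware$total - n_extra))
    )
    list(db = db, truth = truth)
  })
}

#' Deterministic 63-PIN fixture for the item-level congruity audit
#'
#' Builds a database whose audit sample is seed-invariant: three mutually
#' exclusive criterion groups (diagnosis-only, prescription-only,
#' laboratory-only) of 21 patients each, with exactly 7 per group whose
#' first qualifying event falls in each of the three calendar periods --
#' so every (criterion, period) stratum holds exactly the stratum quota
#' and stratified sampling must select all 63 PINs. Register item totals
#' per criterion group are exact by construction (defaults 1,060 / 1,216 /
#' 769, i.e. 3,045 items overall), every patient carries data in all nine
#' tables, and a configurable number of contact entries (default 13) are
#' soft-deleted so that a deletion-blind extraction emits items absent
#' from the normal source view.
#'
#' @param items_per_criterion Named total register items (rows, including
#'   the patient row) for the `icd`, `atc` and `lab` groups.
#' @param n_deleted_contacts Number of soft-deleted contact entries.
#' @param pins_per_stratum Patients per (criterion, period) stratum.
#' @param periods List of length-2 Date vectors (the audit periods).
#' @param seed RNG seed (dates, demographic noise).
#' @return A list with `db` and `truth` (per-PIN criterion group, period
#'   index and item count).
#' @export
generate_congruity_fixture <- function(items_per_criterion = c(icd = 1060,
                                                               atc = 1216,
                                                               lab = 769),
                                       n_deleted_contacts = 13,
                                       pins_per_stratum = 7,
                                       periods = default_audit_periods(),
                                       seed = 1L) {
  criteria_groups <- c("icd", "atc", "lab")
  n_periods <- length(periods)
  n_group <- pins_per_stratum * n_periods
  n_pins <- n_group * length(criteria_groups)
  period <- as.Date(c(min(vapply(periods, function(p) as.character(p[1]), "")),
                      max(vapply(periods, function(p) as.character(p[2]), ""))))
  with_stream_seed(seed, "congruity-fixture", {
    truth <- tibble::tibble(
      pin = sprintf("A%03d", seq_len(n_pins)),
      criterion = rep(criteria_groups, each = n_group),
      period_index = rep(rep(seq_len(n_periods), each = pins_per_stratum),
                         times = length(criteria_groups))
    )
    # exact per-PIN item totals: distribute each group total over its PINs
    truth$n_items <- unlist(lapply(criteria_groups, function(g) {
      tot <- items_per_criterion[[g]]
      base <- tot %/% n_group
      rem <- tot %% n_group
      base + as.integer(seq_len(n_group) <= rem)
    }))
    stopifnot(all(truth$n_items >= 22))  # room for >=1 row per table

    patients <- tibble::tibble(
      pin = truth$pin,
      gender = sample(c("female", "male"), n_pins, replace = TRUE),
      birth_year = sample(1908:1992, n_pins, replace = TRUE),
      alive = TRUE,
      record_opened = runif_date(n_pins, period[1], period[2])
    )

    # fixed small allocations per PIN; contacts absorb the remainder
    alloc <- list(diagnoses = 3L, drugs = 3L, labs = 4L, biometrics = 2L,
                  documents = 1L, measurements = 2L, narrative = 5L)
    fixed <- sum(unlist(alloc)) + 1L  # + the Patients row
    n_contacts_pin <- truth$n_items - fixed

    rep_pin <- function(k) rep(truth$pin, k)
    qual_date <- as.Date(vapply(seq_len(n_pins), function(i) {
      p <- periods[[truth$period_index[i]]]
      as.character(runif_date(1, p[1], p[2]))
    }, ""))

    mc <- sum(n_contacts_pin)
    contacts <- tibble::tibble(
      pin = rep(truth$pin, n_contacts_pin),
      date = runif_date(mc, period[1], period[2]),
      contact_type = sample(CONTACT_TYPES, mc, replace = TRUE,
                            prob = c(0.45, 0.3, 0.15, 0.1)),
      user_id = sprintf("U%02d", sample(25, mc, replace = TRUE)),
      deleted = FALSE
    )
    if (n_deleted_contacts > 0) {
      stopifnot(n_deleted_contacts <= mc)
      # first contact row of the first k PINs, deterministically
      first_rows <- match(truth$pin[seq_len(n_deleted_contacts)], contacts$pin)
      contacts$deleted[first_rows] <- TRUE
    }

    md <- n_pins * alloc$diagnoses
    diagnoses <- tibble::tibble(
      pin = rep_pin(alloc$diagnoses),
      date = runif_date(md, period[1], period[2]),
      icd_version = 10L, code = "I10", name = "Essential hypertension",
      deleted = FALSE
    )
    first_dx <- match(truth$pin, diagnoses$pin)
    is_icd <- truth$criterion == "icd"
    diagnoses$code[first_dx[is_icd]] <- "E11.9"
    diagnoses$name[first_dx[is_icd]] <-
      "Type 2 diabetes mellitus without complications"
    diagnoses$date[first_dx[is_icd]] <- qual_date[is_icd]

    mr <- n_pins * alloc$drugs
    drugs <- tibble::tibble(
      pin = rep_pin(alloc$drugs),
      date = runif_date(mr, period[1], period[2]),
      drug_name = "Metoprolol", atc_code = "C07AB02",
      iteration = sample(0:3, mr, replace = TRUE), dosage = "50 mg 1x1",
      deleted = FALSE
    )
    first_rx <- match(truth$pin, drugs$pin)
    is_atc <- truth$criterion == "atc"
    drugs$drug_name[first_rx[is_atc]] <- "Metformin"
    drugs$atc_code[first_rx[is_atc]] <- "A10BA02"
    drugs$dosage[first_rx[is_atc]] <- "500 mg 1x2"
    drugs$date[first_rx[is_atc]] <- qual_date[is_atc]

    ml <- n_pins * alloc$labs
    labs <- tibble::tibble(
      pin = rep_pin(alloc$labs),
      date = runif_date(ml, period[1], period[2]),
      analyte = "glucose",
      value = rnoncase_glucose(ml, "plasma"),
      unit = "mmol/L", fasting = FALSE, specimen = "plasma", deleted = FALSE
    )
    first_lab <- match(truth$pin, labs$pin)
    is_lab <- truth$criterion == "lab"
    labs$value[first_lab[is_lab]] <- rqualifying_glucose(sum(is_lab))
    labs$fasting[first_lab[is_lab]] <- TRUE
    labs$date[first_lab[is_lab]] <- qual_date[is_lab]

    mb <- n_pins * alloc$biometrics
    weight <- round(runif(mb, 50, 110), 1)
    height <- round(runif(mb, 150, 195))
    biometrics <- tibble::tibble(
      pin = rep_pin(alloc$biometrics),
      date = runif_date(mb, period[1], period[2]),
      weight = weight, height = height,
      bmi = round(weight / (height / 100)^2, 1), deleted = FALSE
    )

    mdoc <- n_pins * alloc$documents
    documents <- tibble::tibble(
      pin = rep_pin(alloc$documents),
      date = runif_date(mdoc, period[1], period[2]),
      doc_type = "referral", text = "Referral note.", deleted = FALSE
    )

    mm <- n_pins * alloc$measurements
    measurements <- tibble::tibble(
      pin = rep_pin(alloc$measurements),
      date = runif_date(mm, period[1], period[2]),
      name = "pulse", value = round(runif(mm, 55, 95)), unit = "bpm",
      deleted = FALSE
    )

    mn <- n_pins * alloc$narrative
    narrative <- tibble::tibble(
      pin = rep_pin(alloc$narrative),
      date = runif_date(mn, period[1], period[2]),
      subheading = sample(SUBHEADINGS, mn, replace = TRUE),
      text = "Documented in journal text.", deleted = FALSE
    )

    db <- emr_database(
      patients = patients, contacts = contacts, diagnoses = diagnoses,
      drugs = drugs, labs = labs, biometrics = biometrics,
      documents = documents, measurements = measurements,
      narrative = narrative, period = period
    )
    list(db = db, truth = truth)
  })
}

#' Default audit periods
#'
#' The three calendar periods of the stratified audit sampling plan:
#' 1993--1997, 1998--2001, 2002--2005.
#' @return List of length-2 Date vectors.
#' @export
default_audit_periods <- function() {
  list(
    as.Date(c("1993-01-01", "1997-12-31")),
    as.Date(c("1998-01-01", "2001-12-31")),
    as.Date(c("2002-01-01", "2005-12-31"))
  )
}
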