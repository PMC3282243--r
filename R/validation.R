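#' Stratified audit sampling plan
#'
#' Defines how PINs are drawn for the item-level congruity audit: for each
#' inclusion criterion in turn, the criterion's PINs are shuffled with a
#' seeded RNG, each PIN is assigned to the calendar period containing its
#' first qualifying event, and the first `pins_per_stratum` PINs per period
#' are taken; PINs already selected under an earlier criterion are excluded
#' before each subsequent step, so no PIN is audited twice.
#'
#' @param pins_per_stratum PINs per (criterion, period) stratum.
#' @param periods Ordered, disjoint list of length-2 Date vectors.
#' @param criterion_order Order in which the criterion steps run.
#' @param seed RNG seed for the shuffles.
#' @param restrict_to_period If `TRUE`, the congruity audit of a sampled
#'   PIN is restricted to register items dated within the PIN's assigned
#'   period; by default the PIN's whole register is audited.
#' @return A `sampling_plan` object.
#' @export
sampling_plan <- function(pins_per_stratum = 7,
                          periods = default_audit_periods(),
                          criterion_order = c("icd", "lab", "atc"),
                          seed = 1L,
                          restrict_to_period = FALSE) {
  stopifnot(pins_per_stratum >= 1,
            setequal(criterion_order, c("icd", "atc", "lab")))
  periods <- lapply(periods, as.Date)
  for (p in periods) {
    stopifnot(length(p) == 2, p[1] <= p[2])
  }
  if (length(periods) > 1) {
    for (i in 2:length(periods)) {
      if (periods[[i]][1] <= periods[[i - 1]][2]) {
        stopf("audit periods must be disjoint and ordered")
      }
    }
  }
  structure(list(pins_per_stratum = as.integer(pins_per_stratum),
                 periods = periods, criterion_order = criterion_order,
                 seed = as.integer(seed),
                 restrict_to_period = isTRUE(restrict_to_period)),
            class = "sampling_plan")
}

# Date of each PIN's first qualifying event for one criterion, honouring
# the criteria's deletion mode.
first_qualifying_dates <- function(db, criteria, criterion) {
  tab <- switch(criterion,
    icd = {
      x <- db$diagnoses
      x[visible_rows(x, criteria$deletion_mode) &
          diagnosis_matches(x, criteria$icd_patterns), c("pin", "date")]
    },
    atc = {
      x <- db$drugs
      x[visible_rows(x, criteria$deletion_mode) &
          match_prefix(x$atc_code, criteria$atc_prefixes), c("pin", "date")]
    },
    lab = {
      x <- db$labs
      x[visible_rows(x, criteria$deletion_mode) &
          lab_matches(x, criteria$lab_rules, warn_units = FALSE),
        c("pin", "date")]
    }
  )
  if (nrow(tab) == 0) {
    return(tibble::tibble(pin = character(),
                          first_event = as.Date(character())))
  }
  dplyr::summarise(dplyr::group_by(tab, .data$pin),
                   first_event = min(.data$date), .groups = "drop")
}

#' Select the audit sample (stratified PIN sampling)
#'
#' Runs the sampling plan against a caseset: per criterion in plan order,
#' shuffle that criterion's PINs, assign each to the period of its first
#' qualifying event, take the first `pins_per_stratum` per period, and
#' exclude previously selected PINs before the next criterion step. A
#' stratum with fewer eligible PINs than the quota yields a partial sample
#' and a warning, never a silent shortfall. With the default plan (7 PINs,
#' 3 periods, 3 criteria) a sufficient caseset yields 63 distinct PINs, 21
#' per criterion.
#'
#' @param caseset A `case_set` from [find_cases()].
#' @param db The database the caseset was computed on.
#' @param plan A [sampling_plan()].
#' @return An `audit_sample`: tibble with columns `criterion`,
#'   `period_index`, `pin`, `first_event`, carrying the plan and an
#'   exclusion log as attributes.
#' @export
select_audit_sample <- function(caseset, db, plan = sampling_plan()) {
  stopifnot(inherits(caseset, "case_set"), inherits(db, "emr_database"),
            inherits(plan, "sampling_plan"))
  criteria <- attr(caseset, "criteria")
  selected <- list()
  excluded <- list()
  with_stream_seed(plan$seed, "audit-sample", {
    for (crit in plan$criterion_order) {
      flag <- caseset[[paste0("by_", crit)]]
      eligible <- caseset$pin[flag]
      prior <- unlist(lapply(selected, function(s) s$pin))
      dropped <- intersect(eligible, prior)
      if (length(dropped) > 0) {
        excluded[[length(excluded) + 1]] <- tibble::tibble(
          criterion = crit, pin = dropped,
          reason = "selected under an earlier criterion"
        )
      }
      eligible <- setdiff(eligible, prior)
      shuffled <- if (length(eligible) > 0) sample(eligible) else character()
      fq <- first_qualifying_dates(db, criteria, crit)
      fdate <- fq$first_event[match(shuffled, fq$pin)]
      pidx <- rep(NA_integer_, length(shuffled))
      for (i in seq_along(plan$periods)) {
        p <- plan$periods[[i]]
        pidx[!is.na(fdate) & fdate >= p[1] & fdate <= p[2]] <- i
      }
      if (any(is.na(pidx))) {
        excluded[[length(excluded) + 1]] <- tibble::tibble(
          criterion = crit, pin = shuffled[is.na(pidx)],
          reason = "first qualifying event outside every audit period"
        )
      }
      for (i in seq_along(plan$periods)) {
        in_stratum <- which(!is.na(pidx) & pidx == i)
        take <- head(in_stratum, plan$pins_per_stratum)
        if (length(take) < plan$pins_per_stratum) {
          warnf("stratum shortfall: criterion %s, period %d has %d of %d PINs",
                crit, i, length(take), plan$pins_per_stratum)
        }
        if (length(take) > 0) {
          selected[[length(selected) + 1]] <- tibble::tibble(
            criterion = crit, period_index = i, pin = shuffled[take],
            first_event = fdate[take]
          )
        }
      }
    }
  })
  out <- if (length(selected) > 0) dplyr::bind_rows(selected) else
    tibble::tibble(criterion = character(), period_index = integer(),
                   pin = character(), first_event = as.Date(character()))
  stopifnot(!anyDuplicated(out$pin))
  structure(out, plan = plan,
            exclusion_log = if (length(excluded) > 0)
              dplyr::bind_rows(excluded) else NULL,
            class = c("audit_sample", class(out)))
}

#' Item-level congruity audit of a register against its source
#'
#' Implements the manual chart-review comparison: every register item of
#' the sampled PINs is located in the source database and classified by
#' *occurrence* (is it there at all, outside the deleted entries?) and
#' *coherence* (are all field values equal after whitespace/number
#' normalization?). Classification: `matched` (present among non-deleted
#' source entries with equal fields), `source_only` (present but with a
#' field difference, recorded with a diff), or `extraction_only` (only
#' locatable among soft-deleted entries, or not at all). The post-audit
#' rate re-matches extraction-only items against deleted source entries,
#' reproducing the resolution step of an audit performed with
#' administrator access to deleted data.
#'
#' @param register A `register` from [extract_register()].
#' @param db The source `emr_database`.
#' @param sample An `audit_sample`; its PINs delimit the audit. (A plain
#'   character vector of PINs is also accepted; the per-criterion
#'   breakdown is then omitted.)
#' @return A `congruity_report`: counts (`n_compared`, `n_matched`,
#'   `n_source_only`, `n_extraction_only`, `n_resolved`), rates
#'   (`congruity_rate`, `post_audit_rate`), per-table and per-criterion
#'   breakdowns, and the item-level detail tibble.
#' @export
compare_items <- function(register, db, sample) {
  stopifnot(inherits(register, "register"), inherits(db, "emr_database"))
  if (inherits(sample, "audit_sample")) {
    sample_tab <- sample
    plan <- attr(sample, "plan")
  } else {
    sample_tab <- tibble::tibble(criterion = NA_character_,
                                 period_index = NA_integer_,
                                 pin = as.character(sample))
    plan <- NULL
  }
  pins <- unique(sample_tab$pin)
  restrict <- !is.null(plan) && isTRUE(plan$restrict_to_period)

  detail <- list()
  mod_of <- stats::setNames(names(REGISTER_TABLES), REGISTER_TABLES)
  for (tname in names(register)) {
    reg <- register[[tname]]
    reg <- reg[reg$pin %in% pins, , drop = FALSE]
    if (restrict && tname != "Patients" && nrow(reg) > 0) {
      pi <- sample_tab$period_index[match(reg$pin, sample_tab$pin)]
      lo <- as.Date(vapply(plan$periods, function(p) as.character(p[1]), ""))
      hi <- as.Date(vapply(plan$periods, function(p) as.character(p[2]), ""))
      reg <- reg[reg$date >= lo[pi] & reg$date <= hi[pi], , drop = FALSE]
    }
    if (nrow(reg) == 0) {
      next
    }
    m <- mod_of[[tname]]
    src <- db[[m]]
    sid <- item_ids(m, src)
    idx <- match(reg$item_id, sid)
    fields <- setdiff(intersect(names(reg), names(src)), "deleted")
    coherent <- rep(TRUE, nrow(reg))
    first_diff <- rep(NA_character_, nrow(reg))
    present <- !is.na(idx)
    for (f in rev(fields)) {
      a <- norm_field(reg[[f]])
      b <- rep(NA_character_, nrow(reg))
      b[present] <- norm_field(src[[f]][idx[present]])
      eq <- (a == b) | (is.na(a) & is.na(b))
      eq[is.na(eq)] <- FALSE
      neq <- present & !eq
      coherent <- coherent & !neq
      first_diff[neq] <- f
    }
    src_deleted <- rep(FALSE, nrow(reg))
    if (m != "patients") {
      src_deleted[present] <- src$deleted[idx[present]]
    }
    status <- ifelse(!present, "extraction_only",
              ifelse(src_deleted, "extraction_only",
              ifelse(coherent, "matched", "source_only")))
    resolved <- status == "extraction_only" & present & src_deleted & coherent
    detail[[length(detail) + 1]] <- tibble::tibble(
      table = tname, item_id = reg$item_id, pin = reg$pin,
      status = status, resolved = resolved,
      field_diff = ifelse(status == "source_only", first_diff, NA_character_)
    )
  }
  detail <- if (length(detail) > 0) dplyr::bind_rows(detail) else
    tibble::tibble(table = character(), item_id = character(),
                   pin = character(), status = character(),
                   resolved = logical(), field_diff = character())

  n_compared <- nrow(detail)
  n_matched <- sum(detail$status == "matched")
  n_source_only <- sum(detail$status == "source_only")
  n_extraction_only <- sum(detail$status == "extraction_only")
  n_resolved <- sum(detail$resolved)

  per_table <- dplyr::summarise(
    dplyr::group_by(detail, .data$table),
    n = dplyr::n(),
    matched = sum(.data$status == "matched"),
    source_only = sum(.data$status == "source_only"),
    extraction_only = sum(.data$status == "extraction_only"),
    .groups = "drop"
  )
  per_criterion <- NULL
  if (!all(is.na(sample_tab$criterion))) {
    crit_of <- sample_tab$criterion[match(detail$pin, sample_tab$pin)]
    per_criterion <- dplyr::count(
      tibble::tibble(criterion = crit_of), .data$criterion, name = "n_items"
    )
  }

  structure(list(
    n_compared = n_compared, n_matched = n_matched,
    n_source_only = n_source_only, n_extraction_only = n_extraction_only,
    n_resolved = n_resolved,
    congruity_rate = if (n_compared > 0) n_matched / n_compared else NA_real_,
    post_audit_rate = if (n_compared > 0)
      (n_matched + n_resolved) / n_compared else NA_real_,
    per_table = per_table, per_criterion = per_criterion, detail = detail
  ), class = "congruity_report")
}

#' @export
print.congruity_report <- function(x, ...) {
  cat(sprintf("<congruity_report> %d items compared\n", x$n_compared))
  cat(sprintf("  matched %d | source-only %d | extraction-only %d (resolved %d)\n",
              x$n_matched, x$n_source_only, x$n_extraction_only, x$n_resolved))
  cat(sprintf("  congruity %.1f%% | post-audit %.1f%%\n",
              pct1(x$congruity_rate), pct1(x$post_audit_rate)))
  invisible(x)
}

#' Diagnostic accuracy of a test caseset against a reference
#'
#' Builds the 2x2 confusion matrix of two casesets over the same population
#' and the four derived accuracy metrics. The reference caseset is treated
#' as truth: tp = |test n ref|, fp = |test \ ref|, fn = |ref \ test|,
#' tn = n_total - tp - fp - fn. Metrics are exact ratios, also reported
#' rounded half-up to one decimal percent.
#'
#' @param test,reference `case_set` objects or character PIN vectors.
#' @param n_total Number of persons in the population both casesets were
#'   drawn from.
#' @return A `diagnostic_metrics` object (counts, raw proportions, and
#'   `pct` with the rounded percentages).
#' @export
compute_diagnostic_metrics <- function(test, reference, n_total) {
  test <- unique(case_pins(test))
  reference <- unique(case_pins(reference))
  if (n_total < length(union(test, reference))) {
    stopf("inconsistent n_total: smaller than |test U reference|")
  }
  tp <- length(intersect(test, reference))
  fp <- length(setdiff(test, reference))
  fn <- length(setdiff(reference, test))
  tn <- n_total - tp - fp - fn
  ratio <- function(a, b) if (b > 0) a / b else NA_real_
  res <- list(
    tp = tp, fp = fp, fn = fn, tn = tn, n_total = n_total,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn)
  )
  res$pct <- lapply(res[c("sensitivity", "specificity", "ppv", "npv")], pct1)
  structure(res, class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf("<diagnostic_metrics> tp %d fp %d fn %d tn %d (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n_total))
  cat(sprintf("  sensitivity %5.1f%% | specificity %5.1f%% | PPV %5.1f%% | NPV %5.1f%%\n",
              x$pct$sensitivity, x$pct$specificity, x$pct$ppv, x$pct$npv))
  invisible(x)
}

#' Venn partition of the three inclusion criteria
#'
#' Counts the seven regions of the three-criterion Venn diagram over a
#' caseset's per-PIN flags, plus the reconstructed marginals and union.
#'
#' @param caseset A `case_set`.
#' @return A `venn_partition`: list with `regions` (named 7-vector),
#'   `marginals` (`icd`, `atc`, `lab`) and `union`.
#' @export
compute_venn_partition <- function(caseset) {
  i <- caseset$by_icd
  a <- caseset$by_atc
  l <- caseset$by_lab
  regions <- c(
    icd_only = sum(i & !a & !l), atc_only = sum(!i & a & !l),
    lab_only = sum(!i & !a & l), icd_atc = sum(i & a & !l),
    icd_lab = sum(i & !a & l), atc_lab = sum(!i & a & l),
    all_three = sum(i & a & l)
  )
  structure(list(
    regions = regions,
    marginals = c(icd = sum(i), atc = sum(a), lab = sum(l)),
    union = nrow(caseset)
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> union %d (ICD %d, ATC %d, lab %d)\n",
              x$union, x$marginals[["icd"]], x$marginals[["atc"]],
              x$marginals[["lab"]]))
  for (r in names(x$regions)) {
    cat(sprintf("  %-10s %5d\n", r, x$regions[[r]]))
  }
  invisible(x)
}

#' Prevalence of the reference caseset in the source population
#'
#' @param reference A `case_set` or PIN vector (the reference extraction).
#' @param n_total Number of persons in the population.
#' @return List with `n_cases`, `n_total`, `prevalence` (raw proportion)
#'   and `pct` (rounded half-up to one decimal percent).
#' @export
compute_prevalence <- function(reference, n_total) {
  if (n_total <= 0) {
    stopf("undefined prevalence: n_total must be > 0")
  }
  n_cases <- length(unique(case_pins(reference)))
  p <- n_cases / n_total
  list(n_cases = n_cases, n_total = n_total, prevalence = p, pct = pct1(p))
}
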