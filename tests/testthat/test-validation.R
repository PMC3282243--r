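test_that("a sufficient caseset yields 63 distinct PINs, 21 per criterion", {
  cf <- generate_congruity_fixture(seed = 3)
  cs <- find_cases(cf$db, t2dm_criteria("deletion_blind"))
  s <- select_audit_sample(cs, cf$db, sampling_plan(seed = 123))
  expect_equal(nrow(s), 63)
  expect_equal(anyDuplicated(s$pin), 0)
  expect_equal(unname(table(s$criterion)[c("icd", "lab", "atc")]),
               rep(21L, 3), ignore_attr = TRUE)
  expect_equal(unname(table(s$criterion, s$period_index)),
               matrix(7L, 3, 3), ignore_attr = TRUE)
})

test_that("a stratum with exactly the quota is selected in full at any seed", {
  cf <- generate_congruity_fixture(seed = 9)
  cs <- find_cases(cf$db, t2dm_criteria("deletion_blind"))
  picks <- lapply(c(1, 99, 4242), function(seed) {
    s <- select_audit_sample(cs, cf$db, sampling_plan(seed = seed))
    sort(s$pin)
  })
  expect_equal(picks[[1]], sort(cs$pin))
  expect_equal(picks[[2]], picks[[1]])
  expect_equal(picks[[3]], picks[[1]])
})

test_that("cross-criterion exclusion prevents duplicate PINs", {
  # overlapping criteria: every case qualifies by all three
  fx <- generate_fixture_from_marginals(30, 30, 30, 30, seed = 5)
  cs <- find_cases(fx$db, t2dm_criteria("deletion_blind"))
  for (seed in 1:20) {
    s <- suppressWarnings(
      select_audit_sample(cs, fx$db, sampling_plan(pins_per_stratum = 2,
                                                   seed = seed))
    )
    expect_equal(anyDuplicated(s$pin), 0)
    log <- attr(s, "exclusion_log")
    expect_true(!is.null(log) && nrow(log) > 0)
  }
})

test_that("stratum shortfall warns and returns a partial sample", {
  fx <- generate_fixture_from_marginals(4, 4, 0, 0, seed = 2)
  cs <- find_cases(fx$db, t2dm_criteria("deletion_blind"))
  w <- capture_warnings(
    s <- select_audit_sample(cs, fx$db, sampling_plan(seed = 1))
  )
  expect_true(all(grepl("shortfall", w)))
  expect_gt(length(w), 0)  # one warning per deficient stratum
  expect_lt(nrow(s), 63)
})

test_that("sampling is reproducible under a fixed seed", {
  pop <- generate_emr(synth_config(n_patients = 2500, seed = 8))
  cs <- find_cases(pop$db, t2dm_criteria("deletion_blind"))
  s1 <- suppressWarnings(select_audit_sample(cs, pop$db,
                                             sampling_plan(seed = 7)))
  s2 <- suppressWarnings(select_audit_sample(cs, pop$db,
                                             sampling_plan(seed = 7)))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("an uncorrupted register with no deletions is fully congruent", {
  db <- tiny_db()
  cs <- find_cases(db, t2dm_criteria())
  reg <- extract_register(db, cs)
  rep <- compare_items(reg, db, cs$pin)
  expect_equal(rep$congruity_rate, 1.0)
  expect_equal(rep$n_compared, register_item_count(reg))
  expect_equal(rep$n_extraction_only, 0)
})

test_that("k injected field corruptions give exactly k mismatches with diffs", {
  cf <- generate_congruity_fixture(seed = 2, n_deleted_contacts = 0)
  cs <- find_cases(cf$db, t2dm_criteria("deletion_blind"))
  reg <- extract_register(cf$db, cs)
  k <- 7
  reg$Contacts$user_id[seq_len(k)] <- "CORRUPT"
  rep <- compare_items(reg, cf$db, select_audit_sample(
    cs, cf$db, sampling_plan(seed = 1)
  ))
  expect_equal(rep$n_source_only, k)
  diffs <- rep$detail$field_diff[rep$detail$status == "source_only"]
  expect_true(all(diffs == "user_id"))
  expect_equal(rep$n_matched, rep$n_compared - k)
})

test_that("soft-deleted source entries are extraction-only until resolved", {
  db <- tiny_db()
  db$contacts$deleted[2] <- TRUE
  cs <- find_cases(db, t2dm_criteria())
  reg <- extract_register(db, cs, extraction_spec(include_deleted = TRUE))
  rep <- compare_items(reg, db, cs$pin)
  expect_equal(rep$n_extraction_only, 1)
  expect_equal(rep$n_resolved, 1)
  expect_lt(rep$congruity_rate, 1)
  expect_equal(rep$post_audit_rate, 1)
  tab <- rep$per_table
  expect_equal(tab$extraction_only[tab$table == "Contacts"], 1)
})

test_that("audit classification is exhaustive over sampled PINs", {
  cf <- generate_congruity_fixture(seed = 11)
  cs <- find_cases(cf$db, t2dm_criteria("deletion_blind"))
  reg <- extract_register(cf$db, cs)
  s <- select_audit_sample(cs, cf$db, sampling_plan(seed = 2))
  rep <- compare_items(reg, cf$db, s)
  expect_equal(rep$n_matched + rep$n_source_only + rep$n_extraction_only,
               rep$n_compared)
  expect_equal(rep$n_compared, register_item_count(reg))  # all PINs sampled
})

test_that("period-restricted auditing is a subset of the full audit", {
  cf <- generate_congruity_fixture(seed = 13)
  cs <- find_cases(cf$db, t2dm_criteria("deletion_blind"))
  reg <- extract_register(cf$db, cs)
  full <- compare_items(reg, cf$db,
                        select_audit_sample(cs, cf$db, sampling_plan(seed = 5)))
  restricted <- compare_items(
    reg, cf$db,
    select_audit_sample(cs, cf$db,
                        sampling_plan(seed = 5, restrict_to_period = TRUE))
  )
  expect_lt(restricted$n_compared, full$n_compared)
  expect_true(all(restricted$detail$item_id %in% full$detail$item_id))
})

test_that("diagnostic metrics are exact ratios of the confusion counts", {
  m <- compute_diagnostic_metrics(test = c("a", "b", "c"),
                                  reference = c("b", "c", "d"),
                                  n_total = 10)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(2, 1, 1, 6))
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 6 / 7)
  expect_equal(m$ppv, 2 / 3)
  expect_equal(m$npv, 6 / 7)
  identical_sets <- compute_diagnostic_metrics(letters[1:5], letters[1:5], 50)
  expect_equal(identical_sets$sensitivity, 1)
  expect_equal(identical_sets$specificity, 1)
  expect_equal(identical_sets$ppv, 1)
  expect_equal(identical_sets$npv, 1)
  expect_error(compute_diagnostic_metrics(letters[1:5], letters[6:10], 8),
               "inconsistent")
})

test_that("metrics equal a brute-force confusion matrix on random casesets", {
  pins <- sprintf("P%03d", 1:200)
  for (seed in 1:10) {
    set.seed(seed)
    test <- sample(pins, sample(0:80, 1))
    ref <- sample(pins, sample(0:80, 1))
    m <- compute_diagnostic_metrics(test, ref, 200)
    conf <- table(factor(pins %in% test, c(TRUE, FALSE)),
                  factor(pins %in% ref, c(TRUE, FALSE)))
    expect_equal(m$tp, conf["TRUE", "TRUE"], ignore_attr = TRUE)
    expect_equal(m$fp, conf["TRUE", "FALSE"], ignore_attr = TRUE)
    expect_equal(m$fn, conf["FALSE", "TRUE"], ignore_attr = TRUE)
    expect_equal(m$tn, conf["FALSE", "FALSE"], ignore_attr = TRUE)
    expect_equal(m$tp + m$fp + m$fn + m$tn, 200)
  }
})

test_that("three disjoint criterion sets fill only the singleton regions", {
  fx <- generate_fixture_from_marginals(9, 3, 3, 3,
                                        region_counts = c(3, 3, 3, 0, 0, 0, 0),
                                        seed = 1)
  cs <- find_cases(fx$db, t2dm_criteria("deletion_blind"))
  v <- compute_venn_partition(cs)
  expect_equal(unname(v$regions[c("icd_only", "atc_only", "lab_only")]),
               c(3, 3, 3))
  expect_equal(sum(v$regions[4:7]), 0)
})

test_that("venn regions sum to the union and reconstruct the marginals", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(1:60, 1)
    flags <- matrix(runif(n * 3) < 0.5, ncol = 3)
    flags[rowSums(flags) == 0, sample(3, 1)] <- TRUE
    cs <- tibble::tibble(pin = sprintf("V%03d", 1:n),
                         by_icd = flags[, 1], by_atc = flags[, 2],
                         by_lab = flags[, 3])
    v <- compute_venn_partition(cs)
    expect_equal(sum(v$regions), n)
    expect_equal(v$marginals[["icd"]],
                 sum(v$regions[c("icd_only", "icd_atc", "icd_lab",
                                 "all_three")]))
    expect_equal(v$marginals[["atc"]],
                 sum(v$regions[c("atc_only", "icd_atc", "atc_lab",
                                 "all_three")]))
    expect_equal(v$marginals[["lab"]],
                 sum(v$regions[c("lab_only", "icd_lab", "atc_lab",
                                 "all_three")]))
  }
})

test_that("prevalence is the exact ratio with half-up percent rounding", {
  p <- compute_prevalence(sprintf("x%d", 1:433), 10753)
  expect_equal(p$prevalence, 433 / 10753)
  expect_equal(p$pct, 4.0)
  expect_equal(compute_prevalence(character(), 100)$prevalence, 0)
  expect_error(compute_prevalence("a", 0), "undefined")
  # independent division check on random sizes
  for (k in c(1, 17, 250)) {
    expect_equal(compute_prevalence(sprintf("p%d", seq_len(k)), 1000)$prevalence,
                 k / 1000)
  }
})
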