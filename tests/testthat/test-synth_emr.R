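test_that("zero prevalence yields zero true cases", {
  pop <- generate_population(synth_config(n_patients = 500, prevalence = 0,
                                          seed = 1))
  expect_equal(sum(pop$truth$is_case), 0)
  expect_equal(nrow(pop$truth), 500)
})

test_that("generated databases pass validation", {
  pop <- generate_emr(synth_config(n_patients = 300, seed = 7))
  expect_equal(nrow(validate_database(pop$db)), 0)
})

test_that("identical seed and config give byte-identical on-disk output", {
  cfg <- synth_config(n_patients = 150, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_database(generate_emr(cfg)$db, d1)
  write_database(generate_emr(cfg)$db, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("invalid probabilities raise a configuration error", {
  expect_error(synth_config(prevalence = 1.2), "configuration error")
  expect_error(synth_config(p_deleted_contact = -0.1), "configuration error")
  expect_error(synth_config(period = as.Date(c("2000-01-01", "1999-01-01"))),
               "configuration error")
})

test_that("case counts are binomially calibrated", {
  n <- 4000
  pop <- generate_population(synth_config(n_patients = n, seed = 5))
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.04)
  k <- sum(pop$truth$is_case)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("documentation-probability calibration solves its fixed point", {
  m <- c(icd = 0.53, atc = 0.38, lab = 0.91)
  p <- calibrate_documentation_probs(m)
  q <- prod(1 - p)
  expect_equal(unname(p / (1 - q)), unname(m), tolerance = 1e-9)
})

test_that("deletion injection only toggles flags and conserves counts", {
  cfg <- synth_config(n_patients = 400, seed = 13, p_deleted_contact = 0.05)
  pop <- generate_population(cfg)
  out <- inject_soft_deletions(pop$db, pop$truth, cfg)
  for (m in c("contacts", "diagnoses", "drugs", "labs")) {
    expect_equal(nrow(out$db[[m]]), nrow(pop$db[[m]]), info = m)
  }
  # flags only set on A10B prescriptions of flagged non-cases and contacts
  changed <- out$db$drugs$deleted & !pop$db$drugs$deleted
  expect_true(all(out$db$drugs$pin[changed] %in%
                    pop$truth$pin[pop$truth$stray_rx]))
  expect_true(any(out$db$contacts$deleted))
})

test_that("zero deletion probabilities leave the database unchanged", {
  cfg <- synth_config(n_patients = 200, seed = 3,
                      p_deleted_rx_noncase = 0, p_deleted_contact = 0)
  pop <- generate_population(cfg)
  out <- inject_soft_deletions(pop$db, pop$truth, cfg)
  expect_identical(as.data.frame(out$db$drugs), as.data.frame(pop$db$drugs))
  expect_identical(as.data.frame(out$db$contacts),
                   as.data.frame(pop$db$contacts))
})

test_that("a deleted-prescription quota produces exactly that deletion-mode gap", {
  cfg <- synth_config(n_patients = 3000, seed = 21, quota_deleted_rx = 12,
                      p_deleted_contact = 0)
  out <- generate_emr(cfg)
  expect_equal(sum(out$truth$deleted_rx), 12)
  blind <- find_cases(out$db, t2dm_criteria("deletion_blind"))
  aware <- find_cases(out$db, t2dm_criteria("deletion_aware"))
  expect_equal(nrow(blind) - nrow(aware), 12)
})

test_that("marginal fixtures achieve requested marginals exactly", {
  fx <- generate_fixture_from_marginals(445, 234, 169, 405, seed = 2)
  cs <- find_cases(fx$db, t2dm_criteria("deletion_blind"))
  expect_equal(nrow(cs), 445)
  expect_equal(sum(cs$by_icd), 234)
  expect_equal(sum(cs$by_atc), 169)
  expect_equal(sum(cs$by_lab), 405)
})

test_that("disjoint singleton marginals flag each patient by one criterion", {
  fx <- generate_fixture_from_marginals(3, 1, 1, 1, seed = 1)
  cs <- find_cases(fx$db, t2dm_criteria("deletion_blind"))
  expect_equal(nrow(cs), 3)
  expect_equal(rowSums(cbind(cs$by_icd, cs$by_atc, cs$by_lab)),
               rep(1, 3), ignore_attr = TRUE)
})

test_that("random feasible marginals are reproduced and satisfy inclusion-exclusion", {
  for (seed in 1:10) {
    set.seed(seed)
    total <- sample(5:40, 1)
    m <- vapply(1:3, function(i) sample(0:total, 1), 0L)
    if (sum(m) < total) m[1] <- m[1] + (total - sum(m))
    if (m[1] > total) next
    fx <- generate_fixture_from_marginals(total, m[1], m[2], m[3], seed = seed)
    cs <- find_cases(fx$db, t2dm_criteria("deletion_blind"))
    expect_equal(nrow(cs), total)
    expect_equal(c(sum(cs$by_icd), sum(cs$by_atc), sum(cs$by_lab)), m,
                 ignore_attr = TRUE)
    v <- compute_venn_partition(cs)
    # inclusion-exclusion: union = sum of marginals - pairwise + triple
    pairwise <- sum(v$regions[c("icd_atc", "icd_lab", "atc_lab")]) +
      3 * v$regions[["all_three"]]
    expect_equal(v$union, sum(v$marginals) - pairwise +
                   v$regions[["all_three"]])
  }
})

test_that("infeasible marginals are rejected explicitly", {
  expect_error(solve_venn_regions(10, 11, 0, 0), "infeasible")
  expect_error(solve_venn_regions(10, 3, 3, 3), "infeasible")
  expect_error(generate_fixture_from_marginals(5, 6, 0, 0), "infeasible")
})

test_that("explicit region counts are honoured and cross-checked", {
  r <- c(icd_only = 1, atc_only = 1, lab_only = 1, icd_atc = 1,
         icd_lab = 1, atc_lab = 1, all_three = 1)
  fx <- generate_fixture_from_marginals(7, 4, 4, 4, region_counts = r,
                                        seed = 1)
  cs <- find_cases(fx$db, t2dm_criteria("deletion_blind"))
  expect_equal(compute_venn_partition(cs)$regions, r, ignore_attr = TRUE)
  expect_error(
    generate_fixture_from_marginals(7, 5, 4, 4, region_counts = r),
    "do not reproduce"
  )
})

test_that("documentation probabilities are recoverable from ground truth", {
  cfg <- synth_config(n_patients = 6000, seed = 31)
  pop <- generate_population(cfg)
  cases <- pop$truth[pop$truth$is_case, ]
  n_case <- nrow(cases)
  for (sig in c("sig_icd", "sig_atc", "sig_lab")) {
    p_hat <- mean(cases[[sig]])
    p_true <- switch(sig, sig_icd = cfg$p_icd_documented,
                     sig_atc = cfg$p_atc_documented,
                     sig_lab = cfg$p_lab_documented)
    se <- sqrt(p_true * (1 - p_true) / n_case)
    expect_lt(abs(p_hat - p_true), 4 * se)
  }
})
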