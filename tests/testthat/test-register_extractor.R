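test_that("an empty caseset yields nine empty tables", {
  db <- tiny_db()
  cs <- find_cases(db, inclusion_criteria(atc_prefixes = "ZZZ"))
  reg <- extract_register(db, cs)
  expect_named(reg, c("Patients", "Contacts", "Diagnosis", "Drugs",
                      "Biochemical analysis", "Biometrics", "Documents",
                      "Measurement", "Terminology"), ignore.order = TRUE)
  expect_equal(register_item_count(reg), 0)
})

test_that("deleted contacts are emitted with a provenance mark when asked", {
  db <- tiny_db()
  db$contacts$deleted[1:2] <- TRUE  # both T1 contacts
  cs <- find_cases(db, t2dm_criteria())
  reg <- extract_register(db, cs, extraction_spec(include_deleted = TRUE))
  t1_contacts <- reg$Contacts[reg$Contacts$pin == "T1", ]
  expect_equal(nrow(t1_contacts), 2)
  expect_true(all(t1_contacts$deleted))
  reg2 <- extract_register(db, cs, extraction_spec(include_deleted = FALSE))
  expect_equal(nrow(reg2$Contacts[reg2$Contacts$pin == "T1", ]), 0)
})

test_that("per-PIN row counts equal brute-force filter counts", {
  for (seed in c(4, 8, 15)) {
    db <- random_small_db(seed)
    cs <- find_cases(db, t2dm_criteria())
    reg <- extract_register(db, cs, extraction_spec(include_deleted = TRUE))
    for (pin in cs$pin) {
      expect_equal(sum(reg$Diagnosis$pin == pin),
                   sum(db$diagnoses$pin == pin))
      expect_equal(sum(reg$Drugs$pin == pin), sum(db$drugs$pin == pin))
      expect_equal(sum(reg$`Biochemical analysis`$pin == pin),
                   sum(db$labs$pin == pin))
    }
    # no rows from outside the caseset
    for (tname in names(reg)) {
      expect_true(all(reg[[tname]]$pin %in% cs$pin))
    }
  }
})

test_that("rows are date-sorted with stable ties", {
  db <- tiny_db()
  db$contacts <- tibble::tibble(
    pin = "T1",
    date = as.Date(c("1999-06-01", "1995-01-10", "1995-01-10")),
    contact_type = c("doctor", "nurse", "telephone"),
    user_id = c("U01", "U02", "U03"), deleted = FALSE
  )
  cs <- find_cases(db, t2dm_criteria())
  reg <- extract_register(db, cs)
  expect_equal(reg$Contacts$user_id, c("U02", "U03", "U01"))
  expect_false(is.unsorted(reg$Contacts$date))
})

test_that("every register item maps back to a source entry", {
  db <- random_small_db(23)
  cs <- find_cases(db, t2dm_criteria())
  reg <- extract_register(db, cs)
  mod_of <- c(Patients = "patients", Contacts = "contacts",
              Diagnosis = "diagnoses", Drugs = "drugs",
              `Biochemical analysis` = "labs", Biometrics = "biometrics",
              Documents = "documents", Measurement = "measurements",
              Terminology = "narrative")
  for (tname in names(reg)) {
    src_ids <- registerforge:::item_ids(mod_of[[tname]], db[[mod_of[[tname]]]])
    expect_true(all(reg[[tname]]$item_id %in% src_ids), info = tname)
  }
})

test_that("enlarging the caseset never shrinks any table", {
  db <- random_small_db(31)
  crit_small <- inclusion_criteria(
    icd_patterns = data.frame(version = 10, prefix = "E11"),
    deletion_mode = "deletion_blind"
  )
  cs_small <- find_cases(db, crit_small)
  cs_big <- find_cases(db, t2dm_criteria("deletion_blind"))
  reg_small <- extract_register(db, cs_small)
  reg_big <- extract_register(db, cs_big)
  for (tname in names(reg_small)) {
    expect_gte(nrow(reg_big[[tname]]), nrow(reg_small[[tname]]))
  }
})

test_that("a stale caseset is refused", {
  db <- tiny_db()
  cs <- find_cases(db, t2dm_criteria())
  db$drugs$dosage[1] <- "850 mg 1x2"
  expect_error(extract_register(db, cs), "stale caseset")
})

test_that("unknown table names are rejected in the spec", {
  expect_error(extraction_spec(tables = c("Patients", "Bogus")),
               "unknown register table")
  expect_error(extraction_spec(tables = "Terminology",
                               subheadings = character()),
               "subheadings")
})

test_that("narrative extraction filters by subheading exactly", {
  db <- tiny_db()
  cs <- find_cases(db, t2dm_criteria())  # T1 (icd), T2 (atc)
  all_rows <- extract_narrative(db, cs, "*")
  expect_equal(nrow(all_rows), 3)
  heritage <- extract_narrative(db, cs, "heritage")
  expect_equal(nrow(heritage), 2)
  expect_true(all(heritage$subheading == "heritage"))
  # excluded PIN's narrative never appears
  db2 <- tiny_db()
  db2$narrative$pin <- "T3"  # T3 meets no criterion
  cs2 <- find_cases(db2, t2dm_criteria())
  expect_equal(nrow(extract_narrative(db2, cs2, "*")), 0)
  expect_error(extract_narrative(db, cs, character()), "non-empty")
})

test_that("date-range filters restrict dated tables", {
  db <- tiny_db()
  cs <- find_cases(db, t2dm_criteria())
  reg <- extract_register(db, cs, extraction_spec(
    date_range = as.Date(c("1999-01-01", "2005-12-31"))
  ))
  expect_true(all(reg$Contacts$date >= as.Date("1999-01-01")))
  expect_equal(nrow(reg$Contacts), 2)  # 1999 and 2000 contacts only
  expect_equal(nrow(reg$Patients), 2)  # static table untouched
})

test_that("a register round-trips to disk with provenance", {
  db <- tiny_db()
  db$contacts$deleted[1] <- TRUE
  cs <- find_cases(db, t2dm_criteria())
  reg <- extract_register(db, cs)
  path <- withr::local_tempdir()
  write_register(reg, path)
  expect_true(file.exists(file.path(path, "Biochemical analysis.csv")))
  prov <- jsonlite::read_json(file.path(path, "provenance.json"))
  expect_equal(unlist(prov$Contacts$items), reg$Contacts$item_id)
  expect_equal(unlist(prov$Contacts$deleted), reg$Contacts$deleted)
})
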