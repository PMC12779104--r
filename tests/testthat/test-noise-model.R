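test_that("target selection follows the two-parameter arithmetic", {
  # build a table population with exactly 1000 eligible cells:
  # 250 ADMISSIONS rows x 4 non-key cells
  t <- small_cohort(n = 4, seed = 1)
  adm <- t$ADMISSIONS[rep(1, 250), ]
  adm$HADM_ID <- as.character(seq_len(250))
  t$ADMISSIONS <- adm
  t$PATIENTS <- t$PATIENTS[0, ]
  t$CPTEVENTS <- t$CPTEVENTS[0, ]
  t$DIAGNOSES_ICD <- t$DIAGNOSES_ICD[0, ]
  expect_equal(nrow(eligible_cells(t)), 1000)

  sel <- select_targets(t, noise_config(0.50, 0.25, seed = 3))
  expect_equal(nrow(sel$missing), 125)
  expect_equal(nrow(sel$inconsistent), 375)

  # disjoint cells, reproducible under seed
  key <- function(df) paste(df$table, df$row, df$field)
  expect_length(intersect(key(sel$missing), key(sel$inconsistent)), 0)
  sel2 <- select_targets(t, noise_config(0.50, 0.25, seed = 3))
  expect_identical(sel, sel2)

  # zero noise selects nothing; (1, 1) makes everything missing
  sel0 <- select_targets(t, noise_config(0, 1, seed = 3))
  expect_equal(nrow(sel0$missing) + nrow(sel0$inconsistent), 0)
  sel11 <- select_targets(t, noise_config(1, 1, seed = 3))
  expect_equal(nrow(sel11$missing), 1000)
  expect_equal(nrow(sel11$inconsistent), 0)

  # fractional counts round half away from zero: 3 cells at 0.5 -> 2 altered
  t3 <- tiny_tables()
  t3$ADMISSIONS <- t3$ADMISSIONS[0, ]
  t3$CPTEVENTS <- t3$CPTEVENTS[0, ]  # leaves GENDER, DOB, ICD9_CODE
  sel3 <- select_targets(t3, noise_config(0.5, 0, seed = 1))
  expect_equal(nrow(sel3$inconsistent), 2)
})

test_that("missing target sets are nested across completeness ratios", {
  t <- small_cohort(n = 15, seed = 4)
  key <- function(df) paste(df$table, df$row, df$field)
  prev <- character(0)
  for (ratio in c(0.25, 0.5, 0.75, 1)) {
    sel <- select_targets(t, noise_config(0.8, ratio, seed = 5))
    expect_true(all(prev %in% key(sel$missing)))
    prev <- key(sel$missing)
  }
})

test_that("gender swap exchanges the two codes", {
  g <- gender_codes()
  male <- g$code[g$label == "male"]
  female <- g$code[g$label == "female"]
  expect_equal(gender_swap(male), female)
  expect_equal(gender_swap(female), male)
  expect_true(is.na(gender_swap("not-a-code")))
})

test_that("age alteration always moves the patient to a different age group", {
  ref <- parse_iso8601("2110-01-01T00:00:00+00:00")
  weights <- c(10, 20, 50, 20)
  set.seed(42)
  for (age0 in c(0, 5, 30, 70)) {
    dob <- format_iso8601(ref - age0 * 365.2425 * 86400)
    g0 <- age_group_of(age_years(parse_iso8601(dob), ref))
    for (i in 1:25) {
      new <- age_alteration(dob, ref, weights)
      g1 <- age_group_of(age_years(parse_iso8601(new), ref))
      expect_false(g1 == g0)
    }
  }
  expect_error(age_alteration(format_iso8601(ref), ref, 1, age_groups()[1, ]),
               "fewer than two groups")
})

test_that("age alteration respects renormalized dataset frequencies", {
  # altered infants land in each other group with probability proportional
  # to that group's weight after excluding the infant group
  ref <- parse_iso8601("2110-01-01T00:00:00+00:00")
  dob <- format_iso8601(ref - 0.5 * 365.2425 * 86400)  # an infant
  weights <- c(infant = 0.10, child = 0.20, adult = 0.30, senior = 0.40)
  set.seed(99)
  draws <- replicate(10000, {
    age_group_of(age_years(parse_iso8601(age_alteration(dob, ref, weights)), ref))
  })
  freq <- table(factor(draws, levels = c("child", "adult", "senior"))) / 10000
  expected <- c(0.20, 0.30, 0.40) / 0.90
  expect_true(all(abs(as.numeric(freq) - expected) < 0.02))
  chi <- stats::chisq.test(table(factor(draws, levels = c("child", "adult", "senior"))),
                           p = expected)
  expect_gt(chi$p.value, 0.001)
})

test_that("admit/discharge swap exchanges the timestamps", {
  rec <- data.frame(ADMITTIME = "2103-01-02T00:00:00+00:00",
                    DISCHTIME = "2103-01-05T00:00:00+00:00", stringsAsFactors = FALSE)
  out <- swap_admit_discharge(rec)
  expect_equal(out$ADMITTIME, "2103-01-05T00:00:00+00:00")
  expect_equal(out$DISCHTIME, "2103-01-02T00:00:00+00:00")
  rec$DISCHTIME <- ""
  expect_warning(out <- swap_admit_discharge(rec), "missing")
  expect_identical(out, rec)
})

test_that("day/month transposition is textual and may produce invalid dates", {
  expect_equal(day_month_swap("2103-03-25T10:00:00+00:00"),
               "2103-25-03T10:00:00+00:00")
  expect_true(is.na(parse_iso8601("2103-25-03T10:00:00+00:00")))
  # both components <= 12: valid but chronologically shifted
  expect_equal(day_month_swap("2103-05-12T10:00:00+00:00"),
               "2103-12-05T10:00:00+00:00")
  expect_false(is.na(parse_iso8601("2103-12-05T10:00:00+00:00")))
  # day == month: fixed point
  expect_equal(day_month_swap("2103-04-04T10:00:00+00:00"),
               "2103-04-04T10:00:00+00:00")
})

test_that("code substitution is uniform over the remaining codes", {
  expect_equal(code_substitution("a", c("a", "b")), "b")  # forced with 2 codes
  pool <- procedure_codes()$code
  expect_length(pool, 15)
  set.seed(7)
  draws <- replicate(10000, code_substitution(pool[1], pool))
  expect_false(any(draws == pool[1]))
  counts <- table(factor(draws, levels = pool[-1]))
  chi <- stats::chisq.test(counts)  # uniform over the 14 alternatives
  expect_gt(chi$p.value, 0.001)
  expect_error(code_substitution("a", "a"), "at least 2 codes")
})

test_that("field deletion blanks exactly the targeted cells", {
  t <- small_cohort(n = 10, seed = 6)
  sel <- select_targets(t, noise_config(0.5, 1, seed = 2))
  out <- delete_fields(t, sel$missing)
  for (i in seq_len(nrow(sel$missing))) {
    expect_identical(out[[sel$missing$table[i]]][sel$missing$row[i], sel$missing$field[i]], "")
  }
  expect_identical(delete_fields(t, sel$missing[0, ]), t)
  # diagnosis rows only ever lose their ICD9 code
  expect_true(all(sel$missing$field[sel$missing$table == "DIAGNOSES_ICD"] == "ICD9_CODE"))
})

test_that("ADMISSIONS deletion shares are near 25% per field", {
  t <- small_cohort(n = 2, seed = 1)
  adm <- t$ADMISSIONS[rep(1, 6000), ]
  adm$HADM_ID <- as.character(seq_len(6000))
  t$ADMISSIONS <- adm
  t$PATIENTS <- t$PATIENTS[0, ]
  t$CPTEVENTS <- t$CPTEVENTS[0, ]
  t$DIAGNOSES_ICD <- t$DIAGNOSES_ICD[0, ]
  sel <- select_targets(t, noise_config(0.5, 1, seed = 11))
  shares <- table(sel$missing$field) / nrow(sel$missing)
  expect_length(shares, 4)
  expect_true(all(abs(shares - 0.25) < 0.02))
})

test_that("injection is reproducible, ledgered and leaves non-targets untouched", {
  t <- small_cohort(n = 25, seed = 8)
  cfg <- noise_config(0.4, 0.3, seed = 42)
  inj1 <- inject_noise(t, cfg)
  inj2 <- inject_noise(t, cfg)
  expect_identical(inj1$tables, inj2$tables)
  expect_identical(as.data.frame(inj1$ledger), as.data.frame(inj2$ledger))

  # ledger partition matches the selection arithmetic
  sel <- select_targets(t, cfg)
  led <- inj1$ledger
  expect_equal(sum(led$targeted & led$kind == "missing"), nrow(sel$missing))
  expect_equal(sum(led$targeted & led$kind == "inconsistent"), nrow(sel$inconsistent))
  expect_true(all((led$kind == "missing") == (led$new_value == "")))

  # every differing cell is ledgered; every unledgered cell is untouched
  led_key <- paste(led$table, led$row, led$field)
  for (nm in names(t)) {
    for (col in setdiff(names(t[[nm]]), c("SUBJECT_ID", "HADM_ID"))) {
      changed <- which(t[[nm]][[col]] != inj1$tables[[nm]][[col]])
      expect_true(all(paste(nm, changed, col) %in% led_key))
    }
  }
  # keys are never corrupted
  expect_identical(inj1$tables$ADMISSIONS$HADM_ID, t$ADMISSIONS$HADM_ID)
  expect_identical(inj1$tables$PATIENTS$SUBJECT_ID, t$PATIENTS$SUBJECT_ID)

  # zero noise is the identity with an empty ledger
  inj0 <- inject_noise(t, noise_config(0, 0.5, seed = 1))
  expect_identical(inj0$tables, t)
  expect_equal(nrow(inj0$ledger), 0)

  # full-consistency boundary: no missing cells, all entries inconsistent
  injc <- inject_noise(t, noise_config(1, 0, seed = 1))
  expect_true(all(injc$ledger$kind == "inconsistent"))
  expect_false(any(injc$tables$PATIENTS$GENDER == ""))
})

test_that("ledgers round-trip through CSV and serialize as JSON lines", {
  t <- small_cohort(n = 10, seed = 3)
  inj <- inject_noise(t, noise_config(0.5, 0.5, seed = 2))
  p <- withr::local_tempfile(fileext = ".csv")
  write_ledger(inj$ledger, p)
  expect_identical(as.data.frame(read_ledger(p)), as.data.frame(inj$ledger))
  pj <- withr::local_tempfile(fileext = ".jsonl")
  write_ledger(inj$ledger, pj, format = "jsonl")
  lines <- readLines(pj)
  expect_length(lines, nrow(inj$ledger))
  first <- jsonlite::fromJSON(lines[1])
  expect_equal(first$field, inj$ledger$field[1])
})

test_that("noise config validation rejects out-of-range parameters", {
  expect_error(noise_config(1.2, 0), "configuration error")
  expect_error(noise_config(0.5, -0.1), "configuration error")
})
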