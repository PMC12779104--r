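male <- function() gender_codes()$code[gender_codes()$label == "male"]
female <- function() gender_codes()$code[gender_codes()$label == "female"]

test_that("ruleset compilation expands shapes per pairing and per code", {
  # 2 gender-specific diagnosis codes x 1 allowed gender each -> 2 shapes
  two <- code_constraints(data.frame(
    code = c("185", "183.0"), kind = "diagnosis",
    allowed_genders = c(male(), female()),
    age_min = c(40, 12), age_max = c(124, 124), stringsAsFactors = FALSE
  ))
  rules <- compile_ruleset(two)
  counts <- shape_counts(rules)
  expect_equal(unname(counts["diagnosis_gender"]), 2L)
  expect_equal(unname(counts["diagnosis_age"]), 2L)
  expect_equal(unname(counts["conditional_completeness"]), 1L)
  expect_equal(unname(counts["essential_completeness"]), 9L)
  expect_equal(unname(counts["datatype"]), 4L)
  expect_equal(unname(counts["time_sequence"]), 4L)

  # a both-gender code contributes one shape per pairing
  both <- code_constraints(data.frame(
    code = "486", kind = "diagnosis",
    allowed_genders = paste(male(), female(), sep = "|"),
    age_min = 0, age_max = 124, stringsAsFactors = FALSE
  ))
  expect_equal(unname(shape_counts(compile_ruleset(both))["diagnosis_gender"]), 2L)

  # empty constraint list: only ontology-based shapes
  none <- compile_ruleset(two[0, ])
  expect_equal(sum(shape_counts(none)[c("diagnosis_gender", "diagnosis_age",
                                        "procedure_gender", "procedure_age")]), 0L)

  # invariant breaches refuse to compile
  expect_error(code_constraints(data.frame(
    code = "x", kind = "diagnosis", allowed_genders = "",
    age_min = 0, age_max = 124)), "allowed_genders")
  expect_error(code_constraints(data.frame(
    code = "x", kind = "diagnosis", allowed_genders = male(),
    age_min = 50, age_max = 30)), "age interval")
})

test_that("each seeded error type is flagged in its category", {
  # female patient with a male-only diagnosis (prostate cancer)
  r <- validate_final(tiny_tables(gender = female(), icd = "185",
                                  dob = "2050-06-01T00:00:00+00:00"))
  expect_equal(category_summary(r, "diagnosis_gender")$violations, 1)
  expect_equal(category_summary(r, "diagnosis_age")$violations, 0)

  # male patient with a female-only procedure (hysterectomy)
  r <- validate_final(tiny_tables(gender = male(), cpt = "58150"))
  expect_equal(category_summary(r, "procedure_gender")$violations, 1)

  # discharge before admission
  r <- validate_final(tiny_tables(admit = "2100-03-15T12:00:00+00:00",
                                  disch = "2100-03-10T08:00:00+00:00",
                                  chart = "2100-03-12T09:30:00+00:00"))
  expect_equal(category_summary(r, "time_sequence")$violations, 1)

  # infant with an adult-only diagnosis (lung cancer)
  r <- validate_final(tiny_tables(dob = "2100-01-20T00:00:00+00:00", icd = "162.9"))
  expect_equal(category_summary(r, "diagnosis_age")$violations, 1)

  # birth date implying an implausible age (> 124 years) at admission
  r <- validate_final(tiny_tables(dob = "1960-01-01T00:00:00+00:00"))
  expect_equal(category_summary(r, "diagnosis_age")$violations, 1)
  expect_equal(category_summary(r, "procedure_age")$violations, 1)

  # chart date outside the admission window
  r <- validate_final(tiny_tables(chart = "2100-04-01T00:00:00+00:00"))
  expect_equal(category_summary(r, "time_sequence")$violations, 1)

  # invalid calendar string on a typed property
  r <- validate_final(tiny_tables(chart = "2100-25-03T09:30:00+00:00"))
  expect_equal(category_summary(r, "datatype")$violations, 1)
  expect_equal(category_summary(r, "time_sequence")$violations, 0)

  # missing mandatory field
  t <- tiny_tables(); t$ADMISSIONS$DISCHTIME <- ""
  r <- validate_final(t)
  expect_equal(category_summary(r, "essential_completeness")$violations, 1)
  expect_equal(category_summary(r, "time_sequence")$violations, 0)

  # diagnosis present but gender deleted: conditional completeness, and the
  # gender-compatibility categories lose their checked admission
  t <- tiny_tables(); t$PATIENTS$GENDER <- ""
  r <- validate_final(t)
  expect_equal(category_summary(r, "conditional_completeness")$violations, 1)
  expect_equal(category_summary(r, "diagnosis_gender")$checked, 0)
  expect_false(category_summary(r, "diagnosis_gender")$assessable)
})

test_that("conditional completeness is N/A before the final integration stage", {
  t <- small_cohort(n = 10, seed = 31)
  staged <- run_staged_integration(t)
  for (i in 1:3) {
    rep <- validate_graphs(staged$stages[[i]], bundled_rules(), roster = staged$roster)
    expect_false(category_summary(rep, "conditional_completeness")$assessable)
  }
  rep4 <- validate_graphs(staged$stages[[4]], bundled_rules(), roster = staged$roster)
  expect_true(category_summary(rep4, "conditional_completeness")$assessable)
  expect_equal(category_summary(rep4, "conditional_completeness")$checked,
               nrow(staged$roster))
})

test_that("age checks fall back to chart dates and exclude unverifiable admissions", {
  # admission time missing: procedure age checked via chart date
  t <- tiny_tables(dob = "2100-01-20T00:00:00+00:00", cpt = "99397")
  t$ADMISSIONS$ADMITTIME <- ""
  r <- validate_final(t)
  expect_equal(category_summary(r, "procedure_age")$violations, 1)
  # ... but diagnosis age has no event time left and drops out of checked
  expect_equal(category_summary(r, "diagnosis_age")$checked, 0)

  # missing birth date excludes the admission from both age categories
  t <- tiny_tables(); t$PATIENTS$DOB <- ""
  r <- validate_final(t)
  expect_equal(category_summary(r, "diagnosis_age")$checked, 0)
  expect_equal(category_summary(r, "procedure_age")$checked, 0)
})

test_that("observability reflects surviving evidence, not just injection", {
  # gender swapped but gender later deleted -> not observable
  t <- tiny_tables(gender = male(), icd = "185", cpt = "55700",
                   dob = "2050-06-01T00:00:00+00:00")
  inj <- inject_noise(t, noise_config(0, 0, seed = 1))  # start clean
  led <- inj$ledger

  swap_entry <- function(tbl, row_id, subject, hadm, field, op, old, new) {
    data.frame(table = tbl, row = 1L, row_id = row_id, subject_id = subject,
               hadm_id = hadm, field = field, kind = "inconsistent",
               operator = op, original_value = old, new_value = new,
               targeted = TRUE, stringsAsFactors = FALSE)
  }
  corrupted <- t
  corrupted$PATIENTS$GENDER <- female()
  led <- swap_entry("PATIENTS", "1", "1", "", "GENDER", "gender_swap",
                    male(), female())

  staged <- run_staged_integration(corrupted)
  obs <- check_observability(led, staged$stages[[4]], bundled_rules(), staged$roster)
  expect_true(obs$observable)
  expect_match(obs$detected_in, "diagnosis_gender")

  # same swap, but the gender field subsequently deleted
  corrupted2 <- corrupted
  corrupted2$PATIENTS$GENDER <- ""
  staged2 <- run_staged_integration(corrupted2)
  obs2 <- check_observability(led, staged2$stages[[4]], bundled_rules(), staged2$roster)
  expect_false(obs2$observable)

  # swapped admit/discharge, both present -> observable
  c3 <- t
  c3$ADMISSIONS$ADMITTIME <- t$ADMISSIONS$DISCHTIME
  c3$ADMISSIONS$DISCHTIME <- t$ADMISSIONS$ADMITTIME
  led3 <- swap_entry("ADMISSIONS", "500", "1", "500", "ADMITTIME",
                     "admit_discharge_swap", t$ADMISSIONS$ADMITTIME,
                     t$ADMISSIONS$DISCHTIME)
  staged3 <- run_staged_integration(c3)
  obs3 <- check_observability(led3, staged3$stages[[4]], bundled_rules(), staged3$roster)
  expect_true(obs3$observable)
  expect_match(obs3$detected_in, "time_sequence")

  # substituted code deleted afterwards -> not observable
  c4 <- t
  c4$DIAGNOSES_ICD$ICD9_CODE <- ""
  led4 <- swap_entry("DIAGNOSES_ICD", "1", "1", "500", "ICD9_CODE",
                     "code_substitution", "486", "183.0")
  staged4 <- run_staged_integration(c4)
  obs4 <- check_observability(led4, staged4$stages[[4]], bundled_rules(), staged4$roster)
  expect_false(obs4$observable)

  # fixed-point operation (value unchanged) is never observable
  led5 <- swap_entry("CPTEVENTS", "1", "1", "500", "CHARTDATE",
                     "day_month_swap", t$CPTEVENTS$CHARTDATE, t$CPTEVENTS$CHARTDATE)
  obs5 <- check_observability(led5, staged$stages[[4]], bundled_rules(), staged$roster)
  expect_false(obs5$observable)
})

test_that("the engine matches the brute-force evaluator on corrupted cohorts", {
  rules <- bundled_rules()
  for (seed in 1:8) {
    t <- generate_cohort(cohort_spec(n_patients = 6, seed = seed))
    inj <- inject_noise(t, noise_config(0.8, 0.3, seed = seed + 100))
    staged <- run_staged_integration(inj$tables)
    for (stage in c(2, 4)) {
      rep <- validate_graphs(staged$stages[[stage]], rules, roster = staged$roster)
      oracle <- oracle_violations(staged$stages[[stage]], rules$constraints, staged$roster)
      expect_identical(violation_pairs(rep), oracle,
                       info = paste("seed", seed, "stage", stage))
    }
  }
})
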