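# Shared fixtures: all built in code at test time.

bundled_rules <- local({
  rules <- NULL
  function() {
    if (is.null(rules)) {
      rules <<- compile_ruleset(rbind(as.data.frame(diagnosis_codes()),
                                      as.data.frame(procedure_codes())))
    }
    rules
  }
})

small_cohort <- function(n = 20, seed = 1) {
  generate_cohort(cohort_spec(n_patients = n, seed = seed))
}

# a minimal hand-built table set: one male patient, one admission, one
# procedure, one diagnosis -- individually overridable for targeted fixtures
tiny_tables <- function(gender = "248153007",
                        dob = "2060-06-01T00:00:00+00:00",
                        admit = "2100-03-10T08:00:00+00:00",
                        disch = "2100-03-15T12:00:00+00:00",
                        chart = "2100-03-12T09:30:00+00:00",
                        cpt = "71020", icd = "486",
                        subject = "1", hadm = "500") {
  structure(list(
    PATIENTS = data.frame(SUBJECT_ID = subject, GENDER = gender, DOB = dob,
                          stringsAsFactors = FALSE),
    ADMISSIONS = data.frame(HADM_ID = hadm, SUBJECT_ID = subject,
                            ADMITTIME = admit, DISCHTIME = disch,
                            ADMISSION_LOCATION = "EMERGENCY ROOM ADMIT",
                            DISCHARGE_LOCATION = "HOME", stringsAsFactors = FALSE),
    CPTEVENTS = data.frame(HADM_ID = hadm, SUBJECT_ID = subject,
                           CHARTDATE = chart, CPT_CD = cpt, stringsAsFactors = FALSE),
    DIAGNOSES_ICD = data.frame(HADM_ID = hadm, SUBJECT_ID = subject,
                               ICD9_CODE = icd, stringsAsFactors = FALSE)
  ), class = "kgqc_ehr_tables")
}

# validate a table set at the final integration stage
validate_final <- function(tables, rules = bundled_rules()) {
  staged <- run_staged_integration(tables)
  validate_graphs(staged$stages[[4]], rules, stage = "final",
                  roster = staged$roster)
}

category_summary <- function(report, category) {
  report$summary[report$summary$category == category, ]
}

violation_pairs <- function(report) {
  sort(unique(paste(report$violations$category, report$violations$focus_node, sep = "|")))
}
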