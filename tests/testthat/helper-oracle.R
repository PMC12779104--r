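# Brute-force reference evaluator: nested loops over admissions applying
# each constraint literally to raw triples. Deliberately naive and written
# independently of the engine's vectorized joins; used to cross-check the
# rule engine's violation sets on small graphs.

oracle_parse <- function(x) {
  if (is.na(x)) return(NA)
  t <- strptime(substr(x, 1, 19), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (is.na(t)) NA else as.POSIXct(t, tz = "UTC")
}

oracle_age <- function(dob, at) {
  yd <- as.integer(format(at, "%Y")) - as.integer(format(dob, "%Y"))
  if (format(at, "%m%d") < format(dob, "%m%d")) yd <- yd - 1L
  yd
}

# returns the sorted set of "category|admission-node" violation pairs
oracle_violations <- function(graphs, constraints, roster) {
  tr <- graph_triples(graphs)
  sources <- graphs$sources
  val <- function(subj, pred) {
    o <- tr$object[tr$subject == subj & tr$predicate == pred]
    if (length(o) > 0) o[1] else NA_character_
  }
  untyped <- function(subj, pred) {
    d <- tr$datatype[tr$subject == subj & tr$predicate == pred]
    length(d) > 0 && !is.na(d[1]) && d[1] == ""
  }
  allowed_gender <- function(code) {
    strsplit(constraints$allowed_genders[constraints$code == code], "|", fixed = TRUE)[[1]]
  }
  age_interval <- function(code) {
    i <- which(constraints$code == code)
    c(constraints$age_min[i], constraints$age_max[i])
  }

  pairs <- character(0)
  add <- function(cat, adm) pairs <<- c(pairs, paste(cat, adm, sep = "|"))

  for (k in seq_len(nrow(roster))) {
    anode <- paste0("ehr:admission_", roster$hadm_id[k])
    pnode <- paste0("ehr:patient_", roster$subject_id[k])
    gender <- val(pnode, "ont:hasGender")
    dob_raw <- val(pnode, "ont:hasBirthDate")
    admit_raw <- val(anode, "ont:hasAdmitTime")
    disch_raw <- val(anode, "ont:hasDischargeTime")
    dob <- oracle_parse(dob_raw)
    admit <- oracle_parse(admit_raw)
    disch <- oracle_parse(disch_raw)
    procs <- unique(tr$subject[tr$predicate == "ont:ofAdmission" & tr$object == anode &
                                 grepl("^ehr:procedure_", tr$subject)])
    diags <- unique(tr$subject[tr$predicate == "ont:ofAdmission" & tr$object == anode &
                                 grepl("^ehr:diagnosis_", tr$subject)])

    # essential completeness over integrated sources
    if ("PATIENTS" %in% sources && any(tr$subject == pnode)) {
      if (is.na(gender)) add("essential_completeness", anode)
      if (is.na(dob_raw)) add("essential_completeness", anode)
    }
    if ("ADMISSIONS" %in% sources && any(tr$subject == anode)) {
      for (p in c("ont:hasAdmitTime", "ont:hasDischargeTime",
                  "ont:hasAdmissionLocation", "ont:hasDischargeLocation")) {
        if (is.na(val(anode, p))) add("essential_completeness", anode)
      }
    }
    if ("CPTEVENTS" %in% sources) {
      for (pr in procs) {
        if (is.na(val(pr, "ont:hasCode"))) add("essential_completeness", anode)
        if (is.na(val(pr, "ont:hasChartDate"))) add("essential_completeness", anode)
      }
    }
    if ("DIAGNOSES_ICD" %in% sources) {
      for (dg in diags) {
        if (is.na(val(dg, "ont:hasCode"))) add("essential_completeness", anode)
      }
    }

    # conditional completeness only once everything is integrated
    if (all(c("PATIENTS", "ADMISSIONS", "CPTEVENTS", "DIAGNOSES_ICD") %in% sources)) {
      if (length(diags) > 0 && is.na(gender)) add("conditional_completeness", anode)
    }

    # datatype: untyped literal on a dateTime property
    if (untyped(pnode, "ont:hasBirthDate")) add("datatype", anode)
    if (untyped(anode, "ont:hasAdmitTime")) add("datatype", anode)
    if (untyped(anode, "ont:hasDischargeTime")) add("datatype", anode)
    for (pr in procs) if (untyped(pr, "ont:hasChartDate")) add("datatype", anode)

    # temporal order (skipped when an operand is missing/unparseable)
    if (!is.na(admit) && !is.na(disch) && admit > disch) add("time_sequence", anode)
    if (!is.na(dob) && !is.na(admit) && dob > admit) add("time_sequence", anode)
    for (pr in procs) {
      chart <- oracle_parse(val(pr, "ont:hasChartDate"))
      if (!is.na(chart) && !is.na(admit) && chart < admit) add("time_sequence", anode)
      if (!is.na(chart) && !is.na(disch) && chart > disch) add("time_sequence", anode)
    }

    # demographic compatibility of codes
    for (dg in diags) {
      code <- val(dg, "ont:hasCode")
      if (is.na(code) || !code %in% constraints$code) next
      if (!is.na(gender) && !gender %in% allowed_gender(code)) {
        add("diagnosis_gender", anode)
      }
      if (!is.na(dob) && !is.na(admit)) {
        age <- oracle_age(dob, admit)
        iv <- age_interval(code)
        if (age < iv[1] || age > iv[2]) add("diagnosis_age", anode)
      }
    }
    for (pr in procs) {
      code <- val(pr, "ont:hasCode")
      if (is.na(code) || !code %in% constraints$code) next
      if (!is.na(gender) && !gender %in% allowed_gender(code)) {
        add("procedure_gender", anode)
      }
      event <- if (!is.na(admit)) admit else oracle_parse(val(pr, "ont:hasChartDate"))
      if (!is.na(dob) && !is.na(event)) {
        age <- oracle_age(dob, event)
        iv <- age_interval(code)
        if (age < iv[1] || age > iv[2]) add("procedure_age", anode)
      }
    }
  }
  sort(unique(pairs))
}
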