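# SHACL-style shape compilation and evaluation over patient graphs.
#
# Eight rule categories, two completeness and six consistency:
#   essential_completeness   mandatory properties present
#   conditional_completeness cross-source dependency (diagnosis => gender)
#   datatype                 typed literals parse as their declared type
#   time_sequence            admit <= discharge, chart within stay, birth first
#   diagnosis_gender / procedure_gender   code allowed for the patient's gender
#   diagnosis_age / procedure_age         code allowed at the patient's age
#
# Scores are reported per admission: an admission violating any shape of a
# category counts once in that category. The evaluation is pure set logic
# over the triple store, so results are independent of patient order.

QUALITY_CATEGORIES <- c(
  "essential_completeness", "conditional_completeness", "datatype",
  "time_sequence", "diagnosis_gender", "diagnosis_age",
  "procedure_gender", "procedure_age"
)

#' Compile declarative constraints into an executable ruleset
#'
#' Produces one shape per mandatory property (min-count), one conditional
#' completeness shape (an admission with a recorded diagnosis requires a
#' recorded gender), one datatype shape per dateTime-typed property, four
#' temporal-order shapes, one gender-compatibility shape per (code, allowed
#' gender) pairing -- mirroring the per-pairing expansion of full shape
#' libraries -- and one age-interval shape per code.
#'
#' @param constraints a `kgqc_code_constraints` data.frame (diagnosis and
#'   procedure rows may be mixed; see [code_constraints()]). May have zero
#'   rows, in which case only ontology-based shapes are compiled.
#' @param ontology a [mini_ontology()].
#' @param mandatory data.frame of mandatory properties (columns `class`,
#'   `property`); defaults to every datatype property of the ontology.
#' @return a list of class `kgqc_rule_set` with elements `shapes`,
#'   `constraints`, `ontology`, `mandatory`.
#' @export
compile_ruleset <- function(constraints, ontology = mini_ontology(),
                            mandatory = NULL) {
  if (!inherits(constraints, "kgqc_code_constraints")) {
    constraints <- code_constraints(constraints)
  }
  mandatory <- mandatory %||% ontology$properties[, c("class", "property")]

  shapes <- list()
  add <- function(id, category, target, property = NA_character_,
                  code = NA_character_, gender = NA_character_,
                  age_min = NA_real_, age_max = NA_real_) {
    shapes[[length(shapes) + 1L]] <<- data.frame(
      shape_id = id, category = category, target_class = target,
      property = property, code = code, gender = gender,
      age_min = age_min, age_max = age_max, stringsAsFactors = FALSE
    )
  }

  for (i in seq_len(nrow(mandatory))) {
    add(paste0("essential.", mandatory$class[i], ".", mandatory$property[i]),
        "essential_completeness", mandatory$class[i], mandatory$property[i])
  }
  add("conditional.diagnosis_requires_gender", "conditional_completeness",
      "Admission", "hasGender")
  dt_props <- ontology$properties[ontology$properties$range == "dateTime", , drop = FALSE]
  for (i in seq_len(nrow(dt_props))) {
    add(paste0("datatype.", dt_props$class[i], ".", dt_props$property[i]),
        "datatype", dt_props$class[i], dt_props$property[i])
  }
  add("temporal.admit_le_discharge", "time_sequence", "Admission")
  add("temporal.chart_ge_admit", "time_sequence", "Procedure")
  add("temporal.chart_le_discharge", "time_sequence", "Procedure")
  add("temporal.birth_le_admit", "time_sequence", "Admission")

  for (i in seq_len(nrow(constraints))) {
    kind <- constraints$kind[i]
    code <- constraints$code[i]
    target <- if (kind == "diagnosis") "Diagnosis" else "Procedure"
    for (g in split_genders(constraints$allowed_genders[i])[[1]]) {
      add(paste0(kind, "_gender.", code, ".", g), paste0(kind, "_gender"),
          target, code = code, gender = g)
    }
    add(paste0(kind, "_age.", code), paste0(kind, "_age"), target,
        code = code, age_min = constraints$age_min[i],
        age_max = constraints$age_max[i])
  }

  structure(
    list(shapes = do.call(rbind, shapes), constraints = constraints,
         ontology = ontology, mandatory = mandatory),
    class = "kgqc_rule_set"
  )
}

#' Shape counts per category
#' @param rules a `kgqc_rule_set`.
#' @return a named integer vector over the eight categories.
#' @export
shape_counts <- function(rules) {
  counts <- table(factor(rules$shapes$category, levels = QUALITY_CATEGORIES))
  out <- as.integer(counts)
  names(out) <- QUALITY_CATEGORIES
  out
}

#' @export
print.kgqc_rule_set <- function(x, ...) {
  cat("<kgqc_rule_set>\n")
  counts <- shape_counts(x)
  for (nm in names(counts)) cat(sprintf("  %-26s %4d shapes\n", nm, counts[nm]))
  invisible(x)
}

# ---- entity frames -------------------------------------------------------
# Flatten the triple store into per-class lookup frames. All downstream
# evaluation (engine, observability) reads these frames, so the semantics
# of "present", "parseable" and "age at event" are defined in one place.

single_prop <- function(triples, pred) {
  t <- triples[triples$predicate == pred, c("subject", "object", "datatype")]
  t[!duplicated(t$subject), , drop = FALSE]
}

build_entity_frames <- function(graphs, roster = NULL) {
  t <- graphs$triples

  if (is.null(roster)) {
    adm_nodes <- unique(c(
      t$subject[t$predicate == "rdf:type" & t$object == "ont:Admission"],
      t$object[t$predicate == "ont:ofAdmission"]
    ))
    pid <- t$patient_id[match(adm_nodes, t$subject)]
    # fall back to the patient_id of any event pointing at the admission
    ev <- t[t$predicate == "ont:ofAdmission", c("patient_id", "object")]
    need <- is.na(pid)
    pid[need] <- ev$patient_id[match(adm_nodes[need], ev$object)]
    roster <- data.frame(
      hadm_id = sub("^ehr:admission_", "", adm_nodes),
      subject_id = pid, stringsAsFactors = FALSE
    )
    roster <- roster[order(roster$hadm_id), , drop = FALSE]
  }

  adm <- data.frame(
    node = iri_admission(roster$hadm_id),
    hadm_id = roster$hadm_id,
    subject_id = roster$subject_id,
    patient_node = iri_patient(roster$subject_id),
    stringsAsFactors = FALSE
  )
  grab <- function(frame, pred, key = "node") {
    p <- single_prop(t, pred)
    i <- match(frame[[key]], p$subject)
    list(value = p$object[i], untyped = !is.na(i) & p$datatype[i] == "")
  }
  a_adm <- grab(adm, "ont:hasAdmitTime")
  a_dis <- grab(adm, "ont:hasDischargeTime")
  a_alo <- grab(adm, "ont:hasAdmissionLocation")
  a_dlo <- grab(adm, "ont:hasDischargeLocation")
  adm$admit_raw <- a_adm$value; adm$admit_untyped <- a_adm$untyped
  adm$disch_raw <- a_dis$value; adm$disch_untyped <- a_dis$untyped
  adm$admit <- parse_iso8601(adm$admit_raw)
  adm$disch <- parse_iso8601(adm$disch_raw)
  adm$admission_location <- a_alo$value
  adm$discharge_location <- a_dlo$value
  adm$node_in_graph <- adm$node %in% t$subject

  pat_nodes <- unique(c(
    t$subject[t$predicate == "rdf:type" & t$object == "ont:Patient"],
    adm$patient_node
  ))
  pat <- data.frame(node = pat_nodes, stringsAsFactors = FALSE)
  pat$subject_id <- sub("^ehr:patient_", "", pat$node)
  p_gen <- grab(pat, "ont:hasGender")
  p_dob <- grab(pat, "ont:hasBirthDate")
  pat$gender <- p_gen$value
  pat$dob_raw <- p_dob$value; pat$dob_untyped <- p_dob$untyped
  pat$dob <- parse_iso8601(pat$dob_raw)
  pat$node_in_graph <- pat$node %in% t$subject

  event_frame <- function(class) {
    nodes <- t$subject[t$predicate == "rdf:type" & t$object == paste0("ont:", class)]
    ev <- data.frame(node = nodes, stringsAsFactors = FALSE)
    link <- single_prop(t, "ont:ofAdmission")
    ev$adm_node <- link$object[match(ev$node, link$subject)]
    e_code <- grab(ev, "ont:hasCode")
    ev$code <- e_code$value
    if (class == "Procedure") {
      e_ch <- grab(ev, "ont:hasChartDate")
      ev$chart_raw <- e_ch$value; ev$chart_untyped <- e_ch$untyped
      ev$chart <- parse_iso8601(ev$chart_raw)
    }
    i <- match(ev$adm_node, adm$node)
    ev$patient_node <- adm$patient_node[i]
    ev$admit <- adm$admit[i]
    ev$disch <- adm$disch[i]
    ev
  }
  proc <- event_frame("Procedure")
  diag <- event_frame("Diagnosis")

  gi <- match(adm$patient_node, pat$node)
  adm$gender <- pat$gender[gi]
  adm$dob <- pat$dob[gi]

  for (f in c("proc", "diag")) {
    ev <- get(f)
    pi <- match(ev$patient_node, pat$node)
    ev$gender <- pat$gender[pi]
    ev$dob <- pat$dob[pi]
    # age at event: admission time, falling back to the chart date when the
    # admission time is missing or unparseable (procedures only)
    ev$event_time <- ev$admit
    if (f == "proc") {
      use_chart <- is.na(ev$event_time) & !is.na(ev$chart)
      ev$event_time[use_chart] <- ev$chart[use_chart]
    }
    ev$age <- age_years(ev$dob, ev$event_time)
    assign(f, ev)
  }

  list(pat = pat, adm = adm, proc = proc, diag = diag, triples = t)
}

# ---- evaluation ----------------------------------------------------------

# violations of the four code-demographic categories, evaluated per event
# row; returns (category, adm_node, shape_id, message) rows
compat_violations <- function(ev, kind, constraints) {
  ci <- match(ev$code, constraints$code)
  known <- !is.na(ev$code) & !is.na(ci) & !is.na(ev$adm_node)
  out <- list()
  g_ok <- known & !is.na(ev$gender)
  if (any(g_ok)) {
    allowed <- split_genders(constraints$allowed_genders[ci[g_ok]])
    bad <- !mapply(function(g, al) g %in% al, ev$gender[g_ok], allowed)
    if (any(bad)) {
      idx <- which(g_ok)[bad]
      out[[length(out) + 1L]] <- data.frame(
        shape_id = paste0(kind, "_gender.", ev$code[idx], ".", ev$gender[idx]),
        category = paste0(kind, "_gender"),
        focus_node = ev$adm_node[idx],
        message = paste0("code ", ev$code[idx], " not allowed for gender ",
                         ev$gender[idx]),
        stringsAsFactors = FALSE
      )
    }
  }
  a_ok <- known & !is.na(ev$age)
  if (any(a_ok)) {
    amin <- constraints$age_min[ci[a_ok]]
    amax <- constraints$age_max[ci[a_ok]]
    bad <- ev$age[a_ok] < amin | ev$age[a_ok] > amax
    if (any(bad)) {
      idx <- which(a_ok)[bad]
      out[[length(out) + 1L]] <- data.frame(
        shape_id = paste0(kind, "_age.", ev$code[idx]),
        category = paste0(kind, "_age"),
        focus_node = ev$adm_node[idx],
        message = paste0("code ", ev$code[idx], " not allowed at age ",
                         ev$age[idx]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) NULL else do.call(rbind, out)
}

# datatype violations: untyped literal sitting on a dateTime property
# (invalid calendar strings survive mapping untyped); rolled to admissions
datatype_violations <- function(frames) {
  pat <- frames$pat; adm <- frames$adm; proc <- frames$proc
  adm_of_patient <- split(adm$node, adm$patient_node)
  dt_bad <- list(
    list(focus = unlist(adm_of_patient[pat$node[pat$dob_untyped %in% TRUE]],
                        use.names = FALSE),
         id = "datatype.Patient.hasBirthDate"),
    list(focus = adm$node[adm$admit_untyped %in% TRUE],
         id = "datatype.Admission.hasAdmitTime"),
    list(focus = adm$node[adm$disch_untyped %in% TRUE],
         id = "datatype.Admission.hasDischargeTime"),
    list(focus = if (nrow(proc)) proc$adm_node[proc$chart_untyped %in% TRUE] else character(0),
         id = "datatype.Procedure.hasChartDate")
  )
  out <- list()
  for (d in dt_bad) {
    focus <- d$focus[!is.na(d$focus)]
    if (length(focus) > 0) {
      out[[length(out) + 1L]] <- data.frame(
        shape_id = d$id, category = "datatype", focus_node = focus,
        message = "value does not conform to xsd:dateTime", stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) NULL else do.call(rbind, out)
}

# time-sequence violations; same frame-level semantics are reused by
# check_observability so the two can never drift apart
time_violations <- function(frames) {
  adm <- frames$adm; proc <- frames$proc
  out <- list()
  bad <- !is.na(adm$admit) & !is.na(adm$disch) & adm$admit > adm$disch
  if (any(bad)) {
    out[[length(out) + 1L]] <- data.frame(
      shape_id = "temporal.admit_le_discharge", category = "time_sequence",
      focus_node = adm$node[bad],
      message = "discharge before admission", stringsAsFactors = FALSE
    )
  }
  bad <- !is.na(adm$dob) & !is.na(adm$admit) & adm$dob > adm$admit
  if (any(bad)) {
    out[[length(out) + 1L]] <- data.frame(
      shape_id = "temporal.birth_le_admit", category = "time_sequence",
      focus_node = adm$node[bad],
      message = "admission before birth", stringsAsFactors = FALSE
    )
  }
  if (nrow(proc) > 0) {
    bad <- !is.na(proc$chart) & !is.na(proc$admit) & proc$chart < proc$admit &
      !is.na(proc$adm_node)
    if (any(bad)) {
      out[[length(out) + 1L]] <- data.frame(
        shape_id = "temporal.chart_ge_admit", category = "time_sequence",
        focus_node = proc$adm_node[bad],
        message = "chart date before admission", stringsAsFactors = FALSE
      )
    }
    bad <- !is.na(proc$chart) & !is.na(proc$disch) & proc$chart > proc$disch &
      !is.na(proc$adm_node)
    if (any(bad)) {
      out[[length(out) + 1L]] <- data.frame(
        shape_id = "temporal.chart_le_discharge", category = "time_sequence",
        focus_node = proc$adm_node[bad],
        message = "chart date after discharge", stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) NULL else do.call(rbind, out)
}

#' Validate patient graphs against a ruleset
#'
#' Evaluates every shape over every applicable focus node and rolls
#' violations up to the admission level. The checked-node denominator is
#' the admission roster for essential/conditional completeness, datatype
#' and time-sequence rules; for the four code-demographic categories it is
#' the set of admissions carrying at least one relevant code together with
#' the demographic needed for the check (a recorded gender, or a computable
#' age). Temporal and demographic comparisons are skipped when an operand
#' is missing or unparseable -- unparseable values are the datatype
#' category's finding, not a temporal one. Conditional completeness is
#' assessable only once all four sources are integrated.
#'
#' @param graphs a `kgqc_graph_set`.
#' @param rules a `kgqc_rule_set`.
#' @param stage optional stage label recorded in the report (defaults to
#'   the last integrated source).
#' @param roster optional admission roster (see [admission_roster()]);
#'   derived from the graph when omitted, which at early stages restricts
#'   the denominator to admissions reachable in the graph.
#' @return a `kgqc_validation_report`: list with `stage`, `sources`,
#'   `summary` (category, violations, checked, assessable) and
#'   `violations` (shape_id, category, focus_node, message, stage).
#' @export
validate_graphs <- function(graphs, rules, stage = NULL, roster = NULL) {
  stopifnot(inherits(rules, "kgqc_rule_set"))
  unknown <- setdiff(unique(graphs$triples$predicate),
                     ontology_predicates(rules$ontology))
  if (length(unknown) > 0) {
    stop("validation error: unknown predicate(s) ", paste(unknown, collapse = ", "))
  }
  stage <- stage %||%
    (if (length(graphs$sources)) graphs$sources[length(graphs$sources)] else "(empty)")
  sources <- graphs$sources
  frames <- build_entity_frames(graphs, roster)
  pat <- frames$pat; adm <- frames$adm; proc <- frames$proc; diag <- frames$diag

  viol <- list()
  push <- function(df) if (!is.null(df) && nrow(df) > 0) {
    viol[[length(viol) + 1L]] <<- df
  }
  adm_of_patient <- split(adm$node, adm$patient_node)

  # essential completeness: mandatory properties of integrated sources
  mand <- merge(rules$mandatory[, c("class", "property")],
                rules$ontology$properties, by = c("class", "property"))
  mand <- mand[mand$table %in% sources, , drop = FALSE]
  for (i in seq_len(nrow(mand))) {
    cls <- mand$class[i]; prop <- mand$property[i]
    missing_nodes <- switch(cls,
      Patient = pat$node[pat$node_in_graph & is.na(
        if (prop == "hasGender") pat$gender else pat$dob_raw)],
      Admission = adm$node[adm$node_in_graph & is.na(adm[[switch(prop,
        hasAdmitTime = "admit_raw", hasDischargeTime = "disch_raw",
        hasAdmissionLocation = "admission_location",
        hasDischargeLocation = "discharge_location")]])],
      Procedure = proc$node[is.na(proc[[if (prop == "hasCode") "code" else "chart_raw"]])],
      Diagnosis = diag$node[is.na(diag$code)]
    )
    if (length(missing_nodes) == 0) next
    focus <- switch(cls,
      Patient = unlist(adm_of_patient[missing_nodes], use.names = FALSE),
      Admission = missing_nodes,
      Procedure = proc$adm_node[match(missing_nodes, proc$node)],
      Diagnosis = diag$adm_node[match(missing_nodes, diag$node)]
    )
    focus <- focus[!is.na(focus)]
    push(data.frame(
      shape_id = paste0("essential.", cls, ".", prop),
      category = "essential_completeness", focus_node = focus,
      message = paste0(cls, " lacks mandatory ", prop), stringsAsFactors = FALSE
    ))
  }

  # conditional completeness (final stage only)
  conditional_assessable <- all(EHR_TABLE_NAMES %in% sources)
  if (conditional_assessable && nrow(diag) > 0) {
    has_diag <- unique(diag$adm_node[!is.na(diag$adm_node)])
    gi <- match(adm$patient_node, pat$node)
    bad <- adm$node %in% has_diag & is.na(pat$gender[gi])
    push(if (any(bad)) data.frame(
      shape_id = "conditional.diagnosis_requires_gender",
      category = "conditional_completeness", focus_node = adm$node[bad],
      message = "diagnosis recorded but patient gender missing",
      stringsAsFactors = FALSE
    ))
  }

  push(datatype_violations(frames))
  push(time_violations(frames))
  push(compat_violations(diag, "diagnosis", rules$constraints))
  push(compat_violations(proc, "procedure", rules$constraints))

  violations <- if (length(viol) > 0) do.call(rbind, viol) else data.frame(
    shape_id = character(0), category = character(0), focus_node = character(0),
    message = character(0), stringsAsFactors = FALSE
  )
  violations <- violations[violations$focus_node %in% adm$node, , drop = FALSE]
  violations$stage <- rep(stage, nrow(violations))
  rownames(violations) <- NULL

  # checked denominators
  n_adm <- nrow(adm)
  checked <- c(
    essential_completeness = n_adm,
    conditional_completeness = if (conditional_assessable) n_adm else 0L,
    datatype = n_adm,
    time_sequence = n_adm
  )
  compat_checked <- function(ev, need) {
    known <- !is.na(ev$code) & ev$code %in% rules$constraints$code & !is.na(ev$adm_node)
    ok <- if (need == "gender") known & !is.na(ev$gender) else known & !is.na(ev$age)
    length(unique(ev$adm_node[ok]))
  }
  checked["diagnosis_gender"] <- compat_checked(diag, "gender")
  checked["diagnosis_age"] <- compat_checked(diag, "age")
  checked["procedure_gender"] <- compat_checked(proc, "gender")
  checked["procedure_age"] <- compat_checked(proc, "age")

  n_violating <- vapply(QUALITY_CATEGORIES, function(cat) {
    length(unique(violations$focus_node[violations$category == cat]))
  }, integer(1))

  summary <- data.frame(
    category = QUALITY_CATEGORIES,
    violations = unname(n_violating[QUALITY_CATEGORIES]),
    checked = as.integer(unname(checked[QUALITY_CATEGORIES])),
    assessable = unname(checked[QUALITY_CATEGORIES] > 0) &
      (QUALITY_CATEGORIES != "conditional_completeness" | conditional_assessable),
    stringsAsFactors = FALSE
  )

  structure(
    list(stage = stage, sources = sources, summary = summary,
         violations = violations),
    class = "kgqc_validation_report"
  )
}

#' @export
print.kgqc_validation_report <- function(x, ...) {
  cat("<kgqc_validation_report> stage: ", x$stage, "\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
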