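# Mapping tables to per-patient knowledge graphs and staged integration.
#
# Triples are held in a flat data.frame (one graph set for a whole cohort;
# per-patient graphs are row subsets keyed by patient_id). Subjects and
# predicates are prefixed IRIs minted deterministically from table keys so
# that runs are comparable. Literals carry a datatype tag: "dateTime",
# "code", "text", or "" for an untyped literal -- the vehicle that carries
# invalid date strings (e.g. month 25) into the graph so datatype rules can
# flag them.

#' The mini reference ontology
#'
#' Four classes connected through Admission -- Patient, Admission,
#' Procedure, Diagnosis -- with one datatype property per table column and
#' object properties `ofPatient` (Admission to Patient) and `ofAdmission`
#' (Procedure/Diagnosis to Admission). Each datatype property declares
#' exactly one expected range: `dateTime`, `code`, or `text`. The
#' vocabulary is plain data, so a richer ontology can be swapped in.
#'
#' @return a list of class `kgqc_ontology` with elements `properties`
#'   (data.frame: property, class, range, table, column), `links`
#'   (data.frame: property, from, to) and `classes`.
#' @export
mini_ontology <- function() {
  properties <- data.frame(
    property = c("hasGender", "hasBirthDate",
                 "hasAdmitTime", "hasDischargeTime",
                 "hasAdmissionLocation", "hasDischargeLocation",
                 "hasChartDate", "hasCode", "hasCode"),
    class = c("Patient", "Patient",
              "Admission", "Admission", "Admission", "Admission",
              "Procedure", "Procedure", "Diagnosis"),
    range = c("code", "dateTime",
              "dateTime", "dateTime", "text", "text",
              "dateTime", "code", "code"),
    table = c("PATIENTS", "PATIENTS",
              "ADMISSIONS", "ADMISSIONS", "ADMISSIONS", "ADMISSIONS",
              "CPTEVENTS", "CPTEVENTS", "DIAGNOSES_ICD"),
    column = c("GENDER", "DOB",
               "ADMITTIME", "DISCHTIME", "ADMISSION_LOCATION", "DISCHARGE_LOCATION",
               "CHARTDATE", "CPT_CD", "ICD9_CODE"),
    stringsAsFactors = FALSE
  )
  links <- data.frame(
    property = c("ofPatient", "ofAdmission", "ofAdmission"),
    from = c("Admission", "Procedure", "Diagnosis"),
    to = c("Patient", "Admission", "Admission"),
    table = c("ADMISSIONS", "CPTEVENTS", "DIAGNOSES_ICD"),
    stringsAsFactors = FALSE
  )
  structure(
    list(properties = properties, links = links,
         classes = c("Patient", "Admission", "Procedure", "Diagnosis")),
    class = "kgqc_ontology"
  )
}

ontology_predicates <- function(ontology) {
  unique(c("rdf:type", paste0("ont:", ontology$properties$property),
           paste0("ont:", ontology$links$property)))
}

empty_triples <- function() {
  data.frame(
    patient_id = character(0), subject = character(0), predicate = character(0),
    object = character(0), is_iri = logical(0), datatype = character(0),
    source = character(0), stringsAsFactors = FALSE
  )
}

new_graph_set <- function(triples, sources) {
  triples <- triples[!duplicated(triples[c("subject", "predicate", "object",
                                           "is_iri", "datatype")]), , drop = FALSE]
  rownames(triples) <- NULL
  structure(list(triples = triples, sources = sources), class = "kgqc_graph_set")
}

#' @export
print.kgqc_graph_set <- function(x, ...) {
  cat("<kgqc_graph_set> ", nrow(x$triples), " triples, ",
      length(unique(x$triples$patient_id[!is.na(x$triples$patient_id)])),
      " patients; sources: ",
      if (length(x$sources)) paste(x$sources, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' Triples of a graph set
#' @param graphs a `kgqc_graph_set`.
#' @return the triple data.frame.
#' @export
graph_triples <- function(graphs) graphs$triples

#' Patients present in a graph set
#' @param graphs a `kgqc_graph_set`.
#' @return character vector of patient ids.
#' @export
graph_patient_ids <- function(graphs) {
  sort(unique(graphs$triples$patient_id[!is.na(graphs$triples$patient_id)]))
}

#' Extract one patient's graph
#'
#' Per-patient graphs are disjoint: every triple belongs to exactly one
#' patient, so validation can be parallelized across patients and is
#' independent of patient processing order.
#'
#' @param graphs a `kgqc_graph_set`.
#' @param patient_id a subject id.
#' @return a `kgqc_graph_set` restricted to that patient.
#' @export
patient_graph <- function(graphs, patient_id) {
  new_graph_set(graphs$triples[graphs$triples$patient_id %in% patient_id, , drop = FALSE],
                graphs$sources)
}

iri_patient <- function(id) paste0("ehr:patient_", id)
iri_admission <- function(id) paste0("ehr:admission_", id)

# deterministic node IRIs per table row; event tables number their nodes by
# order of appearance within each admission (row order is stable because
# corruption never inserts or removes rows)
entity_subjects <- function(table, table_name) {
  n <- nrow(table)
  switch(table_name,
    PATIENTS = iri_patient(table$SUBJECT_ID),
    ADMISSIONS = iri_admission(table$HADM_ID),
    CPTEVENTS = paste0("ehr:procedure_", table$HADM_ID, "_",
                       stats::ave(seq_len(n), table$HADM_ID, FUN = seq_along)),
    DIAGNOSES_ICD = paste0("ehr:diagnosis_", table$HADM_ID, "_",
                           stats::ave(seq_len(n), table$HADM_ID, FUN = seq_along))
  )
}

literal_datatype <- function(values, range) {
  # invalid date strings become untyped literals so datatype rules see them
  if (range == "dateTime") {
    ifelse(is.na(parse_iso8601(values)), "", "dateTime")
  } else {
    rep(range, length(values))
  }
}

#' Map one table to source-knowledge-graph fragments
#'
#' One node per entity row, one triple per non-missing cell; missing cells
#' produce no triple. Type and link triples (`rdf:type`, `ofPatient`,
#' `ofAdmission`) are always emitted because they derive from keys, which
#' are never corrupted. Rows referencing a patient absent from the mapped
#' table raise no error: the node is still created (orphan fragments attach
#' at integration time).
#'
#' @param table one of the four EHR data.frames.
#' @param table_name its name (`"PATIENTS"`, `"ADMISSIONS"`, `"CPTEVENTS"`,
#'   `"DIAGNOSES_ICD"`).
#' @param ontology a [mini_ontology()].
#' @return a `kgqc_graph_set` whose `sources` is `table_name`; an empty
#'   table yields zero graphs.
#' @export
map_source <- function(table, table_name, ontology = mini_ontology()) {
  if (!table_name %in% EHR_TABLE_NAMES) stop("unknown table name: ", table_name)
  n <- nrow(table)
  if (n == 0) return(new_graph_set(empty_triples(), table_name))

  props <- ontology$properties[ontology$properties$table == table_name, , drop = FALSE]
  cls <- switch(table_name, PATIENTS = "Patient", ADMISSIONS = "Admission",
                CPTEVENTS = "Procedure", DIAGNOSES_ICD = "Diagnosis")
  subjects <- entity_subjects(table, table_name)
  patient_id <- table$SUBJECT_ID

  parts <- list(data.frame(
    patient_id = patient_id, subject = subjects, predicate = "rdf:type",
    object = paste0("ont:", cls), is_iri = TRUE, datatype = NA_character_,
    source = table_name, stringsAsFactors = FALSE
  ))
  if (table_name == "ADMISSIONS") {
    parts[[length(parts) + 1L]] <- data.frame(
      patient_id = patient_id, subject = subjects, predicate = "ont:ofPatient",
      object = iri_patient(table$SUBJECT_ID), is_iri = TRUE,
      datatype = NA_character_, source = table_name, stringsAsFactors = FALSE
    )
  }
  if (table_name %in% c("CPTEVENTS", "DIAGNOSES_ICD")) {
    parts[[length(parts) + 1L]] <- data.frame(
      patient_id = patient_id, subject = subjects, predicate = "ont:ofAdmission",
      object = iri_admission(table$HADM_ID), is_iri = TRUE,
      datatype = NA_character_, source = table_name, stringsAsFactors = FALSE
    )
  }
  for (k in seq_len(nrow(props))) {
    vals <- table[[props$column[k]]]
    present <- !is_missing_cell(vals)
    if (!any(present)) next
    parts[[length(parts) + 1L]] <- data.frame(
      patient_id = patient_id[present], subject = subjects[present],
      predicate = paste0("ont:", props$property[k]), object = vals[present],
      is_iri = FALSE, datatype = literal_datatype(vals[present], props$range[k]),
      source = table_name, stringsAsFactors = FALSE
    )
  }
  new_graph_set(do.call(rbind, parts), table_name)
}

#' Integrate a source fragment into a patient graph
#'
#' Triple-set union with provenance retained (first writer wins for the
#' `source` tag of a duplicated triple). Idempotent: integrating the same
#' fragment twice equals integrating it once. The `sources` stage marker is
#' the union of both inputs' sources.
#'
#' @param phkg the accumulating `kgqc_graph_set` (may be `NULL` or empty).
#' @param fragment a `kgqc_graph_set` to merge in.
#' @return the integrated `kgqc_graph_set`.
#' @export
integrate_graphs <- function(phkg, fragment) {
  if (is.null(phkg)) return(fragment)
  new_graph_set(rbind(phkg$triples, fragment$triples),
                union(phkg$sources, fragment$sources))
}

#' An empty patient graph set
#' @return a `kgqc_graph_set` with no triples and no sources.
#' @export
empty_graph_set <- function() new_graph_set(empty_triples(), character(0))

#' Are two graph sets equal as triple sets?
#'
#' Compares `(subject, predicate, object, is_iri, datatype)` tuples,
#' ignoring provenance and row order.
#'
#' @param a,b `kgqc_graph_set` objects.
#' @return `TRUE` or `FALSE`.
#' @export
triples_equal <- function(a, b) {
  key <- function(g) {
    t <- g$triples
    sort(paste(t$subject, t$predicate, t$object, t$is_iri,
               ifelse(is.na(t$datatype), "<iri>", t$datatype), sep = "\r"))
  }
  identical(key(a), key(b))
}

#' The admission roster of a set of tables
#'
#' Distinct `(HADM_ID, SUBJECT_ID)` pairs drawn from the key columns of
#' ADMISSIONS, CPTEVENTS and DIAGNOSES_ICD. Keys are never corrupted, so
#' the roster is exact even for heavily noised tables; it supplies the
#' admission denominator for validation at stages where the ADMISSIONS
#' source is not yet integrated.
#'
#' @param tables a `kgqc_ehr_tables` list.
#' @return a data.frame with columns `hadm_id`, `subject_id`.
#' @export
admission_roster <- function(tables) {
  tables <- as_ehr_tables(tables)
  pairs <- rbind(
    data.frame(hadm_id = tables$ADMISSIONS$HADM_ID,
               subject_id = tables$ADMISSIONS$SUBJECT_ID, stringsAsFactors = FALSE),
    data.frame(hadm_id = tables$CPTEVENTS$HADM_ID,
               subject_id = tables$CPTEVENTS$SUBJECT_ID, stringsAsFactors = FALSE),
    data.frame(hadm_id = tables$DIAGNOSES_ICD$HADM_ID,
               subject_id = tables$DIAGNOSES_ICD$SUBJECT_ID, stringsAsFactors = FALSE)
  )
  pairs <- pairs[!duplicated(pairs$hadm_id), , drop = FALSE]
  pairs <- pairs[order(pairs$hadm_id), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Run the staged integration pipeline
#'
#' Maps each source to its graph fragments and integrates them one source
#' at a time in the requested order, snapshotting the accumulated graph
#' after each step. The default order mirrors a hospital workflow
#' (registration, admission, treatment, diagnosis); the reverse-style order
#' `CPTEVENTS, DIAGNOSES_ICD, ADMISSIONS, PATIENTS` is the canonical
#' alternative. The final snapshot is the same triple set for every order.
#'
#' @param tables a `kgqc_ehr_tables` list.
#' @param order a permutation of the four source names.
#' @param ontology a [mini_ontology()].
#' @return a list of class `kgqc_staged_integration` with elements
#'   `stages` (named list of `kgqc_graph_set` snapshots, one per prefix of
#'   `order`), `order`, and `roster` (see [admission_roster()]).
#' @export
run_staged_integration <- function(tables, order = EHR_TABLE_NAMES,
                                   ontology = mini_ontology()) {
  if (length(order) != 4 || !setequal(order, EHR_TABLE_NAMES)) {
    stop("configuration error: order must be a permutation of ",
         paste(EHR_TABLE_NAMES, collapse = ", "))
  }
  tables <- as_ehr_tables(tables)
  g <- NULL
  stages <- list()
  for (nm in order) {
    g <- integrate_graphs(g, map_source(tables[[nm]], nm, ontology))
    stages[[nm]] <- g
  }
  structure(
    list(stages = stages, order = order, roster = admission_roster(tables)),
    class = "kgqc_staged_integration"
  )
}
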