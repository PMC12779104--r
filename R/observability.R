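# Ledger-based detection accounting: which injected errors are observable
# in the corrupted graph, and recall/precision of the rule engine against
# the injection ledger.
#
# An inconsistent injection is observable when the fields its rule
# conditions on survive in the graph AND the triggering comparison fires --
# a gender swap with no gender-specific code on the patient, a code
# substitution landing on a compatible code, or a day/month transposition
# of a symmetric date are all ledgered but undetectable by construction.
# Observability is computed as the intersection of the operator's sphere
# of influence (the category x admission pairs it can perturb) with the
# frame-level violation predicates shared with the engine.

# sphere of influence: which categories an operator on a field can affect
operator_sphere <- function(operator, field) {
  switch(operator,
    gender_swap = c("diagnosis_gender", "procedure_gender"),
    age_alteration = c("diagnosis_age", "procedure_age", "time_sequence"),
    admit_discharge_swap = c("time_sequence", "diagnosis_age", "procedure_age"),
    day_month_swap = if (field == "CHARTDATE") {
      c("datatype", "time_sequence", "procedure_age")
    } else {
      c("datatype", "time_sequence", "diagnosis_age", "procedure_age")
    },
    code_substitution = switch(field,
      CPT_CD = c("procedure_gender", "procedure_age"),
      ICD9_CODE = c("diagnosis_gender", "diagnosis_age"),
      character(0)),  # location substitutions are benign by construction
    character(0)
  )
}

all_violation_pairs <- function(frames, rules) {
  parts <- Filter(Negate(is.null), list(
    datatype_violations(frames),
    time_violations(frames),
    compat_violations(frames$diag, "diagnosis", rules$constraints),
    compat_violations(frames$proc, "procedure", rules$constraints)
  ))
  if (length(parts) == 0) {
    return(data.frame(category = character(0), focus_node = character(0),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, parts)[, c("category", "focus_node")])
}

#' Which ledgered inconsistencies are observable in a graph?
#'
#' For every targeted inconsistent ledger entry, determines whether the
#' corrupted graph still contains the evidence needed to detect it, and if
#' so, in which categories and at which admissions the engine will flag
#' it. Fixed-point operations (the new value equals the original, e.g. a
#' day/month transposition of 2103-04-04) are never observable; so is an
#' error whose conditioning fields were subsequently deleted (e.g. a gender
#' swap followed by deletion of the gender field).
#'
#' @param ledger a `kgqc_injection_ledger`.
#' @param graphs the corrupted `kgqc_graph_set` (all sources integrated).
#' @param rules a `kgqc_rule_set`.
#' @param roster optional admission roster.
#' @return a data.frame with one row per targeted inconsistent entry:
#'   ledger columns plus `observable` and `detected_in`
#'   (`;`-separated `category@admission` pairs).
#' @export
check_observability <- function(ledger, graphs, rules, roster = NULL) {
  frames <- build_entity_frames(graphs, roster)
  pairs <- all_violation_pairs(frames, rules)
  pair_key <- paste(pairs$category, pairs$focus_node)

  entries <- ledger[ledger$kind == "inconsistent" & ledger$targeted, , drop = FALSE]
  out <- entries
  out$observable <- rep(FALSE, nrow(out))
  out$detected_in <- rep("", nrow(out))
  adm <- frames$adm
  for (i in seq_len(nrow(entries))) {
    if (entries$original_value[i] == entries$new_value[i]) next
    focus <- if (entries$table[i] == "PATIENTS") {
      adm$node[adm$subject_id == entries$subject_id[i]]
    } else {
      iri_admission(entries$hadm_id[i])
    }
    cats <- operator_sphere(entries$operator[i], entries$field[i])
    if (length(cats) == 0 || length(focus) == 0) next
    sphere <- paste(rep(cats, each = length(focus)), focus)
    hit <- sphere[sphere %in% pair_key]
    if (length(hit) > 0) {
      out$observable[i] <- TRUE
      out$detected_in[i] <- paste(sub(" ", "@", hit), collapse = ";")
    }
  }
  rownames(out) <- NULL
  out
}

# expected (category, admission) pairs attributable to completeness noise
completeness_expectation <- function(ledger, frames) {
  entries <- ledger[ledger$kind == "missing", , drop = FALSE]
  adm <- frames$adm
  parts <- list()
  for (i in seq_len(nrow(entries))) {
    focus <- if (entries$table[i] == "PATIENTS") {
      adm$node[adm$subject_id == entries$subject_id[i]]
    } else {
      iri_admission(entries$hadm_id[i])
    }
    if (length(focus) == 0) next
    cats <- "essential_completeness"
    if (entries$field[i] == "GENDER") cats <- c(cats, "conditional_completeness")
    # deleting the admission time makes procedure ages fall back to the
    # chart date, which can surface a previously masked age violation
    if (entries$field[i] == "ADMITTIME") cats <- c(cats, "procedure_age")
    parts[[length(parts) + 1L]] <- data.frame(
      category = rep(cats, each = length(focus)),
      focus_node = rep(focus, times = length(cats)), stringsAsFactors = FALSE
    )
  }
  if (length(parts) == 0) {
    data.frame(category = character(0), focus_node = character(0))
  } else {
    unique(do.call(rbind, parts))
  }
}

#' Score engine detections against the injection ledger
#'
#' Recall: per consistency category, the share of observable injected
#' errors (see [check_observability()]) flagged by the engine. Precision:
#' the share of violating (category, admission) pairs in the report that
#' are attributable to a ledgered injection -- an inconsistent operation
#' whose sphere of influence covers the pair, or a deletion affecting the
#' admission for the completeness categories. On clean data both are
#' vacuously perfect (no violations, no injections).
#'
#' @param report a `kgqc_validation_report` for `graphs` (recomputed when
#'   `NULL`).
#' @param ledger the `kgqc_injection_ledger` behind the corruption.
#' @param graphs the corrupted, fully integrated `kgqc_graph_set`.
#' @param rules the `kgqc_rule_set` used for validation.
#' @param roster optional admission roster.
#' @return a list with `recall` (data.frame: category, observable,
#'   detected, recall), `precision` (data.frame: category, violations,
#'   attributed, precision) and `overall_precision`.
#' @export
verify_against_ledger <- function(report, ledger, graphs, rules, roster = NULL) {
  if (is.null(report)) report <- validate_graphs(graphs, rules, roster = roster)
  obs <- check_observability(ledger, graphs, rules, roster)
  vio <- unique(report$violations[, c("category", "focus_node")])
  vio_key <- paste(vio$category, vio$focus_node)

  consistency <- setdiff(QUALITY_CATEGORIES,
                         c("essential_completeness", "conditional_completeness"))
  recall <- do.call(rbind, lapply(consistency, function(cat) {
    claims <- obs[obs$observable &
                    grepl(paste0("(^|;)", cat, "@"), obs$detected_in), , drop = FALSE]
    detected <- vapply(claims$detected_in, function(d) {
      ps <- strsplit(d, ";", fixed = TRUE)[[1]]
      ps <- sub("@", " ", ps[startsWith(ps, paste0(cat, "@"))])
      any(ps %in% vio_key)
    }, logical(1))
    data.frame(category = cat, observable = nrow(claims),
               detected = sum(detected),
               recall = if (nrow(claims) > 0) sum(detected) / nrow(claims) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  frames <- build_entity_frames(graphs, roster)
  expected <- rbind(
    do.call(rbind, lapply(which(obs$observable), function(i) {
      ps <- strsplit(obs$detected_in[i], ";", fixed = TRUE)[[1]]
      m <- do.call(rbind, strsplit(ps, "@", fixed = TRUE))
      data.frame(category = m[, 1], focus_node = m[, 2], stringsAsFactors = FALSE)
    })),
    completeness_expectation(ledger, frames)
  )
  expected_key <- if (is.null(expected)) character(0) else
    unique(paste(expected$category, expected$focus_node))

  precision <- do.call(rbind, lapply(QUALITY_CATEGORIES, function(cat) {
    keys <- vio_key[vio$category == cat]
    data.frame(category = cat, violations = length(keys),
               attributed = sum(keys %in% expected_key),
               precision = if (length(keys) > 0) mean(keys %in% expected_key) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  list(
    recall = recall,
    precision = precision,
    overall_precision = if (length(vio_key) > 0) mean(vio_key %in% expected_key) else 1
  )
}
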