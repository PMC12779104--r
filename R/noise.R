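# Two-parameter noise model over the EHR tables.
#
# noise_level is the proportion of eligible cells altered; completeness_ratio
# the share of altered cells made missing, the remainder being made
# logically inconsistent. Keys (SUBJECT_ID, HADM_ID) are never corrupted, so
# referential integrity is preserved. Every change is recorded in an
# injection ledger, the ground truth for detection tests.
#
# The inconsistency operator applied to a cell is determined by its column:
#   GENDER                -> gender_swap
#   DOB                   -> age_alteration
#   ADMITTIME / DISCHTIME -> admit/discharge swap or day/month swap (coin flip)
#   CHARTDATE             -> day_month_swap
#   CPT_CD / ICD9_CODE    -> code_substitution

NOISE_FIELDS <- list(
  PATIENTS = c("GENDER", "DOB"),
  ADMISSIONS = c("ADMITTIME", "DISCHTIME", "ADMISSION_LOCATION", "DISCHARGE_LOCATION"),
  CPTEVENTS = c("CHARTDATE", "CPT_CD"),
  DIAGNOSES_ICD = "ICD9_CODE"
)

#' Configure the noise model
#'
#' @param noise_level proportion of eligible cells altered, in `[0, 1]`.
#' @param completeness_ratio share of altered cells made missing (rather
#'   than inconsistent), in `[0, 1]`.
#' @param seed integer randomization seed; a fixed seed makes injection
#'   fully reproducible.
#' @return a list of class `kgqc_noise_config`.
#' @export
noise_config <- function(noise_level, completeness_ratio, seed = 1L) {
  if (length(noise_level) != 1 || is.na(noise_level) ||
      noise_level < 0 || noise_level > 1) {
    stop("configuration error: noise_level must be in [0, 1]")
  }
  if (length(completeness_ratio) != 1 || is.na(completeness_ratio) ||
      completeness_ratio < 0 || completeness_ratio > 1) {
    stop("configuration error: completeness_ratio must be in [0, 1]")
  }
  structure(
    list(noise_level = noise_level, completeness_ratio = completeness_ratio,
         seed = as.integer(seed)),
    class = "kgqc_noise_config"
  )
}

#' Enumerate the cells eligible for corruption
#'
#' All non-missing, non-key cells: GENDER/DOB in PATIENTS, the four
#' timestamp/location columns in ADMISSIONS, CHARTDATE/CPT_CD in CPTEVENTS,
#' ICD9_CODE in DIAGNOSES_ICD.
#'
#' @param tables a `kgqc_ehr_tables` list.
#' @return a data.frame with columns `table`, `row` (row index), `field`.
#' @export
eligible_cells <- function(tables) {
  tables <- as_ehr_tables(tables)
  parts <- list()
  for (nm in EHR_TABLE_NAMES) {
    df <- tables[[nm]]
    for (field in NOISE_FIELDS[[nm]]) {
      rows <- which(!is_missing_cell(df[[field]]))
      if (length(rows) > 0) {
        parts[[length(parts) + 1L]] <- data.frame(
          table = nm, row = rows, field = field, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(parts) == 0) {
    return(data.frame(table = character(0), row = integer(0), field = character(0)))
  }
  do.call(rbind, parts)
}

#' Select corruption targets
#'
#' With `n` eligible cells, `round(noise_level * n)` cells are altered
#' (rounding half away from zero), of which `round(completeness_ratio *
#' altered)` are made missing and the remainder inconsistent. Selection is
#' uniform without replacement and seeded; for a fixed seed and noise level
#' the missing sets are nested across completeness ratios, so raising the
#' ratio only converts inconsistent targets into deletions.
#'
#' @param tables a `kgqc_ehr_tables` list.
#' @param config a [noise_config()].
#' @return a list with data.frames `missing` and `inconsistent` (columns
#'   `table`, `row`, `field`); empty tables yield empty selections.
#' @export
select_targets <- function(tables, config) {
  stopifnot(inherits(config, "kgqc_noise_config"))
  cells <- eligible_cells(tables)
  n <- nrow(cells)
  n_altered <- as.integer(round_half_away(config$noise_level * n))
  n_missing <- as.integer(round_half_away(config$completeness_ratio * n_altered))
  if (n == 0 || n_altered == 0) {
    empty <- cells[0, , drop = FALSE]
    return(list(missing = empty, inconsistent = empty))
  }
  set.seed(derive_seed(config$seed, "select_targets"))
  perm <- sample.int(n)
  altered <- perm[seq_len(n_altered)]
  missing_idx <- altered[seq_len(n_missing)]
  inconsistent_idx <- if (n_missing < n_altered) altered[(n_missing + 1):n_altered] else integer(0)
  list(
    missing = cells[missing_idx, , drop = FALSE],
    inconsistent = cells[inconsistent_idx, , drop = FALSE]
  )
}

#' Swap a binary gender code
#'
#' Exchanges the two gender codes of the bundled table (male <-> female).
#' Values outside the two-code table return `NA` so callers can skip with a
#' warning.
#'
#' @param code a gender code string.
#' @param genders gender code table.
#' @return the opposite gender code, or `NA_character_`.
#' @export
gender_swap <- function(code, genders = gender_codes()) {
  if (nrow(genders) != 2) stop("gender_swap requires a two-code gender table")
  if (!code %in% genders$code) return(NA_character_)
  setdiff(genders$code, code)
}

#' Move a birth date into a different age group
#'
#' The patient's current age group (relative to `reference_date`) is
#' excluded; a new group is drawn with the supplied dataset-frequency
#' weights renormalized over the remaining groups, and a new age is drawn
#' uniformly within the chosen group. The returned birth date is
#' `reference_date` minus the new age, floored to midnight UTC.
#'
#' @param dob ISO 8601 birth date string (must parse).
#' @param reference_date `POSIXct` reference time used to compute ages.
#' @param weights four non-negative group frequencies (infant, child,
#'   adult, senior); need not be normalized.
#' @param partition age-group partition; must have at least two groups.
#' @return a new ISO 8601 birth date string.
#' @export
age_alteration <- function(dob, reference_date, weights, partition = age_groups()) {
  if (nrow(partition) < 2) {
    stop("age_alteration impossible: partition has fewer than two groups")
  }
  dob_t <- parse_iso8601(dob)
  if (is.na(dob_t)) stop("age_alteration requires a parseable birth date")
  cur_group <- age_group_of(age_years(dob_t, reference_date), partition)
  other <- which(partition$group != cur_group)
  w <- weights[other]
  if (sum(w) <= 0) w <- rep(1, length(other))
  for (attempt in 1:10) {
    g <- other[sample.int(length(other), 1, prob = w)]
    new_age <- stats::runif(1, partition$min[g], partition$max[g])
    new_dob <- reference_date - round(new_age * 365.2425 * 86400)
    new_dob <- as.POSIXct(trunc(as.POSIXlt(new_dob, tz = "UTC"), units = "days"), tz = "UTC")
    # flooring to midnight can nudge the age across a boundary; re-check
    if (age_group_of(age_years(new_dob, reference_date), partition) != cur_group) break
  }
  format_iso8601(new_dob)
}

#' Swap admission and discharge timestamps of an admission record
#'
#' @param record a one-row data.frame with `ADMITTIME` and `DISCHTIME`.
#' @return the record with the two timestamps exchanged. Equal timestamps
#'   make the swap a fixed point; the operation is still ledgered when
#'   applied through [inject_noise()].
#' @export
swap_admit_discharge <- function(record) {
  if (is_missing_cell(record$ADMITTIME) || is_missing_cell(record$DISCHTIME)) {
    warning("swap_admit_discharge: missing timestamp, record left unchanged")
    return(record)
  }
  tmp <- record$ADMITTIME
  record$ADMITTIME <- record$DISCHTIME
  record$DISCHTIME <- tmp
  record
}

#' Transpose the day and month components of a timestamp string
#'
#' The exchange is textual: `2103-03-25T...` becomes `2103-25-03T...`,
#' which is not a valid calendar date (month 25). The result is emitted as
#' a raw string and never re-parsed, so invalid dates survive into the
#' knowledge graph where datatype rules can flag them. When both components
#' are <= 12 the result is a valid but chronologically shifted date, and
#' when day equals month the value is unchanged (still ledgered as operated
#' on by [inject_noise()]).
#'
#' @param value ISO 8601-shaped timestamp string.
#' @return the transposed string.
#' @export
day_month_swap <- function(value) {
  if (!is_iso8601_shaped(value)) {
    warning("day_month_swap: value is not ISO 8601 shaped, left unchanged")
    return(value)
  }
  paste0(
    substr(value, 1, 5),
    substr(value, 9, 10), "-", substr(value, 6, 7),
    substr(value, 11, nchar(value))
  )
}

#' Replace a code with a different one drawn uniformly from a ruleset
#'
#' The original code is excluded; the replacement is sampled uniformly from
#' the remaining codes, so with a two-code ruleset the substitution is
#' deterministic.
#'
#' @param code the current code.
#' @param pool character vector of all codes in the ruleset (>= 2 codes).
#' @return a code different from `code`.
#' @export
code_substitution <- function(code, pool) {
  remaining <- setdiff(pool, code)
  if (length(remaining) == 0) {
    stop("code_substitution requires a ruleset with at least 2 codes")
  }
  remaining[sample.int(length(remaining), 1)]
}

#' Delete targeted cells (completeness noise)
#'
#' Sets every targeted cell to the missing sentinel (the empty string).
#' Because targets are drawn uniformly over each table's non-key cells, the
#' per-field deletion shares follow each table's cell layout: GENDER/DOB
#' half each, the four ADMISSIONS fields a quarter each, CHARTDATE/CPT_CD
#' half each, and ICD9_CODE always.
#'
#' @param tables a `kgqc_ehr_tables` list.
#' @param missing_targets data.frame of targets (`table`, `row`, `field`).
#' @return the tables with targeted cells blanked; zero targets is the
#'   identity.
#' @export
delete_fields <- function(tables, missing_targets) {
  tables <- as_ehr_tables(tables)
  if (nrow(missing_targets) == 0) return(tables)
  for (i in seq_len(nrow(missing_targets))) {
    t <- missing_targets$table[i]
    tables[[t]][missing_targets$row[i], missing_targets$field[i]] <- ""
  }
  tables
}

row_id_for <- function(tables, table, row) {
  switch(table,
    PATIENTS = tables$PATIENTS$SUBJECT_ID[row],
    ADMISSIONS = tables$ADMISSIONS$HADM_ID[row],
    as.character(row)  # event tables have no natural key; use the row index
  )
}

new_ledger <- function() {
  data.frame(
    table = character(0), row = integer(0), row_id = character(0),
    subject_id = character(0), hadm_id = character(0),
    field = character(0), kind = character(0), operator = character(0),
    original_value = character(0), new_value = character(0),
    targeted = logical(0), stringsAsFactors = FALSE
  )
}

#' Inject noise into clean tables
#'
#' Composes target selection, the five consistency operators (dispatched by
#' the targeted cell's column) and field deletion, and records every change
#' in an injection ledger. Inconsistencies are applied before deletions, in
#' a fixed deterministic cell order; the same seed therefore yields
#' identical corrupted tables and an identical ledger.
#'
#' The ledger has one row per changed cell: `kind` is `"missing"` or
#' `"inconsistent"`, `operator` names the responsible operator, and
#' `targeted` distinguishes selected cells from the partner cell of an
#' admit/discharge swap (which changes two cells for one target). Counts of
#' targeted rows by kind match [select_targets()] exactly, except for the
#' rare skip of a cell whose operator precondition fails (warned about).
#'
#' @param tables clean `kgqc_ehr_tables`.
#' @param config a [noise_config()].
#' @param diagnosis_constraints,procedure_constraints code rulesets
#'   supplying substitution pools.
#' @param genders gender code table.
#' @param partition age-group partition for [age_alteration()].
#' @return a list of class `kgqc_injection` with elements `tables`
#'   (corrupted) and `ledger`.
#' @export
inject_noise <- function(tables, config,
                         diagnosis_constraints = diagnosis_codes(),
                         procedure_constraints = procedure_codes(),
                         genders = gender_codes(),
                         partition = age_groups()) {
  tables <- as_ehr_tables(tables)
  stopifnot(inherits(config, "kgqc_noise_config"))
  targets <- select_targets(tables, config)

  # dataset age-group frequencies and reference date, from the input tables
  admit_t <- parse_iso8601(tables$ADMISSIONS$ADMITTIME)
  reference_date <- if (any(!is.na(admit_t))) max(admit_t, na.rm = TRUE) else
    parse_iso8601("2120-01-01T00:00:00+00:00")
  dob_t <- parse_iso8601(tables$PATIENTS$DOB)
  grp <- age_group_of(age_years(dob_t[!is.na(dob_t)], reference_date), partition)
  weights <- as.numeric(table(factor(grp, levels = partition$group)))
  if (sum(weights) == 0) weights <- rep(1, nrow(partition))

  inc <- targets$inconsistent
  if (nrow(inc) > 0) {
    ord <- order(match(inc$table, EHR_TABLE_NAMES), inc$row,
                 match(inc$field, unlist(NOISE_FIELDS, use.names = FALSE)))
    inc <- inc[ord, , drop = FALSE]
  }

  set.seed(derive_seed(config$seed, "operators"))
  ledger <- vector("list", 0)
  note <- function(table, row, field, kind, operator, old, new, targeted = TRUE) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      table = table, row = row, row_id = row_id_for(tables, table, row),
      subject_id = tables[[table]]$SUBJECT_ID[row],
      hadm_id = if (table == "PATIENTS") "" else tables[[table]]$HADM_ID[row],
      field = field, kind = kind, operator = operator,
      original_value = old, new_value = new, targeted = targeted,
      stringsAsFactors = FALSE
    )
  }

  for (i in seq_len(nrow(inc))) {
    tb <- inc$table[i]; r <- inc$row[i]; f <- inc$field[i]
    cur <- tables[[tb]][r, f]
    if (is_missing_cell(cur)) {
      warning("inconsistency target ", tb, "[", r, ",", f, "] is missing; skipped")
      next
    }
    if (f == "GENDER") {
      new <- gender_swap(cur, genders)
      if (is.na(new)) {
        warning("gender value '", cur, "' not in the gender code table; skipped")
        next
      }
      tables[[tb]][r, f] <- new
      note(tb, r, f, "inconsistent", "gender_swap", cur, new)
    } else if (f == "DOB") {
      if (is.na(parse_iso8601(cur))) {
        warning("unparseable DOB at row ", r, "; skipped")
        next
      }
      new <- age_alteration(cur, reference_date, weights, partition)
      tables[[tb]][r, f] <- new
      note(tb, r, f, "inconsistent", "age_alteration", cur, new)
    } else if (f %in% c("ADMITTIME", "DISCHTIME")) {
      partner <- setdiff(c("ADMITTIME", "DISCHTIME"), f)
      use_swap <- stats::runif(1) < 0.5
      if (use_swap && !is_missing_cell(tables[[tb]][r, partner])) {
        pv <- tables[[tb]][r, partner]
        tables[[tb]][r, f] <- pv
        tables[[tb]][r, partner] <- cur
        note(tb, r, f, "inconsistent", "admit_discharge_swap", cur, pv)
        note(tb, r, partner, "inconsistent", "admit_discharge_swap", pv, cur,
             targeted = FALSE)
      } else {
        new <- day_month_swap(cur)
        tables[[tb]][r, f] <- new
        note(tb, r, f, "inconsistent", "day_month_swap", cur, new)
      }
    } else if (f == "CHARTDATE") {
      new <- day_month_swap(cur)
      tables[[tb]][r, f] <- new
      note(tb, r, f, "inconsistent", "day_month_swap", cur, new)
    } else if (f == "CPT_CD") {
      new <- code_substitution(cur, procedure_constraints$code)
      tables[[tb]][r, f] <- new
      note(tb, r, f, "inconsistent", "code_substitution", cur, new)
    } else if (f == "ICD9_CODE") {
      new <- code_substitution(cur, diagnosis_constraints$code)
      tables[[tb]][r, f] <- new
      note(tb, r, f, "inconsistent", "code_substitution", cur, new)
    } else if (f == "ADMISSION_LOCATION") {
      # free-label fields have no dedicated operator; substitute uniformly
      # from the location vocabulary (benign: no rule constrains locations)
      new <- code_substitution(cur, ADMISSION_LOCATIONS)
      tables[[tb]][r, f] <- new
      note(tb, r, f, "inconsistent", "code_substitution", cur, new)
    } else if (f == "DISCHARGE_LOCATION") {
      new <- code_substitution(cur, DISCHARGE_LOCATIONS)
      tables[[tb]][r, f] <- new
      note(tb, r, f, "inconsistent", "code_substitution", cur, new)
    } else {
      stop("no consistency operator for field ", f)
    }
  }

  mis <- targets$missing
  if (nrow(mis) > 0) {
    ord <- order(match(mis$table, EHR_TABLE_NAMES), mis$row,
                 match(mis$field, unlist(NOISE_FIELDS, use.names = FALSE)))
    mis <- mis[ord, , drop = FALSE]
    for (i in seq_len(nrow(mis))) {
      tb <- mis$table[i]; r <- mis$row[i]; f <- mis$field[i]
      note(tb, r, f, "missing", "field_deletion", tables[[tb]][r, f], "")
    }
    tables <- delete_fields(tables, mis)
  }

  ledger <- if (length(ledger) > 0) do.call(rbind, ledger) else new_ledger()
  class(ledger) <- c("kgqc_injection_ledger", "data.frame")
  structure(list(tables = tables, ledger = ledger), class = "kgqc_injection")
}

#' Write an injection ledger to CSV or JSON lines
#'
#' @param ledger a `kgqc_injection_ledger` data.frame.
#' @param path output file.
#' @param format `"csv"` or `"jsonl"` (one JSON object per entry and line).
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(ledger, path, row.names = FALSE, quote = TRUE)
  } else {
    lines <- vapply(seq_len(nrow(ledger)), function(i) {
      jsonlite::toJSON(as.list(ledger[i, , drop = FALSE]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an injection ledger written by [write_ledger()]
#'
#' @param path a CSV ledger file.
#' @return a `kgqc_injection_ledger` data.frame.
#' @export
read_ledger <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    table = "character", row = "integer", row_id = "character",
    subject_id = "character", hadm_id = "character",
    field = "character", kind = "character", operator = "character",
    original_value = "character", new_value = "character", targeted = "logical"
  ))
  df$original_value[is.na(df$original_value)] <- ""
  df$new_value[is.na(df$new_value)] <- ""
  class(df) <- c("kgqc_injection_ledger", "data.frame")
  df
}
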