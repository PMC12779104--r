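# Synthetic MIMIC-like cohort generation.
#
# Four linked tables -- PATIENTS, ADMISSIONS, CPTEVENTS, DIAGNOSES_ICD --
# with the column names of their MIMIC-III counterparts. Clean output is
# internally consistent by construction: admission episodes are
# chronologically valid, chart dates fall inside their admission, every
# admission carries at least one diagnosis and one procedure (the inclusion
# criterion applied to the source data), and every assigned code is
# compatible with the patient's gender and age at that admission.

EHR_TABLE_NAMES <- c("PATIENTS", "ADMISSIONS", "CPTEVENTS", "DIAGNOSES_ICD")

EHR_COLUMNS <- list(
  PATIENTS = c("SUBJECT_ID", "GENDER", "DOB"),
  ADMISSIONS = c("HADM_ID", "SUBJECT_ID", "ADMITTIME", "DISCHTIME",
                 "ADMISSION_LOCATION", "DISCHARGE_LOCATION"),
  CPTEVENTS = c("HADM_ID", "SUBJECT_ID", "CHARTDATE", "CPT_CD"),
  DIAGNOSES_ICD = c("HADM_ID", "SUBJECT_ID", "ICD9_CODE")
)

ADMISSION_LOCATIONS <- c("EMERGENCY ROOM ADMIT", "PHYSICIAN REFERRAL",
                         "CLINIC REFERRAL", "TRANSFER FROM HOSPITAL")
DISCHARGE_LOCATIONS <- c("HOME", "HOME HEALTH CARE", "SNF", "REHAB")

#' Specify a synthetic cohort
#'
#' Counts-per-entity distributions are shifted Poisson (`1 + Poisson(mean - 1)`),
#' so every patient has at least one admission and every admission at least
#' one procedure and one diagnosis, mirroring an inclusion filter that drops
#' admissions lacking relevant codes. Age-group weights give the marginal
#' distribution over the four age groups of [age_groups()].
#'
#' @param n_patients number of patients (>= 0).
#' @param admissions_per_patient,procedures_per_admission,diagnoses_per_admission
#'   mean of the shifted Poisson count distribution (>= 1).
#' @param age_group_weights four non-negative weights (infant, child, adult,
#'   senior) summing to 1.
#' @param seed integer seed; a fixed seed makes [generate_cohort()] output
#'   bit-identical across runs.
#' @return a list of class `kgqc_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200,
                        admissions_per_patient = 1.6,
                        procedures_per_admission = 1.8,
                        diagnoses_per_admission = 2.2,
                        age_group_weights = c(infant = 0.05, child = 0.10,
                                              adult = 0.55, senior = 0.30),
                        seed = 1L) {
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients < 0 ||
      n_patients != trunc(n_patients)) {
    stop("configuration error: n_patients must be a non-negative integer")
  }
  means <- c(admissions_per_patient, procedures_per_admission, diagnoses_per_admission)
  if (any(is.na(means)) || any(means < 1)) {
    stop("configuration error: per-entity count means must be >= 1")
  }
  w <- as.numeric(age_group_weights)
  if (length(w) != 4 || any(is.na(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("configuration error: age_group_weights must be 4 non-negative values summing to 1")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      admissions_per_patient = admissions_per_patient,
      procedures_per_admission = procedures_per_admission,
      diagnoses_per_admission = diagnoses_per_admission,
      age_group_weights = w,
      seed = as.integer(seed)
    ),
    class = "kgqc_cohort_spec"
  )
}

empty_ehr_tables <- function() {
  tabs <- lapply(EHR_COLUMNS, function(cols) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    df
  })
  structure(tabs, class = "kgqc_ehr_tables")
}

as_ehr_tables <- function(tables) {
  stopifnot(all(EHR_TABLE_NAMES %in% names(tables)))
  structure(tables[EHR_TABLE_NAMES], class = "kgqc_ehr_tables")
}

#' @export
print.kgqc_ehr_tables <- function(x, ...) {
  cat("<kgqc_ehr_tables>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-13s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Generate a clean synthetic cohort
#'
#' Admissions are placed in the years 2100-2120 (echoing the shifted-era
#' feel of deidentified critical-care data while keeping age arithmetic
#' meaningful); the birth date is derived from the age drawn for the first
#' admission. Diagnosis and procedure codes are sampled only from codes
#' compatible with the patient's gender and completed age at that admission,
#' so a clean cohort raises zero violations in every rule category.
#'
#' @param spec a [cohort_spec()].
#' @param diagnosis_constraints,procedure_constraints code rulesets to draw
#'   codes from (defaults: the bundled mini rulesets).
#' @param genders gender code table.
#' @return a `kgqc_ehr_tables` list of four character-column data.frames.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            diagnosis_constraints = diagnosis_codes(),
                            procedure_constraints = procedure_codes(),
                            genders = gender_codes()) {
  if (!inherits(spec, "kgqc_cohort_spec")) spec <- do.call(cohort_spec, spec)
  if (spec$n_patients == 0) return(empty_ehr_tables())

  set.seed(derive_seed(spec$seed, "cohort"))
  groups <- age_groups()
  # generation stays below 100y so that ages remain plausible across later
  # admissions; the partition itself extends to 124
  gen_max <- c(1, 12, 56, 100)

  n <- spec$n_patients
  subject_id <- as.character(10000L + seq_len(n))
  gender_lbl <- sample(genders$label, n, replace = TRUE)
  gender_code <- genders$code[match(gender_lbl, genders$label)]
  grp_idx <- sample.int(4, n, replace = TRUE, prob = spec$age_group_weights)
  age_draw <- stats::runif(n, groups$min[grp_idx], gen_max[grp_idx])

  window_start <- as.POSIXct("2100-01-01 00:00:00", tz = "UTC")
  window_end <- as.POSIXct("2120-12-31 00:00:00", tz = "UTC")
  first_admit <- window_start +
    round(stats::runif(n, 0, as.numeric(difftime(window_end, window_start, units = "secs"))))
  # birth date = first admission minus drawn age, floored to midnight UTC
  dob <- first_admit - round(age_draw * 365.2425) * 86400
  dob <- as.POSIXct(trunc(as.POSIXlt(dob, tz = "UTC"), units = "days"), tz = "UTC")

  n_adm <- 1L + stats::rpois(n, spec$admissions_per_patient - 1)

  adm_rows <- vector("list", n)
  hadm_counter <- 100000L
  for (i in seq_len(n)) {
    k <- n_adm[i]
    admit <- disch <- as.POSIXct(numeric(k), origin = "1970-01-01", tz = "UTC")
    t0 <- first_admit[i]
    for (j in seq_len(k)) {
      if (j > 1) t0 <- disch[j - 1] + round(stats::runif(1, 30, 400) * 86400)
      admit[j] <- t0
      disch[j] <- t0 + round(stats::runif(1, 1, 30) * 86400)
    }
    adm_rows[[i]] <- data.frame(
      HADM_ID = as.character(hadm_counter + seq_len(k)),
      SUBJECT_ID = subject_id[i],
      ADMITTIME = format_iso8601(admit),
      DISCHTIME = format_iso8601(disch),
      ADMISSION_LOCATION = sample(ADMISSION_LOCATIONS, k, replace = TRUE),
      DISCHARGE_LOCATION = sample(DISCHARGE_LOCATIONS, k, replace = TRUE),
      stringsAsFactors = FALSE
    )
    hadm_counter <- hadm_counter + k
  }
  admissions <- do.call(rbind, adm_rows)

  patients <- data.frame(
    SUBJECT_ID = subject_id,
    GENDER = gender_code,
    DOB = format_iso8601(dob),
    stringsAsFactors = FALSE
  )

  # per-admission code assignment, compatible with gender and age at admit
  adm_admit <- parse_iso8601(admissions$ADMITTIME)
  adm_disch <- parse_iso8601(admissions$DISCHTIME)
  adm_subject <- admissions$SUBJECT_ID
  adm_gender <- patients$GENDER[match(adm_subject, patients$SUBJECT_ID)]
  adm_dob <- parse_iso8601(patients$DOB[match(adm_subject, patients$SUBJECT_ID)])
  adm_age <- age_years(adm_dob, adm_admit)

  pick_codes <- function(constraints, gender, age, k) {
    ok <- vapply(split_genders(constraints$allowed_genders),
                 function(g) gender %in% g, logical(1)) &
      constraints$age_min <= age & age <= constraints$age_max
    pool <- constraints$code[ok]
    if (length(pool) == 0) stop("no compatible codes for age ", age)
    sample(pool, min(k, length(pool)))
  }

  m <- nrow(admissions)
  n_proc <- 1L + stats::rpois(m, spec$procedures_per_admission - 1)
  n_diag <- 1L + stats::rpois(m, spec$diagnoses_per_admission - 1)
  proc_rows <- vector("list", m)
  diag_rows <- vector("list", m)
  for (r in seq_len(m)) {
    stay <- as.numeric(difftime(adm_disch[r], adm_admit[r], units = "secs"))
    cpt <- pick_codes(procedure_constraints, adm_gender[r], adm_age[r], n_proc[r])
    chart <- adm_admit[r] + round(stats::runif(length(cpt), 0, stay))
    proc_rows[[r]] <- data.frame(
      HADM_ID = admissions$HADM_ID[r],
      SUBJECT_ID = adm_subject[r],
      CHARTDATE = format_iso8601(chart),
      CPT_CD = cpt,
      stringsAsFactors = FALSE
    )
    icd <- pick_codes(diagnosis_constraints, adm_gender[r], adm_age[r], n_diag[r])
    diag_rows[[r]] <- data.frame(
      HADM_ID = admissions$HADM_ID[r],
      SUBJECT_ID = adm_subject[r],
      ICD9_CODE = icd,
      stringsAsFactors = FALSE
    )
  }

  as_ehr_tables(list(
    PATIENTS = patients,
    ADMISSIONS = admissions,
    CPTEVENTS = do.call(rbind, proc_rows),
    DIAGNOSES_ICD = do.call(rbind, diag_rows)
  ))
}

#' Drop admissions lacking diagnosis or procedure codes
#'
#' Retains only admissions with at least one non-missing diagnosis code and
#' at least one non-missing procedure code; dependent procedure/diagnosis
#' rows of dropped admissions are removed as well. Patients are retained
#' even if all their admissions are dropped. The filter is total: already
#' complete input passes through unchanged.
#'
#' @param tables a `kgqc_ehr_tables` list.
#' @return the filtered tables.
#' @export
apply_inclusion_filter <- function(tables) {
  tables <- as_ehr_tables(tables)
  diag_ok <- unique(tables$DIAGNOSES_ICD$HADM_ID[!is_missing_cell(tables$DIAGNOSES_ICD$ICD9_CODE)])
  proc_ok <- unique(tables$CPTEVENTS$HADM_ID[!is_missing_cell(tables$CPTEVENTS$CPT_CD)])
  keep <- intersect(tables$ADMISSIONS$HADM_ID, intersect(diag_ok, proc_ok))
  tables$ADMISSIONS <- tables$ADMISSIONS[tables$ADMISSIONS$HADM_ID %in% keep, , drop = FALSE]
  tables$CPTEVENTS <- tables$CPTEVENTS[tables$CPTEVENTS$HADM_ID %in% keep, , drop = FALSE]
  tables$DIAGNOSES_ICD <- tables$DIAGNOSES_ICD[tables$DIAGNOSES_ICD$HADM_ID %in% keep, , drop = FALSE]
  rownames(tables$ADMISSIONS) <- NULL
  rownames(tables$CPTEVENTS) <- NULL
  rownames(tables$DIAGNOSES_ICD) <- NULL
  tables
}
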