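# Bundled terminology: gender codes and demographically constrained
# diagnosis (ICD-9) / procedure (CPT) code lists.
#
# These mini rulesets mirror the structure of full code-compatibility shape
# libraries at toy scale: every code carries the set of genders it may be
# assigned to and an allowed age interval in completed years. Both lists
# include gender-specific and age-specific entries so that demographic
# corruption is detectable.

#' Gender code table
#'
#' Two-entry concept table mapping gender labels to terminology codes
#' (SNOMED CT: 248153007 male, 248152002 female). The GENDER column of the
#' patients table carries the code, not the label. The field is an open code
#' string: values outside this table pass format checks, the table only
#' defines the two codes the generator and the swap operator use.
#'
#' @param path optional path to an alternative two-column (`code`,`label`)
#'   CSV; defaults to the bundled table.
#' @return a data.frame with columns `code`, `label`.
#' @export
gender_codes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gender_codes.csv", package = "kgqc")
  utils::read.csv(path, colClasses = "character")
}

#' Construct a validated set of code-demographic constraints
#'
#' Each row constrains one diagnosis or procedure code: which genders it may
#' be assigned to and the allowed age interval `[age_min, age_max]` in
#' completed years (both ends inclusive, `0 <= min < max <= 124`).
#'
#' @param df a data.frame with columns `code`, `kind` (`"diagnosis"` or
#'   `"procedure"`), `allowed_genders` (pipe-separated gender codes),
#'   `age_min`, `age_max`, and optionally `description`.
#' @return the data.frame with class `kgqc_code_constraints`.
#' @export
code_constraints <- function(df) {
  required <- c("code", "kind", "allowed_genders", "age_min", "age_max")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("code constraint table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  df$code <- as.character(df$code)
  df$allowed_genders <- as.character(df$allowed_genders)
  df$age_min <- as.numeric(df$age_min)
  df$age_max <- as.numeric(df$age_max)
  if (any(!df$kind %in% c("diagnosis", "procedure"))) {
    stop("code constraint kind must be 'diagnosis' or 'procedure'")
  }
  if (any(is.na(df$allowed_genders) | df$allowed_genders == "")) {
    stop("every code constraint needs a non-empty allowed_genders set")
  }
  bad_age <- is.na(df$age_min) | is.na(df$age_max) |
    df$age_min < 0 | df$age_min >= df$age_max | df$age_max > 124
  if (any(bad_age)) {
    stop(
      "invalid age interval for code(s): ",
      paste(df$code[bad_age], collapse = ", "),
      " (need 0 <= min < max <= 124)"
    )
  }
  if (anyDuplicated(df$code)) {
    stop("duplicate codes in constraint table: ",
         paste(unique(df$code[duplicated(df$code)]), collapse = ", "))
  }
  class(df) <- c("kgqc_code_constraints", "data.frame")
  df
}

load_code_table <- function(path, kind, genders) {
  df <- utils::read.csv(path, colClasses = "character")
  df$kind <- kind
  # the CSVs carry labels ("male|female"); translate to gender codes
  df$allowed_genders <- vapply(strsplit(df$allowed_genders, "|", fixed = TRUE), function(lbls) {
    codes <- genders$code[match(lbls, genders$label)]
    if (anyNA(codes)) stop("unknown gender label in ", path)
    paste(codes, collapse = "|")
  }, character(1))
  code_constraints(df[, c("code", "kind", "allowed_genders", "age_min", "age_max", "description")])
}

#' Bundled diagnosis (ICD-9) code constraints
#'
#' @param path optional alternative CSV (`code`, `description`,
#'   `allowed_genders` as pipe-separated labels, `age_min`, `age_max`).
#' @param genders gender code table used to translate labels to codes.
#' @return a `kgqc_code_constraints` data.frame.
#' @export
diagnosis_codes <- function(path = NULL, genders = gender_codes()) {
  path <- path %||% system.file("extdata", "diagnosis_codes.csv", package = "kgqc")
  load_code_table(path, "diagnosis", genders)
}

#' Bundled procedure (CPT) code constraints
#'
#' @inheritParams diagnosis_codes
#' @return a `kgqc_code_constraints` data.frame.
#' @export
procedure_codes <- function(path = NULL, genders = gender_codes()) {
  path <- path %||% system.file("extdata", "procedure_codes.csv", package = "kgqc")
  load_code_table(path, "procedure", genders)
}

# split a pipe-joined allowed_genders cell into a character vector
split_genders <- function(x) strsplit(x, "|", fixed = TRUE)
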