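# CSV round-trip for the four EHR tables.

DATE_COLUMNS <- list(
  PATIENTS = "DOB",
  ADMISSIONS = c("ADMITTIME", "DISCHTIME"),
  CPTEVENTS = "CHARTDATE",
  DIAGNOSES_ICD = character(0)
)

#' Write the four EHR tables as CSV
#'
#' One file per table (`PATIENTS.csv`, `ADMISSIONS.csv`, `CPTEVENTS.csv`,
#' `DIAGNOSES_ICD.csv`), header row included, dates serialized as ISO 8601
#' with timezone offset. Output is byte-identical for identical input, and
#' [read_tables()] restores the tables exactly (missing cells are empty
#' strings on both sides).
#'
#' @param tables a `kgqc_ehr_tables` list.
#' @param directory output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_tables <- function(tables, directory) {
  tables <- as_ehr_tables(tables)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (nm in EHR_TABLE_NAMES) {
    utils::write.csv(tables[[nm]], file.path(directory, paste0(nm, ".csv")),
                     row.names = FALSE, quote = TRUE, na = "")
  }
  invisible(directory)
}

#' Read the four EHR tables from CSV
#'
#' Validates the schema strictly: every table must carry exactly its
#' expected columns, and every non-empty value in a date column must match
#' the ISO 8601 timestamp shape `YYYY-MM-DDThh:mm:ss+zz:zz`. A value like
#' `12/05/2103` is rejected with an error naming the file and line; a value
#' like `2103-25-03T10:00:00+00:00` (right shape, impossible month, as
#' produced by day/month transposition noise) is accepted here and left to
#' datatype validation downstream.
#'
#' @param directory directory holding the four CSV files.
#' @return a `kgqc_ehr_tables` list with all-character columns.
#' @export
read_tables <- function(directory) {
  out <- list()
  for (nm in EHR_TABLE_NAMES) {
    path <- file.path(directory, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("format error: missing table file ", path)
    df <- tryCatch(
      utils::read.csv(path, colClasses = "character", check.names = FALSE),
      error = function(e) stop("format error in ", path, ": ", conditionMessage(e))
    )
    expected <- EHR_COLUMNS[[nm]]
    unknown <- setdiff(names(df), expected)
    if (length(unknown) > 0) {
      stop("format error in ", path, ": unknown column(s) ",
           paste(unknown, collapse = ", "))
    }
    if (length(setdiff(expected, names(df))) > 0) {
      stop("format error in ", path, ": missing column(s) ",
           paste(setdiff(expected, names(df)), collapse = ", "))
    }
    df <- df[, expected, drop = FALSE]
    df[is.na(df)] <- ""
    for (col in DATE_COLUMNS[[nm]]) {
      vals <- df[[col]]
      bad <- vals != "" & !is_iso8601_shaped(vals)
      if (any(bad)) {
        line <- which(bad)[1] + 1L  # +1 for the header row
        stop("format error in ", path, " line ", line, ": '", vals[which(bad)[1]],
             "' in column ", col, " is not an ISO 8601 timestamp")
      }
    }
    out[[nm]] <- df
  }
  as_ehr_tables(out)
}
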