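# Category-wise quality scores across integration stages.
#
# Quality score = 1 - e, with e the error rate: violating admissions
# divided by checked admissions within the category. A category with no
# checkable admissions is N/A rather than perfect, so empty categories
# cannot masquerade as clean data.

#' Quality scores of a validation report
#'
#' @param report a `kgqc_validation_report`.
#' @return a data.frame with one row per category: `stage`, `category`,
#'   `violations`, `checked`, `error_rate`, `score` (`NA` when the
#'   category is not assessable at this stage or has no checked nodes).
#' @export
quality_scores <- function(report) {
  s <- report$summary
  e <- ifelse(s$assessable & s$checked > 0, s$violations / s$checked, NA_real_)
  data.frame(
    stage = report$stage, category = s$category,
    violations = s$violations, checked = s$checked,
    error_rate = e, score = 1 - e, stringsAsFactors = FALSE
  )
}

#' Collect staged validation reports into a long score table
#'
#' Pure bookkeeping: no score is recomputed, the per-stage reports are
#' concatenated in pipeline order into a long (stage x category) table.
#'
#' @param reports a list of `kgqc_validation_report`, one per stage.
#' @return a long-format data.frame of [quality_scores()] rows.
#' @export
track_stages <- function(reports) {
  out <- do.call(rbind, lapply(reports, quality_scores))
  rownames(out) <- NULL
  out
}

#' Truncate a score to a percentage with two decimals
#'
#' Truncation toward zero, not rounding: 13,593/13,607 = 0.998971 prints
#' as 99.89, not 99.9. Centralized here so every report renders
#' identically.
#'
#' @param score a score in `[0, 1]` (or `NA`).
#' @return numeric percentage truncated at two decimals.
#' @export
truncate_percent <- function(score) {
  floor(score * 10000 + 1e-9) / 100
}

#' Render a score as a percentage string
#'
#' Two decimals with truncation toward zero and trailing zeros trimmed:
#' `0.998971` renders as `"99.89%"`, `1` as `"100%"`, `NA` as `"N/A"`.
#'
#' @param score a score in `[0, 1]` (vectorized; `NA` allowed).
#' @return character vector.
#' @export
format_percent <- function(score) {
  p <- truncate_percent(score)
  txt <- sub("0+$", "", sprintf("%.2f", p))
  txt <- sub("\\.$", "", txt)
  out <- paste0(txt, "%")
  out[is.na(score)] <- "N/A"
  out
}

#' Write experiment results as CSV and JSON
#'
#' `scores.csv` is the long score table over every grid cell, order and
#' stage (with a `score_pct` column rendered by [format_percent()]);
#' `experiment.json` echoes the grid metadata and per-cell score tables in
#' plotting-ready form.
#'
#' @param results a list of experiment results as returned by
#'   [run_experiment()].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
format_report <- function(results, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  scores <- do.call(rbind, lapply(results, function(r) {
    if (!is.null(r$error)) return(NULL)
    cbind(grid = r$label, order = paste(r$order, collapse = ">"), r$scores,
          stringsAsFactors = FALSE)
  }))
  scores$score_pct <- format_percent(scores$score)
  utils::write.csv(scores, file.path(path, "scores.csv"), row.names = FALSE)
  meta <- lapply(results, function(r) {
    list(grid = r$label, order = r$order,
         noise_level = r$noise_level, completeness_ratio = r$completeness_ratio,
         seed = r$seed, error = r$error,
         scores = if (is.null(r$error)) r$scores else NULL)
  })
  jsonlite::write_json(meta, file.path(path, "experiment.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
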