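# Internal helpers: ISO 8601 handling, seeded substreams, age arithmetic.

ISO8601_REGEX <- "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}[+-]\\d{2}:\\d{2}$"

#' Format timestamps as ISO 8601 with explicit UTC offset
#'
#' All timestamps carried in the EHR tables use the
#' `YYYY-MM-DDThh:mm:ss+zz:zz` profile of ISO 8601. Values are rendered in
#' UTC with a `+00:00` offset.
#'
#' @param x a `POSIXct` vector.
#' @return a character vector of ISO 8601 strings.
#' @export
format_iso8601 <- function(x) {
  out <- strftime(x, "%Y-%m-%dT%H:%M:%S+00:00", tz = "UTC")
  out[is.na(x)] <- NA_character_
  out
}

#' Parse ISO 8601 timestamps, returning NA for malformed or invalid values
#'
#' Accepts only the `YYYY-MM-DDThh:mm:ss+zz:zz` profile. Strings that match
#' the textual shape but are not valid calendar dates (for example a month
#' of 25 produced by a day/month transposition) parse to `NA`; so do strings
#' in any other layout. The distinction between "wrong shape" (rejected at
#' file read) and "right shape, invalid calendar value" (carried through so
#' datatype rules can flag it) is deliberate.
#'
#' @param x a character vector.
#' @return a `POSIXct` vector (UTC), `NA` where unparseable.
#' @export
parse_iso8601 <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  ok <- !is.na(x) & grepl(ISO8601_REGEX, x)
  if (any(ok)) {
    y <- x[ok]
    # fold "+zz:zz" into "%z" form, then let strptime enforce calendar validity
    z <- paste0(substr(y, 1, 19), sub(":", "", substr(y, 20, 25), fixed = TRUE))
    parsed <- strptime(z, "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
    out[ok] <- as.POSIXct(parsed, tz = "UTC")
  }
  out
}

#' Does a string match the ISO 8601 timestamp shape?
#' @param x character vector.
#' @return logical vector.
#' @export
is_iso8601_shaped <- function(x) {
  !is.na(x) & grepl(ISO8601_REGEX, x)
}

# Missing sentinel in CSV cells is the empty string.
is_missing_cell <- function(x) {
  is.na(x) | x == ""
}

# Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x) {
  trunc(x + 0.5 * sign(x))
}

#' Derive a reproducible substream seed from a top-level seed and a label
#'
#' A single experiment seed fans out into independent substreams (cohort
#' generation, target selection, operator draws, ...) so that changing one
#' part of a configuration does not reshuffle unrelated random draws.
#'
#' @param seed integer top-level seed.
#' @param label character label naming the substream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 * 31 + h) %% 2147483646 + 1)
}

#' Age in completed years at a reference time
#'
#' Calendar-aware: the age increments on the anniversary of the birth date,
#' so a patient born 2060-06-01 is 39 on 2100-05-31 and 40 on 2100-06-01.
#' Negative ages (event before birth) are returned as negative values so
#' callers can treat them as temporal violations rather than clamping.
#'
#' @param dob,at `POSIXct` vectors (recycled to common length).
#' @return integer vector of completed years; `NA` where either input is `NA`.
#' @export
age_years <- function(dob, at) {
  n <- max(length(dob), length(at))
  dob <- rep_len(dob, n)
  at <- rep_len(at, n)
  d <- as.POSIXlt(dob, tz = "UTC")
  a <- as.POSIXlt(at, tz = "UTC")
  age <- a$year - d$year
  before_anniv <- (a$mon < d$mon) | (a$mon == d$mon & a$mday < d$mday)
  age - as.integer(before_anniv)
}

#' The age-group partition used by the noise model and code rulesets
#'
#' Four ordered intervals covering ages 0 to 124: infants `[0,1)`,
#' children `[1,12)`, teens and adults `[12,56)`, seniors `[56,124]`.
#'
#' @return a data.frame with columns `group`, `min`, `max` (`max` exclusive
#'   except for the final interval, which is closed at 124).
#' @export
age_groups <- function() {
  data.frame(
    group = c("infant", "child", "adult", "senior"),
    min = c(0, 1, 12, 56),
    max = c(1, 12, 56, 124),
    stringsAsFactors = FALSE
  )
}

#' Assign ages to age groups
#'
#' @param age numeric vector of ages in years.
#' @param partition an age-group partition as returned by [age_groups()].
#' @return character vector of group labels; ages outside `[0, 124]` are
#'   clamped into the nearest boundary group.
#' @export
age_group_of <- function(age, partition = age_groups()) {
  idx <- findInterval(age, partition$min)
  idx[idx < 1] <- 1L
  idx[idx > nrow(partition)] <- nrow(partition)
  out <- partition$group[idx]
  out[is.na(age)] <- NA_character_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
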