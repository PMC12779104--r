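# Turtle serialization of patient graphs.
#
# Writer and parser cover exactly the subset the package emits: prefixed
# names in the ehr:/ont: namespaces, plain literals, and literals typed
# xsd:dateTime, ont:code or xsd:string. Triple ordering in the output is
# deterministic (sorted), so a fixed graph always serializes to the same
# bytes.

TURTLE_PREFIXES <- c(
  "@prefix ehr: <http://example.org/ehr#> .",
  "@prefix ont: <http://example.org/ehr/ontology#> .",
  "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
  "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> ."
)

escape_turtle <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x
}

unescape_turtle <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  x <- gsub("\\\\", "\\", x, fixed = TRUE)
  x
}

datatype_suffix <- function(datatype) {
  ifelse(is.na(datatype) | datatype == "", "",
    paste0("^^", c(dateTime = "xsd:dateTime", code = "ont:code",
                   text = "xsd:string")[datatype]))
}

#' Serialize a patient graph to Turtle
#'
#' @param graphs a `kgqc_graph_set` (a whole cohort or one patient's graph).
#' @param path output `.ttl` file.
#' @return `path`, invisibly. An empty graph yields a valid Turtle document
#'   containing only prefix declarations.
#' @export
write_turtle <- function(graphs, path) {
  t <- graphs$triples
  lines <- if (nrow(t) == 0) character(0) else {
    obj <- ifelse(t$is_iri, t$object,
                  paste0("\"", escape_turtle(t$object), "\"", datatype_suffix(t$datatype)))
    sort(paste(t$subject, t$predicate, obj, "."))
  }
  writeLines(c(TURTLE_PREFIXES, "", lines), path)
  invisible(path)
}

#' Parse a Turtle file written by [write_turtle()]
#'
#' Restores the triple set exactly (round-trip set equality over subject,
#' predicate, object and datatype). Provenance is not serialized, so the
#' `source` column comes back `NA`; patient attribution is reconstructed
#' from `ofPatient`/`ofAdmission` links and patient-node IRIs where the
#' graph contains them.
#'
#' @param path a `.ttl` file.
#' @return a `kgqc_graph_set` with empty `sources`.
#' @export
read_turtle <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "@prefix")]
  if (length(lines) == 0) return(new_graph_set(empty_triples(), character(0)))

  m <- regmatches(lines, regexec(
    "^(\\S+) (\\S+) (?:\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^(\\S+))?|(\\S+)) \\.$",
    lines))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) stop("cannot parse Turtle line: ", lines[which(bad)[1]])

  subject <- vapply(m, `[[`, character(1), 2)
  predicate <- vapply(m, `[[`, character(1), 3)
  lit <- vapply(m, `[[`, character(1), 4)
  dt <- vapply(m, `[[`, character(1), 5)
  iri <- vapply(m, `[[`, character(1), 6)
  is_iri <- iri != ""
  object <- ifelse(is_iri, iri, unescape_turtle(lit))
  datatype <- ifelse(is_iri, NA_character_,
    c("xsd:dateTime" = "dateTime", "ont:code" = "code", "xsd:string" = "text")[dt])
  datatype[!is_iri & (dt == "")] <- ""

  triples <- data.frame(
    patient_id = NA_character_, subject = subject, predicate = predicate,
    object = object, is_iri = is_iri, datatype = unname(datatype),
    source = NA_character_, stringsAsFactors = FALSE
  )

  # reconstruct patient attribution from structural links
  adm_to_pat <- triples[triples$predicate == "ont:ofPatient", c("subject", "object")]
  pat_of <- function(node) {
    out <- rep(NA_character_, length(node))
    is_pat <- startsWith(node, "ehr:patient_")
    out[is_pat] <- sub("^ehr:patient_", "", node[is_pat])
    idx <- match(node, adm_to_pat$subject)
    hit <- !is.na(idx)
    out[hit] <- sub("^ehr:patient_", "", adm_to_pat$object[idx[hit]])
    out
  }
  triples$patient_id <- pat_of(triples$subject)
  ev_to_adm <- triples[triples$predicate == "ont:ofAdmission", c("subject", "object")]
  idx <- match(triples$subject, ev_to_adm$subject)
  hit <- !is.na(idx) & is.na(triples$patient_id)
  triples$patient_id[hit] <- pat_of(ev_to_adm$object[idx[hit]])

  new_graph_set(triples, character(0))
}
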