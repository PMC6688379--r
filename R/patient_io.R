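#' Tri-state symptom responses
#'
#' A patient answers each symptom of the catalog with one of exactly three
#' states: \code{PRESENT} ("Yes" in the entry mask), \code{ABSENT} ("No"),
#' or \code{UNTESTED} ("0", meaning not tested or not testable).  Symptoms
#' left out of a record are UNTESTED.
#'
#' @name responses
NULL

RESPONSE_LEVELS <- c("PRESENT", "ABSENT", "UNTESTED")

.token_to_response <- function(tokens, where = NULL) {
  t <- tolower(trimws(tokens))
  out <- rep(NA_character_, length(t))
  out[t == "yes"] <- "PRESENT"
  out[t == "no"] <- "ABSENT"
  out[t == "0" | t == ""] <- "UNTESTED"
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    stop(sprintf("unknown response token '%s'%s (expected Yes/No/0/empty)",
                 tokens[i], .at_cell(where, i)))
  }
  out
}

.response_to_token <- function(responses) {
  c(PRESENT = "Yes", ABSENT = "No", UNTESTED = "0")[responses]
}

#' Construct a patient record
#'
#' A patient record is the in-memory form of one entry-mask row: a named
#' vector of tri-state responses over the full symptom catalog.
#'
#' @param patient_id non-empty string.
#' @param symptoms the governing symptom catalog (character vector).
#' @param present,absent symptom ids answered "Yes" / "No"; everything else
#'   is UNTESTED.
#' @return object of class \code{patient_record}: list with `patient_id` and
#'   `responses` (named character vector over `symptoms`, values PRESENT /
#'   ABSENT / UNTESTED).
#' @export
patient_record <- function(patient_id, symptoms, present = character(),
                           absent = character()) {
  bad <- setdiff(c(present, absent), symptoms)
  if (length(bad))
    stop("symptom not in catalog: ", paste(bad, collapse = ", "))
  overlap <- intersect(present, absent)
  if (length(overlap))
    stop("symptom both present and absent: ", overlap[1])
  responses <- stats::setNames(rep("UNTESTED", length(symptoms)), symptoms)
  responses[present] <- "PRESENT"
  responses[absent] <- "ABSENT"
  structure(list(patient_id = as.character(patient_id),
                 responses = responses),
            class = "patient_record")
}

#' Read patient entry masks from a wide table
#'
#' One row per patient; a \code{patient_id} column plus one column per
#' symptom, with cells \code{Yes} (present), \code{No} (absent) or \code{0} /
#' empty (not tested).  Token matching is case-insensitive on read; columns
#' missing from the file are UNTESTED for every patient.  Column names must
#' all belong to the governing symptom catalog.
#'
#' @param source path to a CSV (default) or TSV mask file.
#' @param symptoms the governing symptom catalog (character vector), e.g.
#'   `example_disease_kb()$symptoms`.
#' @param sep field separator; guessed from the extension.
#' @return list of \code{patient_record}.
#' @export
read_patients <- function(source, symptoms, sep = NULL) {
  if (is.null(sep))
    sep <- if (is.character(source) && grepl("\\.tsv$", source, TRUE)) "\t" else ","
  tab <- utils::read.table(source, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           strip.white = TRUE, na.strings = character())
  if (!"patient_id" %in% names(tab)) stop("mask file needs a patient_id column")
  sym_cols <- setdiff(names(tab), "patient_id")
  bad <- setdiff(sym_cols, symptoms)
  if (length(bad))
    stop("symptom not in catalog: ", paste(bad, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    responses <- stats::setNames(rep("UNTESTED", length(symptoms)), symptoms)
    where <- sprintf("row %d ('%s'), column '%s'", i, tab$patient_id[i],
                     sym_cols)
    responses[sym_cols] <-
      .token_to_response(unlist(tab[i, sym_cols, drop = TRUE]), where)
    structure(list(patient_id = tab$patient_id[i], responses = responses),
              class = "patient_record")
  })
}

#' Write patient entry masks
#'
#' Emits the wide Yes/No/0 table read by [read_patients()], with canonical
#' token casing, one column per catalog symptom.  Reading the written file
#' back reproduces the records exactly.
#'
#' @param patients list of \code{patient_record} (sharing one catalog).
#' @param sink file path or connection.
#' @param sep field separator (comma default).
#' @return `sink`, invisibly.
#' @export
write_patients <- function(patients, sink, sep = ",") {
  stopifnot(length(patients) > 0)
  symptoms <- names(patients[[1]]$responses)
  tokens <- t(vapply(patients,
                     function(p) .response_to_token(p$responses[symptoms]),
                     character(length(symptoms))))
  df <- data.frame(patient_id = vapply(patients, `[[`, "", "patient_id"),
                   tokens, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("patient_id", symptoms)
  utils::write.table(df, sink, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(sink)
}

#' Construct a labeled patient
#'
#' Pairs an entry mask with the ground truth used for accuracy evaluation:
#' exactly one true disease, a (possibly empty) set of true brain zones, and
#' an evaluability flag for the zone tables (patients whose lesion site could
#' not be verified are excluded from zone accuracy accounting).
#'
#' @param record a \code{patient_record}.
#' @param true_disease single disease id.
#' @param true_zones character vector of zone ids (default none).
#' @param zones_evaluable logical; if FALSE the patient contributes to no
#'   zone tally.
#' @return object of class \code{labeled_patient}.
#' @export
labeled_patient <- function(record, true_disease, true_zones = character(),
                            zones_evaluable = TRUE) {
  stopifnot(inherits(record, "patient_record"),
            length(true_disease) == 1L, is.logical(zones_evaluable))
  structure(list(record = record, true_disease = as.character(true_disease),
                 true_zones = unique(as.character(true_zones)),
                 zones_evaluable = isTRUE(zones_evaluable)),
            class = "labeled_patient")
}

#' Read cohort ground-truth labels
#'
#' CSV with columns \code{patient_id}, \code{true_disease},
#' \code{true_zones} (semicolon-separated set, may be empty) and optionally
#' \code{zones_evaluable} (TRUE/FALSE, default TRUE).  Joined against a mask
#' file's records by patient_id to build labeled patients.
#'
#' @param source path to the label CSV.
#' @param patients list of \code{patient_record} to attach labels to.
#' @param diseases,zones governing catalogs used to validate the labels.
#' @return list of \code{labeled_patient}, in `patients` order.
#' @export
read_labels <- function(source, patients, diseases, zones) {
  tab <- utils::read.csv(source, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  need <- c("patient_id", "true_disease", "true_zones")
  if (!all(need %in% names(tab)))
    stop("label file needs columns: ", paste(need, collapse = ", "))
  ids <- vapply(patients, `[[`, "", "patient_id")
  missing <- setdiff(ids, tab$patient_id)
  if (length(missing))
    stop("no label row for patient: ", paste(missing, collapse = ", "))
  rows <- match(ids, tab$patient_id)
  lapply(seq_along(patients), function(i) {
    r <- rows[i]
    d <- tab$true_disease[r]
    if (!d %in% diseases)
      stop(sprintf("true_disease '%s' (patient '%s') not in disease catalog",
                   d, ids[i]))
    z <- strsplit(tab$true_zones[r], ";", fixed = TRUE)[[1]]
    z <- trimws(z[nzchar(trimws(z))])
    bad <- setdiff(z, zones)
    if (length(bad))
      stop(sprintf("true_zone '%s' (patient '%s') not in zone catalog",
                   bad[1], ids[i]))
    ev <- if ("zones_evaluable" %in% names(tab))
      !tolower(tab$zones_evaluable[r]) %in% c("false", "f", "0", "no")
    else TRUE
    labeled_patient(patients[[i]], d, z, ev)
  })
}

#' Write cohort ground-truth labels
#'
#' Inverse of [read_labels()]: emits patient_id, true_disease, true_zones
#' (semicolon-joined) and zones_evaluable columns.
#'
#' @param cohort list of \code{labeled_patient}.
#' @param sink file path or connection.
#' @return `sink`, invisibly.
#' @export
write_labels <- function(cohort, sink) {
  df <- data.frame(
    patient_id = vapply(cohort, function(p) p$record$patient_id, ""),
    true_disease = vapply(cohort, `[[`, "", "true_disease"),
    true_zones = vapply(cohort,
                        function(p) paste(p$true_zones, collapse = ";"), ""),
    zones_evaluable = vapply(cohort, `[[`, TRUE, "zones_evaluable"),
    stringsAsFactors = FALSE)
  utils::write.csv(df, sink, row.names = FALSE, quote = TRUE)
  invisible(sink)
}

#' @export
print.patient_record <- function(x, ...) {
  n <- table(factor(x$responses, RESPONSE_LEVELS))
  cat(sprintf("<patient_record> %s: %d present, %d absent, %d untested\n",
              x$patient_id, n[["PRESENT"]], n[["ABSENT"]], n[["UNTESTED"]]))
  invisible(x)
}
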