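#' Score one patient against a knowledge base
#'
#' The additive scoring rule at the heart of the algorithm: each entity's
#' score is the sum, over the symptoms the patient PRESENTs, of that
#' entity's linkage weight for the symptom.  A "Yes" on a highly related
#' (HR, +2) symptom adds two points instead of one; a "Yes" on a negatively
#' linked symptom subtracts points.  ABSENT and UNTESTED responses
#' contribute exactly zero — a "No" never subtracts.
#'
#' @param patient a \code{patient_record} whose symptoms all belong to the
#'   knowledge base's catalog.
#' @param kb a \code{knowledge_base}.
#' @return object of class \code{score_vector}: list with `entity_kind` and
#'   `scores`, a named integer vector in knowledge-base entity order.
#' @export
score_patient <- function(patient, kb) {
  stopifnot(inherits(patient, "patient_record"),
            inherits(kb, "knowledge_base"))
  bad <- setdiff(names(patient$responses), kb$symptoms)
  if (length(bad))
    stop("symptom not in catalog: ", paste(bad, collapse = ", "))
  present <- names(patient$responses)[patient$responses == "PRESENT"]
  ind <- stats::setNames(integer(length(kb$symptoms)), kb$symptoms)
  ind[present] <- 1L
  scores <- as.integer(kb$weights %*% ind)
  structure(list(entity_kind = kb$entity_kind,
                 scores = stats::setNames(scores, kb$entities)),
            class = "score_vector")
}

#' Score a cohort of patients
#'
#' @param patients list of \code{patient_record}.
#' @param kb a \code{knowledge_base}.
#' @return integer matrix, patients x entities, rownames = patient ids.
#' @export
score_cohort <- function(patients, kb) {
  m <- t(vapply(patients, function(p) score_patient(p, kb)$scores,
                integer(length(kb$entities))))
  rownames(m) <- vapply(patients, `[[`, "", "patient_id")
  colnames(m) <- kb$entities
  m
}

#' Rank entities by score
#'
#' Entities sorted by score descending, catalog order breaking ties; the
#' ranked list mirrors the output list shown to the user.
#'
#' @param scores a \code{score_vector}.
#' @return data.frame with columns `entity`, `score`.
#' @export
rank_scores <- function(scores) {
  ord <- order(-scores$scores, seq_along(scores$scores))
  data.frame(entity = names(scores$scores)[ord],
             score = as.integer(scores$scores[ord]),
             stringsAsFactors = FALSE)
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> (%s)\n", x$entity_kind))
  print(rank_scores(x), row.names = FALSE)
  invisible(x)
}
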