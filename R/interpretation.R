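#' Interpret disease scores as a diagnostic shortlist
#'
#' Applies the three disease result rules to a score vector:
#' \enumerate{
#'   \item Dominance: if one disease scores at least three points higher than
#'     every other disease, it is the only result (`dominant = TRUE`).
#'   \item Otherwise the result consists of the diseases holding the two
#'     highest score ranks — every disease whose score is at least the
#'     second-ranked score, so ties expand the list (two diseases tied at the
#'     top fill both slots by themselves; a tie at the second rank pulls in
#'     all its members).
#'   \item If that shortlist has more than five diseases the output is
#'     considered not helpful: `not_helpful = TRUE` and the shortlist is
#'     empty.
#' }
#'
#' No score threshold is applied to diseases: a top score of zero or below
#' still forms a shortlist unless the five-disease cap fires.
#'
#' @param scores a \code{score_vector} of kind \code{"DISEASE"}.
#' @return object of class \code{interpretation_result}: list with
#'   `entity_kind`, `shortlist` (character, empty iff not helpful),
#'   `not_helpful`, `dominant`, and the input `scores`.
#' @export
interpret_disease_scores <- function(scores) {
  stopifnot(inherits(scores, "score_vector"))
  if (scores$entity_kind != "DISEASE")
    stop("expected a DISEASE score vector, got ", scores$entity_kind)
  s <- scores$scores
  ranked <- rank_scores(scores)
  if (length(s) > 1L && ranked$score[1] >= max(s[names(s) != ranked$entity[1]]) + 3L)
    return(.interp("DISEASE", ranked$entity[1], dominant = TRUE,
                   scores = scores))
  cutoff <- if (nrow(ranked) >= 2L) ranked$score[2] else ranked$score[1]
  shortlist <- ranked$entity[ranked$score >= cutoff]
  if (length(shortlist) > 5L)
    return(.interp("DISEASE", character(), not_helpful = TRUE,
                   scores = scores))
  .interp("DISEASE", shortlist, scores = scores)
}

#' Interpret brain-zone scores as a localization shortlist
#'
#' Applies the three zone result rules, which differ from the disease rules:
#' \enumerate{
#'   \item The result consists of the zones holding the two highest score
#'     ranks, ties expanding the list as for diseases.
#'   \item Any score of one point or less is ignored — unless one point is
#'     the highest existing score, in which case the one-point zones stand.
#'   \item More than four zones in the result is not helpful.
#' }
#' If no zone survives the filter (highest score is zero or negative) the
#' result is likewise not helpful.  There is no dominance rule for zones.
#'
#' @param scores a \code{score_vector} of kind \code{"BRAIN_ZONE"}.
#' @return An \code{interpretation_result} (see
#'   [interpret_disease_scores()]); `dominant` is always FALSE for zones.
#' @export
interpret_zone_scores <- function(scores) {
  stopifnot(inherits(scores, "score_vector"))
  if (scores$entity_kind != "BRAIN_ZONE")
    stop("expected a BRAIN_ZONE score vector, got ", scores$entity_kind)
  s <- scores$scores
  top <- max(s)
  keep <- if (top == 1L) s == 1L else s > 1L
  if (!any(keep))
    return(.interp("BRAIN_ZONE", character(), not_helpful = TRUE,
                   scores = scores))
  ranked <- rank_scores(scores)
  ranked <- ranked[keep[ranked$entity], , drop = FALSE]
  cutoff <- if (nrow(ranked) >= 2L) ranked$score[2] else ranked$score[1]
  shortlist <- ranked$entity[ranked$score >= cutoff]
  if (length(shortlist) > 4L)
    return(.interp("BRAIN_ZONE", character(), not_helpful = TRUE,
                   scores = scores))
  .interp("BRAIN_ZONE", shortlist, scores = scores)
}

#' Interpret a score vector under the rules for its entity kind
#'
#' @param scores a \code{score_vector}.
#' @return An \code{interpretation_result}.
#' @export
interpret_scores <- function(scores) {
  if (scores$entity_kind == "DISEASE") interpret_disease_scores(scores)
  else interpret_zone_scores(scores)
}

.interp <- function(entity_kind, shortlist, not_helpful = FALSE,
                    dominant = FALSE, scores = NULL) {
  structure(list(entity_kind = entity_kind,
                 shortlist = as.character(shortlist),
                 not_helpful = not_helpful,
                 dominant = dominant,
                 scores = scores),
            class = "interpretation_result")
}

#' @export
print.interpretation_result <- function(x, ...) {
  kind <- if (x$entity_kind == "DISEASE") "diseases" else "brain zones"
  if (x$not_helpful) {
    cat(sprintf("<interpretation_result> %s: not helpful (shortlist too long)\n",
                kind))
  } else {
    cat(sprintf("<interpretation_result> %s: %s%s\n", kind,
                paste(x$shortlist, collapse = ", "),
                if (x$dominant) " [dominant]" else ""))
  }
  invisible(x)
}
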