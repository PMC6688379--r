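# Independent reference implementations used as oracles.  Deliberately
# written as literal, loop-heavy transcriptions of the rules, sharing no
# code with the package internals.

# code -> weight, hand-copied table
oracle_code_map <- list(NEV = -3, OTTD = -2, UL = -1, N = 0, Y = 1, R = 1,
                        HR = 2)

# brute-force double-loop scoring: for every entity, walk every symptom
oracle_score <- function(responses, weights) {
  out <- numeric(nrow(weights))
  names(out) <- rownames(weights)
  for (e in rownames(weights)) {
    acc <- 0
    for (s in colnames(weights)) {
      if (!is.na(responses[s]) && responses[s] == "PRESENT")
        acc <- acc + weights[e, s]
    }
    out[e] <- acc
  }
  out
}

# literal rule-by-rule disease interpretation on a named score vector
oracle_interpret_disease <- function(s) {
  stopifnot(length(s) >= 2)
  # rule 3 first: sole result if >= 3 above every other score
  for (e in names(s)) {
    if (all(s[e] >= s[setdiff(names(s), e)] + 3))
      return(list(shortlist = e, not_helpful = FALSE, dominant = TRUE))
  }
  # rule 1: the two highest score ranks, ties expand
  sorted <- sort(s, decreasing = TRUE)
  second <- sorted[2]
  short <- names(s)[s >= second]
  # keep score-descending order, original order within ties
  short <- short[order(-s[short], match(short, names(s)))]
  # rule 2: more than five diseases -> not helpful
  if (length(short) > 5)
    return(list(shortlist = character(), not_helpful = TRUE,
                dominant = FALSE))
  list(shortlist = short, not_helpful = FALSE, dominant = FALSE)
}

# literal rule-by-rule zone interpretation
oracle_interpret_zone <- function(s) {
  # rule 2: ignore scores of one point or less, unless 1 is the top score
  if (max(s) == 1) surv <- s[s == 1]
  else surv <- s[s >= 2]
  if (length(surv) == 0)
    return(list(shortlist = character(), not_helpful = TRUE))
  sorted <- sort(surv, decreasing = TRUE)
  second <- if (length(sorted) >= 2) sorted[2] else sorted[1]
  short <- names(surv)[surv >= second]
  short <- short[order(-s[short], match(short, names(s)))]
  if (length(short) > 4)
    return(list(shortlist = character(), not_helpful = TRUE))
  list(shortlist = short, not_helpful = FALSE)
}

# case-by-case confusion increments for one disease result
oracle_tally_disease <- function(truth, shortlist, not_helpful, entities) {
  inc <- matrix(0, length(entities), 4,
                dimnames = list(entities, c("TP", "FP", "TN", "FN")))
  for (e in entities) {
    if (not_helpful) {
      if (e == truth) inc[e, "FN"] <- 1 else inc[e, "FP"] <- 1
    } else if (e == truth) {
      if (e %in% shortlist) inc[e, "TP"] <- 1 else inc[e, "FN"] <- 1
    } else {
      if (e %in% shortlist) inc[e, "FP"] <- 1 else inc[e, "TN"] <- 1
    }
  }
  inc
}

# multi-label zone increments
oracle_tally_zone <- function(truth, shortlist, not_helpful, entities) {
  inc <- matrix(0, length(entities), 4,
                dimnames = list(entities, c("TP", "FP", "TN", "FN")))
  for (e in entities) {
    is_true <- e %in% truth
    in_list <- !not_helpful && e %in% shortlist
    if (not_helpful) {
      if (is_true) inc[e, "FN"] <- 1 else inc[e, "FP"] <- 1
    } else if (is_true && in_list) inc[e, "TP"] <- 1
    else if (is_true) inc[e, "FN"] <- 1
    else if (in_list) inc[e, "FP"] <- 1
    else inc[e, "TN"] <- 1
  }
  inc
}

# random patient record over a symptom catalog
random_record <- function(id, symptoms,
                          probs = c(PRESENT = 0.3, ABSENT = 0.4,
                                    UNTESTED = 0.3)) {
  r <- sample(names(probs), length(symptoms), replace = TRUE, prob = probs)
  names(r) <- symptoms
  structure(list(patient_id = id, responses = r), class = "patient_record")
}

# random toy knowledge base
random_kb <- function(n_entities, n_symptoms, entity_kind = "DISEASE") {
  pool <- if (entity_kind == "DISEASE") -3:4 else 0:4
  w <- matrix(sample(pool, n_entities * n_symptoms, replace = TRUE,
                     prob = c(rep(0.05, length(pool) - 5),
                              0.5, 0.2, 0.15, 0.05, 0.05)),
              n_entities, n_symptoms,
              dimnames = list(paste0("E", seq_len(n_entities)),
                              paste0("s", seq_len(n_symptoms))))
  knowledge_base(w, entity_kind)
}

make_score_vector <- function(scores, entity_kind = "DISEASE") {
  structure(list(entity_kind = entity_kind,
                 scores = stats::setNames(as.integer(scores),
                                          names(scores))),
            class = "score_vector")
}
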