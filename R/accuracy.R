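#' Wald (asymptotic normal) binomial confidence interval
#'
#' The 95% confidence limits used throughout the accuracy tables: for k
#' successes in n trials, p = k/n and the interval is
#' p +/- z * sqrt(p(1-p)/n) with z the two-sided normal quantile
#' (1.959964 at the default 95% level), truncated to [0, 1].  The interval
#' degenerates to a point at p = 0 or p = 1, matching the printed
#' 1.000-1.000 rows for perfect sensitivity.
#'
#' @param k number of successes, 0 <= k <= n.
#' @param n number of trials; if 0 the interval is undefined and `c(NA, NA)`
#'   is returned.
#' @param conf confidence level (default 0.95).
#' @return numeric `c(low, high)`, un-rounded proportions.
#' @export
wald_ci <- function(k, n, conf = 0.95) {
  stopifnot(length(k) == 1L, length(n) == 1L, n >= 0, k >= 0, k <= max(n, 0))
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  hw <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - hw), min(1, p + hw))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention of the
#' printed accuracy tables, rather than R's round-half-even.
#'
#' @param x numeric vector (non-negative in this package's use).
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

.empty_tally <- function(entities) {
  m <- matrix(0L, nrow = length(entities), ncol = 4L,
              dimnames = list(entities, c("TP", "FP", "TN", "FN")))
  m
}

#' Tally one disease result into per-entity confusion counts
#'
#' The shortlist confusion accounting: if the true disease appears in the
#' result shortlist it is a true positive, and every disease absent from the
#' shortlist a true negative; every incorrect shortlist member is a false
#' positive.  If the true disease is missing from a (non-empty) shortlist it
#' is a false negative.  A not-helpful result counts as a false negative for
#' the true disease and a false positive for all the other diseases.
#'
#' @param truth the patient's true disease id.
#' @param result an \code{interpretation_result} (kind DISEASE).
#' @param entities the disease catalog.
#' @return integer matrix entities x c(TP, FP, TN, FN) of 0/1 increments;
#'   each row sums to 1.
#' @export
tally_disease_result <- function(truth, result, entities) {
  if (!truth %in% entities) stop("truth '", truth, "' not in catalog")
  m <- .empty_tally(entities)
  if (result$not_helpful) {
    m[truth, "FN"] <- 1L
    m[setdiff(entities, truth), "FP"] <- 1L
    return(m)
  }
  sl <- result$shortlist
  if (truth %in% sl) m[truth, "TP"] <- 1L else m[truth, "FN"] <- 1L
  m[setdiff(sl, truth), "FP"] <- 1L
  m[setdiff(entities, union(sl, truth)), "TN"] <- 1L
  m
}

#' Tally one brain-zone result into per-entity confusion counts
#'
#' The multi-label extension of the disease accounting: zone truth is a set
#' (a lesion can span several zones).  Each true zone found in the shortlist
#' is a true positive and each true zone missed a false negative; each
#' shortlist zone that is not true is a false positive; zones in neither are
#' true negatives.  A not-helpful result is a false negative for every true
#' zone and a false positive for every other zone.
#'
#' @param truth_zones character vector of true zone ids (possibly empty).
#' @param result an \code{interpretation_result} (kind BRAIN_ZONE).
#' @param entities the zone catalog.
#' @return integer matrix entities x c(TP, FP, TN, FN); each row sums to 1.
#' @export
tally_zone_result <- function(truth_zones, result, entities) {
  bad <- setdiff(truth_zones, entities)
  if (length(bad)) stop("truth zone '", bad[1], "' not in catalog")
  m <- .empty_tally(entities)
  if (result$not_helpful) {
    m[truth_zones, "FN"] <- 1L
    m[setdiff(entities, truth_zones), "FP"] <- 1L
    return(m)
  }
  sl <- result$shortlist
  m[intersect(truth_zones, sl), "TP"] <- 1L
  m[setdiff(truth_zones, sl), "FN"] <- 1L
  m[setdiff(sl, truth_zones), "FP"] <- 1L
  m[setdiff(entities, union(sl, truth_zones)), "TN"] <- 1L
  m
}

#' Per-entity sensitivity/specificity table with Wald confidence intervals
#'
#' Turns accumulated confusion tallies into the standard accuracy report:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), percentages rounded
#' half-up to one decimal, and 95% Wald interval bounds rounded half-up to
#' three decimals.  Rows are emitted even when a denominator is zero, with
#' the percentage and interval left NA.
#'
#' @param tallies integer matrix entities x c(TP, FP, TN, FN), e.g. a sum of
#'   [tally_disease_result()] increments, or a data.frame with those columns
#'   and an `entity` column.
#' @param conf confidence level for the Wald intervals.
#' @return data.frame with columns entity, TP, FP, TN, FN, sens_num,
#'   sens_den, sensitivity_pct, sens_ci_low, sens_ci_high, spec_num,
#'   spec_den, specificity_pct, spec_ci_low, spec_ci_high.
#' @export
accuracy_table <- function(tallies, conf = 0.95) {
  if (is.data.frame(tallies)) {
    m <- as.matrix(tallies[, c("TP", "FP", "TN", "FN")])
    rownames(m) <- tallies$entity
    tallies <- m
  }
  ent <- rownames(tallies)
  one <- function(k, n) {
    ci <- wald_ci(k, n, conf)
    c(pct = if (n > 0) round_half_up(100 * k / n, 1) else NA_real_,
      low = round_half_up(ci[1], 3), high = round_half_up(ci[2], 3))
  }
  sens <- t(vapply(ent, function(e)
    one(tallies[e, "TP"], tallies[e, "TP"] + tallies[e, "FN"]), numeric(3)))
  spec <- t(vapply(ent, function(e)
    one(tallies[e, "TN"], tallies[e, "TN"] + tallies[e, "FP"]), numeric(3)))
  data.frame(entity = unname(ent),
             TP = unname(tallies[, "TP"]), FP = unname(tallies[, "FP"]),
             TN = unname(tallies[, "TN"]), FN = unname(tallies[, "FN"]),
             sens_num = unname(tallies[, "TP"]),
             sens_den = unname(tallies[, "TP"] + tallies[, "FN"]),
             sensitivity_pct = unname(sens[, "pct"]),
             sens_ci_low = unname(sens[, "low"]),
             sens_ci_high = unname(sens[, "high"]),
             spec_num = unname(tallies[, "TN"]),
             spec_den = unname(tallies[, "TN"] + tallies[, "FP"]),
             specificity_pct = unname(spec[, "pct"]),
             spec_ci_low = unname(spec[, "low"]),
             spec_ci_high = unname(spec[, "high"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Evaluate a labeled cohort end to end
#'
#' Runs the whole validation pipeline: scores every patient against the
#' disease and zone knowledge bases, applies the interpretation rules,
#' accumulates the shortlist confusion tallies, and returns the two accuracy
#' tables.  Patients flagged `zones_evaluable = FALSE` contribute to the
#' disease table only.  Deterministic and invariant to patient order.
#'
#' @param cohort list of \code{labeled_patient}.
#' @param disease_kb,zone_kb the two knowledge bases (kinds DISEASE and
#'   BRAIN_ZONE).
#' @param conf confidence level for the Wald intervals.
#' @return list with elements `disease` and `zone`, each an
#'   [accuracy_table()] data.frame.
#' @export
evaluate_cohort <- function(cohort, disease_kb, zone_kb, conf = 0.95) {
  stopifnot(disease_kb$entity_kind == "DISEASE",
            zone_kb$entity_kind == "BRAIN_ZONE")
  dt <- .empty_tally(disease_kb$entities)
  zt <- .empty_tally(zone_kb$entities)
  for (p in cohort) {
    dres <- interpret_disease_scores(score_patient(p$record, disease_kb))
    dt <- dt + tally_disease_result(p$true_disease, dres,
                                    disease_kb$entities)
    if (p$zones_evaluable) {
      zres <- interpret_zone_scores(score_patient(p$record, zone_kb))
      zt <- zt + tally_zone_result(p$true_zones, zres, zone_kb$entities)
    }
  }
  list(disease = accuracy_table(dt, conf), zone = accuracy_table(zt, conf))
}

#' Published validation-cohort accuracy counts
#'
#' The numerator/denominator pairs reported for the algorithm's 104-patient
#' validation cohort: per-disease and per-zone sensitivity (TP / diseased)
#' and specificity (TN / non-diseased) fractions.  From these counts every
#' published percentage and 95% Wald confidence bound can be recomputed with
#' [accuracy_table()]; the underlying patient-level data are not public.
#' Zone denominators reflect multi-label zone truth (a patient may have
#' several affected zones) and the exclusion of 7 of the 104 patients from
#' zone evaluation (paired zone denominators sum to 97).
#'
#' @return data.frame with columns entity, kind (DISEASE/BRAIN_ZONE),
#'   sens_num, sens_den, spec_num, spec_den.
#' @export
reference_validation_counts <- function() {
  d <- rbind(
    c("NPC",                       10, 10, 71, 94),
    c("inflammatory encephalitis",  5,  5, 65, 99),
    c("tumor",                      3,  4, 82, 100),
    c("infarction/hemorrhage",     11, 11, 82, 93),
    c("MS",                         8, 10, 63, 94),
    c("Parkinsonian syndromes",     8, 10, 89, 94),
    c("PSP",                        8, 10, 83, 94),
    c("Wernicke encephalopathy",    5,  5, 89, 99),
    c("AT",                         3,  5, 86, 99),
    c("AOA1/2",                     4,  4, 78, 100),
    c("GD3",                        8, 10, 86, 94),
    c("Huntington chorea",          4,  5, 94, 99),
    c("cerebellar syndromes",      10, 10, 79, 94),
    c("TS",                         5,  5, 78, 99))
  z <- rbind(
    c("midbrain",                 30, 39, 30, 58),
    c("pons",                     28, 34, 34, 63),
    c("medulla oblongata",         4,  4, 78, 93),
    c("flocculus/paraflocculus",  34, 54, 25, 43),
    c("vermis/fastigial nucleus", 14, 54, 34, 43),
    c("nodulus/uvula",             0, 54, 42, 43),
    c("basal ganglia",            22, 28, 57, 69),
    c("frontoparietal cortex",     5, 11, 85, 86))
  out <- data.frame(
    entity = c(d[, 1], z[, 1]),
    kind = rep(c("DISEASE", "BRAIN_ZONE"), c(nrow(d), nrow(z))),
    sens_num = as.integer(c(d[, 2], z[, 2])),
    sens_den = as.integer(c(d[, 3], z[, 3])),
    spec_num = as.integer(c(d[, 4], z[, 4])),
    spec_den = as.integer(c(d[, 5], z[, 5])),
    stringsAsFactors = FALSE)
  out
}

#' Recompute the published accuracy statistics from the reference counts
#'
#' Applies [accuracy_table()]'s percentage and Wald-interval arithmetic to
#' the [reference_validation_counts()] fractions, reproducing the published
#' sensitivity/specificity percentages and 95% CI bounds exactly.
#'
#' @param counts a data.frame shaped like [reference_validation_counts()].
#' @return the counts data.frame with sensitivity_pct, sens_ci_low,
#'   sens_ci_high, specificity_pct, spec_ci_low, spec_ci_high appended.
#' @export
reference_accuracy_table <- function(counts = reference_validation_counts()) {
  tallies <- .empty_tally(counts$entity)
  tallies[, "TP"] <- counts$sens_num
  tallies[, "FN"] <- counts$sens_den - counts$sens_num
  tallies[, "TN"] <- counts$spec_num
  tallies[, "FP"] <- counts$spec_den - counts$spec_num
  tab <- accuracy_table(tallies)
  cbind(counts,
        tab[, c("sensitivity_pct", "sens_ci_low", "sens_ci_high",
                "specificity_pct", "spec_ci_low", "spec_ci_high")])
}
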