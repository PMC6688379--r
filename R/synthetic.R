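#' Configuration for the synthetic cohort generator
#'
#' The generator emulates disease-conditional symptom profiles.  For a
#' patient whose true disease is d, each symptom is drawn independently
#' (Bernoulli) PRESENT with a probability set by its linkage weight to d:
#' \itemize{
#'   \item weight >= +2 (highly related): `p_typical + p_hr_boost`
#'   \item weight == +1 (related): `p_typical`
#'   \item weight == 0 (unlinked): `p_spurious` (noise)
#'   \item weight <= -1 (negatively linked): never present
#' }
#' and afterwards each response is independently masked to UNTESTED with
#' probability `p_untested`, emulating incomplete examinations.
#'
#' The default per-disease counts reproduce the size and disease mix of a
#' 104-patient validation cohort (e.g. 10 NPC, 5 AT, 10 GD3, ...); the
#' default probabilities describe a moderately noisy but informative
#' examination (80% penetrance of typical signs, +15% for highly related
#' ones, 5% spurious signs, 20% of answers untested).
#'
#' @param counts named integer vector/list, disease -> number of patients.
#' @param p_typical probability a +1-linked symptom is present.
#' @param p_hr_boost additive bump for symptoms linked +2 or stronger;
#'   `p_typical + p_hr_boost` must be <= 1.
#' @param p_spurious probability an unlinked (weight-0) symptom is present.
#' @param p_untested probability any response is masked to UNTESTED.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the config including the seed.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(counts = default_cohort_counts(),
                          p_typical = 0.8, p_hr_boost = 0.15,
                          p_spurious = 0.05, p_untested = 0.2,
                          seed = 1L) {
  probs <- c(p_typical = p_typical, p_hr_boost = p_hr_boost,
             p_spurious = p_spurious, p_untested = p_untested)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must be in [0, 1]; got ",
         paste(sprintf("%s=%g", names(probs), probs), collapse = ", "))
  if (p_typical + p_hr_boost > 1)
    stop("p_typical + p_hr_boost must be <= 1")
  counts <- unlist(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("`counts` must be named by disease")
  if (any(counts < 0)) stop("patient counts must be >= 0")
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 p_typical = p_typical, p_hr_boost = p_hr_boost,
                 p_spurious = p_spurious, p_untested = p_untested,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default per-disease patient counts
#'
#' The disease mix of the reference 104-patient validation cohort.
#'
#' @return named integer vector, disease -> count (sums to 104).
#' @export
default_cohort_counts <- function() {
  c("NPC" = 10L, "AT" = 5L, "AOA1/2" = 4L, "GD3" = 10L, "TS" = 5L,
    "Wernicke encephalopathy" = 5L, "Huntington chorea" = 5L, "MS" = 10L,
    "Parkinsonian syndromes" = 10L, "PSP" = 10L, "tumor" = 4L,
    "infarction/hemorrhage" = 11L, "inflammatory encephalitis" = 5L,
    "cerebellar syndromes" = 10L)
}

# Per-patient RNG substream: a fixed affine counter scheme on the global
# seed, kept below 2^31, so patient i's draws do not depend on how many
# draws earlier patients consumed.
.patient_seed <- function(seed, i) {
  (abs(seed) %% 1000003L) * 2011L + i * 7919L
}

#' Generate a labeled synthetic cohort
#'
#' Draws patients disease by disease under the Bernoulli model described in
#' [cohort_config()]; ground-truth zone labels come from `zone_map`.
#' Identical config (including seed) yields byte-identical cohorts: each
#' patient uses its own RNG substream derived from the seed and the patient
#' index, and symptoms are visited in fixed catalog order.
#'
#' @param disease_kb a \code{knowledge_base} of kind DISEASE; diseases named
#'   in `config$counts` must all be in its entity catalog.
#' @param zone_map named list disease -> character vector of true zones.
#' @param config a \code{cohort_config}.
#' @return list of \code{labeled_patient} (class \code{synthetic_cohort},
#'   with the config attached as attribute `config`).
#' @export
generate_cohort <- function(disease_kb, zone_map, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(disease_kb, "knowledge_base"),
            disease_kb$entity_kind == "DISEASE")
  bad <- setdiff(names(config$counts), disease_kb$entities)
  if (length(bad)) stop("disease not in KB catalog: ", bad[1])
  symptoms <- disease_kb$symptoms
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  cohort <- list()
  idx <- 0L
  for (d in names(config$counts)) {
    w <- disease_kb$weights[d, ]
    p_present <- ifelse(w >= 2L, config$p_typical + config$p_hr_boost,
                 ifelse(w == 1L, config$p_typical,
                 ifelse(w == 0L, config$p_spurious, 0)))
    zones <- zone_map[[d]]
    if (is.null(zones)) zones <- character()
    for (k in seq_len(config$counts[[d]])) {
      idx <- idx + 1L
      set.seed(.patient_seed(config$seed, idx))
      present <- stats::runif(length(symptoms)) < p_present
      untested <- stats::runif(length(symptoms)) < config$p_untested
      responses <- ifelse(untested, "UNTESTED",
                          ifelse(present, "PRESENT", "ABSENT"))
      names(responses) <- symptoms
      rec <- structure(list(patient_id = sprintf("synth-%03d", idx),
                            responses = responses),
                       class = "patient_record")
      cohort[[idx]] <- labeled_patient(rec, d, zones)
    }
  }
  structure(cohort, class = c("synthetic_cohort", "list"), config = config)
}

#' Sweep spurious-symptom noise and measure accuracy degradation
#'
#' A small experiment harness around the full pipeline: for each value of
#' `p_spurious` in the grid it generates `replicates` fresh cohorts (seeds
#' derived from the base config seed), evaluates each against the two
#' knowledge bases, and averages per-disease sensitivity and specificity
#' over the replicates.
#'
#' @param disease_kb,zone_kb the two knowledge bases.
#' @param zone_map disease -> true zones, as for [generate_cohort()].
#' @param base_config a \code{cohort_config}; its `p_spurious` is overridden
#'   by each grid value.
#' @param p_spurious_grid numeric vector of noise levels in [0, 1].
#' @param replicates number of cohorts per noise level (0 gives an empty
#'   table).
#' @return data.frame with columns p_spurious, entity, mean_sensitivity_pct,
#'   mean_specificity_pct (means over replicates, NA-dropped).
#' @export
noise_sweep <- function(disease_kb, zone_kb, zone_map,
                        base_config = cohort_config(),
                        p_spurious_grid = c(0, 0.1, 0.25, 0.5),
                        replicates = 20L) {
  if (any(p_spurious_grid < 0 | p_spurious_grid > 1))
    stop("p_spurious_grid values must be in [0, 1]")
  rows <- list()
  for (p in p_spurious_grid) {
    sens <- spec <- NULL
    for (r in seq_len(replicates)) {
      cfg <- cohort_config(counts = base_config$counts,
                           p_typical = base_config$p_typical,
                           p_hr_boost = base_config$p_hr_boost,
                           p_spurious = p,
                           p_untested = base_config$p_untested,
                           seed = (base_config$seed + 104729L * r) %% 2147483647L)
      cohort <- generate_cohort(disease_kb, zone_map, cfg)
      tab <- evaluate_cohort(cohort, disease_kb, zone_kb)$disease
      sens <- rbind(sens, tab$sensitivity_pct)
      spec <- rbind(spec, tab$specificity_pct)
    }
    if (is.null(sens)) next
    rows[[length(rows) + 1L]] <- data.frame(
      p_spurious = p,
      entity = disease_kb$entities,
      mean_sensitivity_pct = colMeans(sens, na.rm = TRUE),
      mean_specificity_pct = colMeans(spec, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(p_spurious = numeric(), entity = character(),
                      mean_sensitivity_pct = numeric(),
                      mean_specificity_pct = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
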