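#' The reference symptom catalog
#'
#' Sixty neurological and ocular motor signs and symptoms, split into the two
#' major groups used by the entry mask: general neurological findings and
#' ocular motor findings.
#'
#' @return data.frame with columns `symptom` and `group`
#'   (\code{"GENERAL"} / \code{"OCULOMOTOR"}).
#' @export
example_symptom_catalog <- function() {
  general <- c(
    "ataxia", "dysarthria", "dysphagia", "paresis", "resting tremor",
    "intention tremor", "rigidity", "bradykinesia", "chorea", "dystonia",
    "cognitive decline", "psychiatric symptoms", "epileptic seizures",
    "polyneuropathy", "telangiectasia", "splenomegaly", "confusion",
    "falls", "sensory deficits", "headache", "acute onset")
  oculomotor <- c(
    "vertical saccade palsy", "horizontal saccade palsy",
    "vertical supranuclear gaze palsy", "horizontal supranuclear gaze palsy",
    "internuclear ophthalmoplegia, aged < 60 years",
    "internuclear ophthalmoplegia, aged >= 60 years",
    "oculomotor apraxia", "slowed vertical saccades",
    "slowed horizontal saccades", "hypometric saccades",
    "hypermetric saccades", "saccadic smooth pursuit",
    "gaze-evoked nystagmus", "downbeat nystagmus", "upbeat nystagmus",
    "rebound nystagmus", "spontaneous nystagmus", "fixation nystagmus",
    "head-shaking nystagmus", "positional nystagmus",
    "periodic alternating nystagmus", "convergence-retraction nystagmus",
    "square wave jerks", "macrosaccadic oscillations", "saccadic intrusions",
    "ocular flutter", "opsoclonus", "convergence impairment", "ptosis",
    "diplopia", "skew deviation", "ocular tilt reaction",
    "impaired VOR suppression", "bilateral vestibulopathy",
    "head impulse test positive", "optokinetic nystagmus impairment",
    "vertical gaze-holding deficit", "lid retraction", "reduced blink rate")
  data.frame(
    symptom = c(general, oculomotor),
    group = rep(c("GENERAL", "OCULOMOTOR"),
                c(length(general), length(oculomotor))),
    stringsAsFactors = FALSE)
}

#' The reference disease catalog
#'
#' The fourteen candidate diseases of the differential: Niemann-Pick type C,
#' ataxia teleangiectasia, ataxia with oculomotor apraxia 1/2, Gaucher
#' disease type 3, Tay-Sachs, Wernicke encephalopathy, Huntington chorea,
#' multiple sclerosis, Parkinsonian syndromes, progressive supranuclear
#' palsy, tumor, infarction/hemorrhage, inflammatory encephalitis, and the
#' various cerebellar syndromes.
#'
#' @return character vector of 14 disease identifiers.
#' @export
example_disease_catalog <- function() {
  c("NPC", "AT", "AOA1/2", "GD3", "TS", "Wernicke encephalopathy",
    "Huntington chorea", "MS", "Parkinsonian syndromes", "PSP", "tumor",
    "infarction/hemorrhage", "inflammatory encephalitis",
    "cerebellar syndromes")
}

#' The reference brain-zone catalog
#'
#' The eight zones whose lesions produce central ocular motor disorders:
#' midbrain, pons, medulla oblongata, basal ganglia, frontoparietal cortex,
#' and the three cerebellar regions flocculus/paraflocculus, vermis/fastigial
#' nucleus and nodulus/uvula.
#'
#' @return character vector of 8 zone identifiers.
#' @export
example_zone_catalog <- function() {
  c("midbrain", "pons", "medulla oblongata", "basal ganglia",
    "frontoparietal cortex", "flocculus/paraflocculus",
    "vermis/fastigial nucleus", "nodulus/uvula")
}

.kb_from_signatures <- function(entities, entity_kind, sig) {
  cat_df <- example_symptom_catalog()
  w <- matrix(0L, nrow = length(entities), ncol = nrow(cat_df),
              dimnames = list(entities, cat_df$symptom))
  for (e in names(sig)) {
    for (wt in names(sig[[e]])) {
      syms <- sig[[e]][[wt]]
      bad <- setdiff(syms, cat_df$symptom)
      if (length(bad)) stop("unknown symptom in signature: ", bad[1])
      w[e, syms] <- as.integer(wt)
    }
  }
  knowledge_base(w, entity_kind,
                 symptom_groups = stats::setNames(cat_df$group,
                                                  cat_df$symptom))
}

#' Illustrative disease knowledge base (synthetic, non-clinical)
#'
#' A 14-disease by 60-symptom linkage matrix for demonstration and testing.
#' It is NOT a clinically validated weight matrix: it encodes the handful of
#' linkages that are documented for the published algorithm (internuclear
#' ophthalmoplegia under age 60 highly related to MS, vertical saccade palsy
#' highly related to NPC, resting tremor highly related to Parkinsonian
#' syndromes, and paresis negatively linked (-2) to NPC and GD3 to separate
#' them from Tay-Sachs) plus plausible placeholder linkages chosen so that
#' each disease has a distinctive positive-weight profile.  Do not use it for
#' patient care.
#'
#' @return A \code{knowledge_base} of kind \code{"DISEASE"}.
#' @export
example_disease_kb <- function() {
  sig <- list(
    "NPC" = list(
      "2" = c("vertical saccade palsy", "vertical supranuclear gaze palsy"),
      "1" = c("slowed vertical saccades", "ataxia", "dysarthria", "dysphagia",
              "splenomegaly", "cognitive decline", "psychiatric symptoms",
              "dystonia"),
      "-2" = "paresis"),
    "AT" = list(
      "2" = c("telangiectasia", "oculomotor apraxia"),
      "1" = c("ataxia", "polyneuropathy", "chorea", "dysarthria",
              "hypometric saccades", "head impulse test positive")),
    "AOA1/2" = list(
      "2" = c("oculomotor apraxia", "polyneuropathy"),
      "1" = c("ataxia", "chorea", "dystonia", "hypometric saccades",
              "saccadic smooth pursuit")),
    "GD3" = list(
      "2" = c("horizontal saccade palsy",
              "horizontal supranuclear gaze palsy"),
      "1" = c("slowed horizontal saccades", "ataxia", "splenomegaly",
              "epileptic seizures", "dysarthria"),
      "-2" = "paresis"),
    "TS" = list(
      "2" = c("vertical saccade palsy"),
      "1" = c("slowed vertical saccades", "paresis", "ataxia", "dysarthria",
              "psychiatric symptoms", "epileptic seizures")),
    "Wernicke encephalopathy" = list(
      "2" = c("confusion"),
      "1" = c("gaze-evoked nystagmus", "ataxia", "upbeat nystagmus",
              "bilateral vestibulopathy", "diplopia",
              "horizontal supranuclear gaze palsy",
              "optokinetic nystagmus impairment")),
    "Huntington chorea" = list(
      "2" = c("chorea"),
      "1" = c("psychiatric symptoms", "cognitive decline",
              "hypometric saccades", "saccadic intrusions",
              "slowed horizontal saccades", "dystonia")),
    "MS" = list(
      "2" = c("internuclear ophthalmoplegia, aged < 60 years"),
      "1" = c("spontaneous nystagmus", "diplopia", "sensory deficits",
              "paresis", "gaze-evoked nystagmus", "ataxia",
              "optokinetic nystagmus impairment")),
    "Parkinsonian syndromes" = list(
      "2" = c("resting tremor"),
      "1" = c("rigidity", "bradykinesia", "hypometric saccades",
              "square wave jerks", "reduced blink rate")),
    "PSP" = list(
      "2" = c("slowed vertical saccades", "falls"),
      "1" = c("vertical supranuclear gaze palsy", "square wave jerks",
              "rigidity", "bradykinesia", "cognitive decline",
              "reduced blink rate", "lid retraction"),
      "-1" = "resting tremor"),
    "tumor" = list(
      "2" = c("headache"),
      "1" = c("epileptic seizures", "paresis", "diplopia",
              "cognitive decline", "vertical gaze-holding deficit")),
    "infarction/hemorrhage" = list(
      "2" = c("acute onset"),
      "1" = c("skew deviation", "ocular tilt reaction", "paresis",
              "dysarthria", "spontaneous nystagmus", "sensory deficits")),
    "inflammatory encephalitis" = list(
      "2" = c("opsoclonus"),
      "1" = c("ocular flutter", "epileptic seizures", "confusion",
              "headache", "psychiatric symptoms", "fixation nystagmus")),
    "cerebellar syndromes" = list(
      "2" = c("downbeat nystagmus", "rebound nystagmus"),
      "1" = c("ataxia", "intention tremor", "gaze-evoked nystagmus",
              "saccadic smooth pursuit", "hypermetric saccades",
              "dysarthria", "impaired VOR suppression",
              "bilateral vestibulopathy", "head impulse test positive")))
  .kb_from_signatures(example_disease_catalog(), "DISEASE", sig)
}

#' Illustrative brain-zone knowledge base (synthetic, non-clinical)
#'
#' An 8-zone by 60-symptom linkage matrix (codes N / R / HR only, so all
#' weights are non-negative) built on textbook topographic associations of
#' ocular motor signs; like [example_disease_kb()] it is a demonstration
#' fixture, not a validated clinical matrix.
#'
#' @return A \code{knowledge_base} of kind \code{"BRAIN_ZONE"}.
#' @export
example_zone_kb <- function() {
  sig <- list(
    "midbrain" = list(
      "2" = c("vertical saccade palsy", "vertical supranuclear gaze palsy",
              "convergence-retraction nystagmus"),
      "1" = c("slowed vertical saccades", "skew deviation", "ptosis",
              "lid retraction", "vertical gaze-holding deficit",
              "internuclear ophthalmoplegia, aged < 60 years",
              "internuclear ophthalmoplegia, aged >= 60 years",
              "upbeat nystagmus", "convergence impairment")),
    "pons" = list(
      "2" = c("horizontal saccade palsy",
              "horizontal supranuclear gaze palsy"),
      "1" = c("internuclear ophthalmoplegia, aged < 60 years",
              "internuclear ophthalmoplegia, aged >= 60 years",
              "slowed horizontal saccades", "skew deviation",
              "ocular tilt reaction", "spontaneous nystagmus", "diplopia",
              "paresis", "dysarthria")),
    "medulla oblongata" = list(
      "2" = c("ocular tilt reaction", "upbeat nystagmus"),
      "1" = c("skew deviation", "dysphagia", "dysarthria",
              "spontaneous nystagmus", "head-shaking nystagmus")),
    "basal ganglia" = list(
      "2" = c("resting tremor", "chorea"),
      "1" = c("rigidity", "bradykinesia", "dystonia", "square wave jerks",
              "hypometric saccades", "reduced blink rate")),
    "frontoparietal cortex" = list(
      "2" = c("oculomotor apraxia"),
      "1" = c("epileptic seizures", "cognitive decline",
              "psychiatric symptoms", "confusion", "saccadic intrusions",
              "headache")),
    "flocculus/paraflocculus" = list(
      "2" = c("downbeat nystagmus", "impaired VOR suppression"),
      "1" = c("gaze-evoked nystagmus", "rebound nystagmus",
              "saccadic smooth pursuit", "fixation nystagmus",
              "optokinetic nystagmus impairment")),
    "vermis/fastigial nucleus" = list(
      "2" = c("hypermetric saccades"),
      "1" = c("ataxia", "saccadic smooth pursuit", "hypometric saccades",
              "macrosaccadic oscillations", "intention tremor")),
    "nodulus/uvula" = list(
      "2" = c("periodic alternating nystagmus", "positional nystagmus"),
      "1" = c("head-shaking nystagmus", "spontaneous nystagmus")))
  .kb_from_signatures(example_zone_catalog(), "BRAIN_ZONE", sig)
}

#' Disease-to-zone map for the illustrative knowledge base
#'
#' The brain zones typically affected by each disease of the reference
#' catalog; used by the synthetic-cohort generator as the ground-truth zone
#' labels.  A disease may map to several zones or (tumor, whose location
#' varies) to none.
#'
#' @return named list, disease -> character vector of zone ids.
#' @export
example_zone_map <- function() {
  list(
    "NPC" = "midbrain",
    "AT" = c("vermis/fastigial nucleus", "frontoparietal cortex"),
    "AOA1/2" = c("vermis/fastigial nucleus", "frontoparietal cortex"),
    "GD3" = "pons",
    "TS" = "midbrain",
    "Wernicke encephalopathy" = c("pons", "medulla oblongata"),
    "Huntington chorea" = c("basal ganglia", "frontoparietal cortex"),
    "MS" = c("pons", "midbrain"),
    "Parkinsonian syndromes" = "basal ganglia",
    "PSP" = c("midbrain", "basal ganglia"),
    "tumor" = character(),
    "infarction/hemorrhage" = c("pons", "medulla oblongata"),
    "inflammatory encephalitis" = "frontoparietal cortex",
    "cerebellar syndromes" = c("flocculus/paraflocculus",
                               "vermis/fastigial nucleus", "nodulus/uvula"))
}
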