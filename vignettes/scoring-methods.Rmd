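---
title: "Weighted linkage scoring for central ocular motor differential diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted linkage scoring for central ocular motor differential diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculodx)
```

## The clinical problem and the model

Central ocular motor disorders localize well: careful bedside examination
can place a lesion in the midbrain, pons, medulla, basal ganglia,
frontoparietal cortex or one of three cerebellar regions, and several rare,
treatable diseases (Niemann-Pick type C, Gaucher disease type 3, Tay-Sachs,
ataxia teleangiectasia, Wernicke encephalopathy, ...) announce themselves
through quite specific ocular motor findings — a vertical supranuclear
saccade palsy, an oculomotor apraxia, an internuclear ophthalmoplegia in a
young patient. These diseases are nevertheless often overlooked, because no
single clinician sees them often.

`oculodx` implements the rule-based scoring engine behind this kind of
"digital expert". The medical content is *data*: a knowledge base
$W \in \mathbb{Z}^{E \times S}$ of linkage weights between $E$ candidate
entities (14 diseases, or 8 brain zones) and $S = 60$ signs and symptoms.
Weights are entered as categorical linkage codes — NEV $=-3$, OTTD $=-2$,
UL $=-1$, N $=0$, Y/R $=+1$, HR $=+2$ — or as bare integers in $[-3, 4]$,
the full arithmetic range the scoring rules use. "HR" (highly related)
marks a symptom so typical of a disease that its presence adds two points
instead of one; negative codes implement *negative linkage*: a symptom
unlikely to occur with a disease subtracts points when present, e.g.
paresis subtracts two points from NPC and GD3 to separate them from
Tay-Sachs. Zone matrices use only non-negative codes.

A patient is a tri-state *entry mask* $r_s \in
\{\mathrm{PRESENT}, \mathrm{ABSENT}, \mathrm{UNTESTED}\}$ ("Yes" / "No" /
"0"). The score of entity $e$ is the sum of its weights over the symptoms
the patient presents:

$$\mathrm{score}(e) \;=\; \sum_{s\,:\,r_s = \mathrm{PRESENT}} W_{e,s}.$$

ABSENT and UNTESTED both contribute exactly zero — a "No" never subtracts,
and an incomplete examination cannot penalize a diagnosis. Scores are plain
integers, deliberately not normalized by the number of tested symptoms;
this keeps the engine bit-exact and the rules below interpretable in
points.

## Interpretation rules

A score vector becomes a result through shortlist rules.

For **diseases**: (1) if one disease scores at least three points above
every other, it is the sole result and flagged *dominant*; (2) otherwise
the result is the diseases holding the two highest score ranks — ties
expand the list, so scores $\{5,5,4\}$ shortlist the two 5s (the tie fills
both slots) while $\{5,4,4\}$ shortlist all three; (3) a shortlist of more
than five diseases is *not helpful* and reported empty.

For **brain zones**: no dominance rule; scores of one point or less are
filtered out before ranking, unless one point is the highest existing
score; more than four zones is not helpful, as is the case where nothing
survives the filter.

Two readings were genuinely open and are decided here as package policy:

* *The top-two rule under ties.* "The two entities with the highest
  scores ... can be more than two if several get the same score" is read as
  "every entity scoring at least the second-ranked score", the most literal
  reading; the worked output examples that exist cannot distinguish it from
  alternatives on the $\{5,5,4\}$ edge case.
* *Degenerate disease shortlists.* Disease shortlists are not
  score-thresholded: a top score of zero (even an all-zero tie over a small
  catalog) still forms a result unless the five-disease cap fires; only the
  zone rules state a filter. An all-zero mask over the full 14-disease
  catalog is a 14-way tie and therefore not helpful — the empty examination
  is correctly uninformative.
* *Rule order.* Dominance is checked before the size cap (a dominant
  single disease can never be "more than five", so the order matters only
  conceptually).
* *Empty zone results* (highest score $\le 0$) are classed not helpful,
  the rules' only defined failure mode.

## Accuracy evaluation

Validation against a labeled cohort uses shortlist confusion accounting,
per entity: a true disease appearing in the shortlist is a true positive
and every disease absent from the shortlist a true negative; every
incorrect shortlist member is a false positive; a missed truth is a false
negative; a not-helpful result counts as a false negative for the truth
and a false positive for all other entities. Zone truth is a *set* (a
lesion can span zones; published zone sensitivity denominators exceed the
cohort size), so zone accounting is multi-label: each true zone found /
missed is a TP / FN, each extra shortlist zone an FP, the rest TN.
Patients whose lesion site could not be verified can be flagged
`zones_evaluable = FALSE` and then contribute to no zone tally — the
published zone tables pair denominators summing to 97 of 104 patients,
i.e. 7 such exclusions.

Sensitivity is $TP/(TP+FN)$ and specificity $TN/(TN+FP)$, reported as
percentages rounded half-up to one decimal. Confidence limits use the 95%
Wald (asymptotic normal) binomial interval
$p \pm z_{0.975}\sqrt{p(1-p)/n}$ truncated to $[0,1]$ and rounded half-up
to three decimals. The exact quantile $z_{0.975} = 1.959964$ is used
rather than 1.96; the two agree to three decimals on every fraction in the
published tables (regression-tested). Wald is the published method and the
package default; it is known to behave poorly at extreme $p$ and small $n$
(the degenerate $1.000$–$1.000$ rows for perfect sensitivity on 4–11
patients illustrate why Wilson or Clopper-Pearson intervals are usually
preferred), but alternative intervals are out of scope here.

```{r reference}
head(reference_accuracy_table()[, c("entity", "sens_num", "sens_den",
                                    "sensitivity_pct", "sens_ci_low",
                                    "sens_ci_high")])
```

## The illustrative knowledge base

The clinically validated 60×14 and 60×8 weight matrices behind the
published tool were never released in full; only excerpts are public. The
package therefore ships a clearly labeled **illustrative, non-clinical**
fixture (`example_disease_kb()`, `example_zone_kb()`, also as TSV under
`inst/extdata/`). It encodes every explicitly documented linkage —
internuclear ophthalmoplegia under age 60 ↦ MS:HR, vertical saccade palsy
↦ NPC:HR, resting tremor ↦ Parkinsonian syndromes:HR, paresis ↦ NPC:OTTD
and GD3:OTTD — and fills the rest with textbook-plausible placeholder
linkages chosen so each disease has a distinctive positive-weight profile.
It exists so every downstream module is fully testable; it makes no claim
of clinical validity and must not be used for patient care.

## The synthetic cohort generator

Patient-level validation data are not public, so the package generates
labeled synthetic cohorts. For a patient with true disease $d$, each
symptom is drawn independently (Bernoulli) PRESENT with probability

| linkage to $d$ | probability | default |
|---|---|---|
| weight $\ge +2$ | `p_typical + p_hr_boost` | 0.95 |
| weight $= +1$ | `p_typical` | 0.80 |
| weight $= 0$ | `p_spurious` | 0.05 |
| weight $\le -1$ | 0 | 0 |

after which every response is independently masked UNTESTED with
probability `p_untested` (default 0.20). Negatively linked symptoms are
never generated present for their own disease, matching the semantics of
negative linkage (symptoms unlikely to occur with the disease). The
default per-disease counts reproduce the 104-patient validation cohort
mix (10 NPC, 5 AT, 4 AOA1/2, 10 GD3, 5 TS, 5 Wernicke, 5 Huntington,
10 MS, 10 Parkinsonian, 10 PSP, 4 tumor, 11 infarction/hemorrhage,
5 encephalitis, 10 cerebellar). The probability defaults are not published
quantities; they were fixed once at values describing a moderately noisy
but informative examination — high (80%) penetrance of typical signs,
near-certain (95%) presence of hallmark signs, rare (5%) spurious
findings, and a fifth of items left untested, roughly the sparsity seen in
retrospective chart review.

Reproducibility: one global integer seed; patient $i$ draws from its own
substream seeded by a fixed affine counter scheme on (seed, $i$), and
symptoms are visited in catalog order, so identical configurations yield
byte-identical cohorts regardless of how many draws other patients
consume.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: symptom-symptom correlation (draws are
independent), disease stage and age structure, systematically untestable
items, comorbidity, and any resemblance of the placeholder weights to the
true clinical matrix. Synthetic results exercise the pipeline's logic;
they do not re-validate the published accuracy.

## Numerical and testing choices

All scoring is integer arithmetic; there are no tolerances inside the
engine. Rounding is half-up (the published tables' convention), applied
only at reporting time; raw fractions are always carried alongside.
Tie-breaks in ranked output follow catalog order, fixed by the knowledge
base.

The test suite checks the scoring engine against a brute-force double-loop
oracle on 1,000 randomized toy knowledge bases, the interpretation rules
exhaustively against a literal rule transcription over the score spaces
$\{0..6\}^4$ (diseases) and $\{0..4\}^5$ (zones), confusion-mass
conservation ($TP+FN=$ prevalence, $FP+TN=$ complement) on 1,000 random
cohorts, and every published percentage and CI bound against the printed
numerator/denominator pairs. End-to-end: a noiseless cohort
(`p_typical = 1`, no noise or masking) is recovered at 100% sensitivity
for every disease, and mean sensitivity degrades monotonically as
`p_spurious` rises from 0 to 0.5 (averaged over 20 replicate cohorts of
104 patients — sizes chosen to keep the full suite under two minutes on a
laptop while leaving Monte-Carlo margins comfortably above 3σ).

## Known limitations

* The shipped weight matrix is illustrative; reproducing the published
  cohort accuracy end-to-end is impossible without the unpublished
  matrices and patient data, and is explicitly not attempted.
* One published figure is internally inconsistent: Huntington chorea
  specificity is printed as 94.5% next to the fraction 94/99 (= 94.9%) and
  a CI that matches 94/99; the package reports the value implied by the
  fraction.
* The iterative expert re-weighting loop that produced the clinical matrix
  is supported (edit TSV, re-evaluate) but no automatic weight tuner is
  provided, by design.
* Wald intervals are reported because they are the published method, with
  the caveats above.
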