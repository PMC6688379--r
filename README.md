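# oculodx

Rule-based differential diagnosis of central ocular motor disorders.

Several rare but treatable diseases — Niemann-Pick type C (NPC), Gaucher
disease type 3, Tay-Sachs, ataxia teleangiectasia, Wernicke encephalopathy —
present with quite specific central ocular motor findings, yet are routinely
overlooked because individual clinicians rarely see them. `oculodx`
implements the weighted symptom–disease linkage scoring engine behind a
"digital expert" for this differential, for neurologists,
neuro-ophthalmologists and methodologists studying rule-based clinical
decision support.

## The method

The medical knowledge is a matrix of integer linkage weights between
entities (14 candidate diseases, or 8 brain zones) and 60 signs and
symptoms, entered as categorical codes: NEV = −3, OTTD = −2, UL = −1,
N = 0, Y/R = +1, HR = +2 ("highly related": presence adds two points
instead of one). A patient is a tri-state entry mask (Yes / No / 0 =
not tested); the score of entity *e* is

    score(e) = Σ_{s present} W[e, s]

with absent and untested symptoms contributing exactly zero. Scores become
a diagnostic shortlist by three rules: a disease at least **three points
above all others is the sole (dominant) result**; otherwise the result is
the diseases on the **two highest score ranks, ties expanded**; **more than
five diseases** (four zones) is "not helpful". Zone scores of one point or
less are filtered out first, unless one point is the top score.

For validation, shortlist confusion accounting gives per-entity
sensitivity/specificity with 95% Wald (asymptotic normal) binomial
confidence intervals, `p ± 1.959964·sqrt(p(1−p)/n)` truncated to [0, 1].
A seeded synthetic-cohort generator (Bernoulli symptom draws conditioned
on disease linkage, spurious-symptom noise, untested masking) makes the
whole pipeline testable without patient data.

The shipped 60×14 and 60×8 matrices are **illustrative, non-clinical
fixtures**: the validated clinical matrices were never published in full.
See `vignette` source `vignettes/scoring-methods.Rmd` for the model,
parameter and design details.

## Worked example

```r
library(oculodx)
kb <- example_disease_kb()
patient <- patient_record("case-1", kb$symptoms,
  present = c("vertical saccade palsy", "vertical supranuclear gaze palsy",
              "slowed vertical saccades", "ataxia", "splenomegaly",
              "psychiatric symptoms"),
  absent  = c("paresis", "resting tremor", "chorea", "telangiectasia"))
scores <- score_patient(patient, kb)
head(rank_scores(scores), 5)
#>   entity score
#> 1    NPC     8
#> 2     TS     5
#> 3    PSP     3
#> 4    GD3     2
#> 5     AT     1
interpret_disease_scores(scores)
#> <interpretation_result> diseases: NPC [dominant]
interpret_zone_scores(score_patient(patient, example_zone_kb()))
#> <interpretation_result> brain zones: midbrain
```

The vertical saccade palsy and supranuclear gaze palsy are highly related
(+2) to NPC, so NPC reaches 8 points — at least three above the runner-up
Tay-Sachs (5), triggering the dominance rule: NPC is the sole suggested
diagnosis, localized to the midbrain. A cohort is evaluated with
`evaluate_cohort()`, which returns the per-disease and per-zone accuracy
tables:

```r
tab <- reference_accuracy_table()   # published validation-cohort counts
tab[tab$entity == "NPC", c("sens_num", "sens_den", "sensitivity_pct",
                           "specificity_pct", "spec_ci_low", "spec_ci_high")]
#>  sens_num sens_den sensitivity_pct specificity_pct spec_ci_low spec_ci_high
#>        10       10             100            75.5       0.668        0.842
```

i.e. 10/10 NPC patients shortlisted (100% sensitivity) and 71/94
non-NPC patients correctly without NPC on their shortlist (75.5%
specificity, 95% CI 0.668–0.842).

## Command line

A thin launcher is installed with the package:

```sh
oculodx=$(Rscript -e 'cat(system.file("cli/oculodx.R", package="oculodx"))')
Rscript $oculodx simulate --out-dir cohort --seed 42
Rscript $oculodx score    --disease-kb inst/extdata/disease_kb.tsv \
                          --zone-kb inst/extdata/zone_kb.tsv \
                          --mask cohort/mask.csv --format json
Rscript $oculodx evaluate --disease-kb inst/extdata/disease_kb.tsv \
                          --zone-kb inst/extdata/zone_kb.tsv \
                          --mask cohort/mask.csv --labels cohort/labels.csv
Rscript $oculodx validate-kb --kb inst/extdata/disease_kb.tsv
```

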