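Package: oculodx
Title: Rule-Based Differential Diagnosis of Central Ocular Motor Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A weighted symptom-disease linkage scoring engine for the
    differential diagnosis of central ocular motor disorders, including
    rare diseases such as Niemann-Pick type C and Gaucher disease type 3.
    Patients are described by a tri-state entry mask (present / absent /
    not tested) over a catalog of neurological and ocular motor signs;
    additive integer scores against a knowledge base of 14 candidate
    diseases and 8 brain zones are turned into a diagnostic shortlist by
    dominance, tie-expansion and not-helpful rules. The package also
    provides shortlist-based confusion accounting with per-entity
    sensitivity and specificity and 95% Wald (asymptotic normal) binomial
    confidence intervals, a seeded synthetic-cohort generator for testing
    the pipeline without patient data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
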