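diseases <- example_disease_catalog()
zones <- example_zone_catalog()

res <- function(shortlist, not_helpful = FALSE, kind = "DISEASE") {
  structure(list(entity_kind = kind, shortlist = shortlist,
                 not_helpful = not_helpful, dominant = FALSE),
            class = "interpretation_result")
}

test_that("a correct shortlist yields TP for truth, FP for co-members, TN elsewhere", {
  m <- tally_disease_result("NPC", res(c("NPC", "PSP")), diseases)
  expect_identical(m["NPC", "TP"], 1L)
  expect_identical(m["PSP", "FP"], 1L)
  expect_identical(sum(m[, "TN"]), 12L)
  expect_identical(sum(m), 14L)
  # dominant single correct result: no FP at all
  m2 <- tally_disease_result("NPC", res("NPC"), diseases)
  expect_identical(m2["NPC", "TP"], 1L)
  expect_identical(sum(m2[, "TN"]), 13L)
  expect_identical(sum(m2[, "FP"]), 0L)
})

test_that("a not-helpful result is FN for the truth and FP for the other 13", {
  m <- tally_disease_result("NPC", res(character(), not_helpful = TRUE),
                            diseases)
  expect_identical(m["NPC", "FN"], 1L)
  expect_identical(sum(m[, "FP"]), 13L)
  expect_identical(sum(m), 14L)
})

test_that("zone tallies follow the multi-label accounting", {
  m <- tally_zone_result(c("midbrain", "pons"),
                         res(c("midbrain", "flocculus/paraflocculus"),
                             kind = "BRAIN_ZONE"), zones)
  expect_identical(m["midbrain", "TP"], 1L)
  expect_identical(m["pons", "FN"], 1L)
  expect_identical(m["flocculus/paraflocculus", "FP"], 1L)
  expect_identical(sum(m[, "TN"]), 5L)
  # not helpful: FN for every true zone, FP for the rest
  m2 <- tally_zone_result("medulla oblongata",
                          res(character(), TRUE, "BRAIN_ZONE"), zones)
  expect_identical(m2["medulla oblongata", "FN"], 1L)
  expect_identical(sum(m2[, "FP"]), 7L)
  # empty truth: shortlist members are FP, everything else TN
  m3 <- tally_zone_result(character(), res("pons", kind = "BRAIN_ZONE"),
                          zones)
  expect_identical(m3["pons", "FP"], 1L)
  expect_identical(sum(m3[, "TN"]), 7L)
  expect_identical(sum(m3[, c("TP", "FN")]), 0L)
})

test_that("1000 random results match the case-by-case oracle and sum to |catalog|", {
  set.seed(1010)
  for (i in 1:1000) {
    truth <- sample(diseases, 1)
    nh <- runif(1) < 0.1
    sl <- if (nh) character() else sample(diseases, sample(1:5, 1))
    m <- tally_disease_result(truth, res(sl, nh), diseases)
    expect_identical(sum(m), 14L)
    expect_equal(unclass(m),
                 oracle_tally_disease(truth, sl, nh, diseases),
                 ignore_attr = FALSE)
    tz <- sample(zones, sample(0:3, 1))
    znh <- runif(1) < 0.1
    zsl <- if (znh) character() else sample(zones, sample(1:4, 1))
    zm <- tally_zone_result(tz, res(zsl, znh, "BRAIN_ZONE"), zones)
    expect_identical(sum(zm), 8L)
    expect_equal(unclass(zm), oracle_tally_zone(tz, zsl, znh, zones))
  }
})

test_that("confusion mass is conserved: TP+FN = prevalence, FP+TN = complement", {
  set.seed(1111)
  dkb <- example_disease_kb(); zkb <- example_zone_kb()
  for (rep in 1:5) {
    cfg <- cohort_config(p_spurious = 0.2, p_untested = 0.3,
                         seed = 2000 + rep)
    cohort <- generate_cohort(dkb, example_zone_map(), cfg)
    tab <- evaluate_cohort(cohort, dkb, zkb)$disease
    prev <- table(factor(vapply(cohort, `[[`, "", "true_disease"),
                         dkb$entities))
    expect_identical(tab$sens_den, as.integer(prev[tab$entity]))
    expect_identical(tab$spec_den,
                     as.integer(length(cohort) - prev[tab$entity]))
  }
})

test_that("percentages reproduce the published fractions", {
  tal <- matrix(c(30L, 0L, 0L, 9L), 1, 4,
                dimnames = list("x", c("TP", "FP", "TN", "FN")))
  expect_identical(accuracy_table(tal)$sensitivity_pct, 76.9)
  tal2 <- matrix(c(0L, 8L, 86L, 0L), 1, 4,
                 dimnames = list("x", c("TP", "FP", "TN", "FN")))
  expect_identical(accuracy_table(tal2)$specificity_pct, 91.5)
  tal3 <- matrix(c(4L, 0L, 0L, 0L), 1, 4,
                 dimnames = list("x", c("TP", "FP", "TN", "FN")))
  t3 <- accuracy_table(tal3)
  expect_identical(t3$sensitivity_pct, 100)
  expect_true(is.na(t3$specificity_pct))  # zero denominator stays NA
})

test_that("Wald intervals reproduce the published 95% bounds", {
  cases <- list(list(30, 39, c(0.637, 0.901)),
                list(3, 5, c(0.171, 1.000)),
                list(86, 94, c(0.858, 0.971)),
                list(10, 10, c(1.000, 1.000)),
                list(3, 4, c(0.326, 1.000)),
                list(0, 54, c(0.000, 0.000)))
  for (c3 in cases)
    expect_identical(round_half_up(wald_ci(c3[[1]], c3[[2]]), 3), c3[[3]])
  expect_identical(wald_ci(0, 0), c(NA_real_, NA_real_))
})

test_that("wald_ci midpoint is k/n and truncation only tightens toward [0,1]", {
  set.seed(1212)
  for (i in 1:200) {
    n <- sample(1:120, 1); k <- sample(0:n, 1)
    ci <- wald_ci(k, n)
    p <- k / n
    z <- qnorm(0.975)
    hw <- z * sqrt(p * (1 - p) / n)
    expect_true(ci[1] >= 0 && ci[2] <= 1 && ci[1] <= p && p <= ci[2])
    expect_equal(ci[1], max(0, p - hw))
    expect_equal(ci[2], min(1, p + hw))
    # z = 1.96 agrees to 3 decimals on every printed fraction
  }
  counts <- reference_validation_counts()
  for (i in seq_len(nrow(counts))) {
    for (pair in list(c(counts$sens_num[i], counts$sens_den[i]),
                      c(counts$spec_num[i], counts$spec_den[i]))) {
      exact <- wald_ci(pair[1], pair[2])
      z196 <- {
        p <- pair[1] / pair[2]
        hw <- 1.96 * sqrt(p * (1 - p) / pair[2])
        c(max(0, p - hw), min(1, p + hw))
      }
      expect_identical(round_half_up(exact, 3), round_half_up(z196, 3))
    }
  }
})

test_that("the reference accuracy table reproduces every published statistic", {
  tab <- reference_accuracy_table()
  r <- function(e) tab[tab$entity == e, ]
  expect_identical(r("NPC")$sensitivity_pct, 100)
  expect_identical(r("NPC")$specificity_pct, 75.5)
  expect_identical(c(r("NPC")$spec_ci_low, r("NPC")$spec_ci_high),
                   c(0.668, 0.842))
  expect_identical(r("GD3")$specificity_pct, 91.5)
  expect_identical(r("AT")$sensitivity_pct, 60.0)
  expect_identical(c(r("AT")$sens_ci_low, r("AT")$sens_ci_high),
                   c(0.171, 1.000))
  expect_identical(r("midbrain")$sensitivity_pct, 76.9)
  expect_identical(c(r("midbrain")$sens_ci_low, r("midbrain")$sens_ci_high),
                   c(0.637, 0.901))
  expect_identical(r("nodulus/uvula")$sensitivity_pct, 0)
  expect_identical(r("frontoparietal cortex")$specificity_pct, 98.8)
  # paired zone denominators all sum to the 97 zone-evaluable patients
  z <- tab[tab$kind == "BRAIN_ZONE", ]
  expect_true(all(z$sens_den + z$spec_den == 97L))
})

test_that("evaluate_cohort is order-invariant and honors zones_evaluable", {
  set.seed(1313)
  dkb <- example_disease_kb(); zkb <- example_zone_kb()
  cohort <- generate_cohort(dkb, example_zone_map(),
                            cohort_config(seed = 77))
  ev1 <- evaluate_cohort(cohort, dkb, zkb)
  ev2 <- evaluate_cohort(rev(cohort), dkb, zkb)
  expect_identical(ev1$disease, ev2$disease)
  expect_identical(ev1$zone, ev2$zone)
  # flag 7 patients out of zone evaluation: zone denominators drop to 97
  cohort2 <- cohort
  for (i in 1:7) cohort2[[i]]$zones_evaluable <- FALSE
  z <- evaluate_cohort(cohort2, dkb, zkb)$zone
  expect_true(all(z$sens_den + z$spec_den == 97L))
  expect_identical(evaluate_cohort(cohort2, dkb, zkb)$disease, ev1$disease)
})

test_that("a single dominant correct diagnosis gives a perfect one-row cohort", {
  dkb <- example_disease_kb(); zkb <- example_zone_kb()
  p <- patient_record("solo", dkb$symptoms,
                      present = names(which(dkb$weights["NPC", ] > 0)))
  cohort <- list(labeled_patient(p, "NPC", "midbrain"))
  tab <- evaluate_cohort(cohort, dkb, zkb)$disease
  expect_identical(tab$sensitivity_pct[tab$entity == "NPC"], 100)
  expect_true(all(tab$spec_num[tab$entity != "NPC"] == 1L))
  expect_true(all(tab$specificity_pct[tab$entity != "NPC"] == 100))
})
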