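test_that("linkage codes translate to their canonical integer weights", {
  expect_identical(
    translate_codes(c("NEV", "OTTD", "UL", "N", "Y", "HR"), "DISEASE"),
    c(-3L, -2L, -1L, 0L, 1L, 2L))
  expect_identical(translate_codes(c("N", "R", "HR"), "BRAIN_ZONE"),
                   c(0L, 1L, 2L))
  # empty cell and bare integers in the arithmetic range
  expect_identical(translate_codes(c("", "3", "4", "-3"), "DISEASE"),
                   c(0L, 3L, 4L, -3L))
})

test_that("kind-mismatched and unknown codes are rejected with location", {
  expect_error(translate_codes("R", "DISEASE", where = "row 'x', column 'y'"),
               "not valid in a DISEASE matrix.*row 'x', column 'y'")
  expect_error(translate_codes("Y", "BRAIN_ZONE"), "not valid")
  expect_error(translate_codes("MAYBE", "DISEASE"), "unknown linkage code")
  expect_error(translate_codes("5", "DISEASE"), "out of range")
  expect_error(translate_codes("-1", "BRAIN_ZONE"), "out of range")
})

test_that("a minimal table loads with the documented weights", {
  txt <- c("# entity_kind: DISEASE",
           "symptom\tNPC\tMS",
           "vertical saccade palsy\tHR\tN")
  tf <- withr::local_tempfile(lines = txt, fileext = ".tsv")
  kb <- load_knowledge_base(tf)
  expect_identical(kb$weights["NPC", "vertical saccade palsy"], 2L)
  expect_identical(kb$weights["MS", "vertical saccade palsy"], 0L)
  # all-N table gives all-zero weights
  tf2 <- withr::local_tempfile(
    lines = c("symptom\tA\tB", "s1\tN\tN", "s2\tN\tN"), fileext = ".tsv")
  expect_true(all(load_knowledge_base(tf2, "DISEASE")$weights == 0L))
})

test_that("random code tables load cell-for-cell per the hand map", {
  set.seed(11)
  codes <- c("NEV", "OTTD", "UL", "N", "Y", "HR")
  ents <- paste0("D", 1:5)
  syms <- paste0("sym", 1:8)
  cells <- matrix(sample(codes, 40, replace = TRUE), 8, 5)
  lines <- c(paste(c("symptom", ents), collapse = "\t"),
             vapply(1:8, function(i)
               paste(c(syms[i], cells[i, ]), collapse = "\t"), ""))
  tf <- withr::local_tempfile(lines = lines, fileext = ".tsv")
  kb <- load_knowledge_base(tf, "DISEASE")
  for (i in 1:8) for (j in 1:5)
    expect_identical(kb$weights[ents[j], syms[i]],
                     as.integer(oracle_code_map[[cells[i, j]]]))
})

test_that("write/load round-trips are the identity on valid KBs", {
  for (kb in list(example_disease_kb(), example_zone_kb())) {
    tf <- withr::local_tempfile(fileext = ".tsv")
    write_knowledge_base(kb, tf)
    kb2 <- load_knowledge_base(tf)
    expect_identical(kb2$weights, kb$weights)
    expect_identical(kb2$entity_kind, kb$entity_kind)
    expect_identical(kb2$symptom_groups, kb$symptom_groups)
  }
  # weight +4 has no canonical code and is serialized as a bare integer
  w <- matrix(c(4L, 0L), 1, 2, dimnames = list("D1", c("s1", "s2")))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_knowledge_base(knowledge_base(w, "DISEASE"), tf)
  expect_match(readLines(tf)[3], "\t4$")
  expect_identical(load_knowledge_base(tf)$weights, w)
})

test_that("validation reports range and kind findings without throwing", {
  kb <- example_disease_kb()
  expect_length(validate_knowledge_base(kb), 0)
  kb$weights["NPC", "ataxia"] <- 5L
  f <- validate_knowledge_base(kb)
  expect_length(f, 1)
  expect_match(f, "out of range.*NPC.*ataxia")
  zkb <- example_zone_kb()
  zkb$weights["pons", "ataxia"] <- -1L
  expect_match(validate_knowledge_base(zkb), "out of range.*BRAIN_ZONE")
})

test_that("duplicate identifiers and malformed files are rejected", {
  tf <- withr::local_tempfile(
    lines = c("symptom\tA\tA", "s1\tN\tN"), fileext = ".tsv")
  expect_error(load_knowledge_base(tf, "DISEASE"), "duplicate entity")
  tf2 <- withr::local_tempfile(
    lines = c("symptom\tA", "s1\tN", "s1\tY"), fileext = ".tsv")
  expect_error(load_knowledge_base(tf2, "DISEASE"), "duplicate symptom")
  tf3 <- withr::local_tempfile(lines = c("symptom\tA", "s1\tQQ"),
                               fileext = ".tsv")
  expect_error(load_knowledge_base(tf3, "DISEASE"),
               "unknown linkage code 'QQ'.*row 's1', column 'A'")
})

test_that("the shipped fixture files equal the in-code builders", {
  d <- load_knowledge_base(system.file("extdata", "disease_kb.tsv",
                                       package = "oculodx"))
  z <- load_knowledge_base(system.file("extdata", "zone_kb.tsv",
                                       package = "oculodx"))
  expect_identical(d$weights, example_disease_kb()$weights)
  expect_identical(z$weights, example_zone_kb()$weights)
  expect_identical(d$entity_kind, "DISEASE")
  expect_identical(z$entity_kind, "BRAIN_ZONE")
  # the documented explicit linkages
  expect_identical(d$weights["NPC", "vertical saccade palsy"], 2L)
  expect_identical(d$weights["MS", "internuclear ophthalmoplegia, aged < 60 years"], 2L)
  expect_identical(d$weights["Parkinsonian syndromes", "resting tremor"], 2L)
  expect_identical(d$weights["NPC", "paresis"], -2L)
  expect_identical(d$weights["GD3", "paresis"], -2L)
  # reference catalog sizes
  expect_length(d$symptoms, 60)
  expect_length(d$entities, 14)
  expect_length(z$entities, 8)
  expect_true(all(z$weights >= 0))
})
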