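risk_of <- function(relatives) {
  assess_fh_risk(make_pedigree("X", relatives))
}

test_that("individual default rules fire as documented", {
  # early-onset breast, inclusive boundary at 45
  expect_equal(risk_of(list(rel("mother", "breast", 45)))$fh_cohort, "increased")
  expect_equal(risk_of(list(rel("mother", "breast", 46)))$fh_cohort, "average")
  # breast with unknown age alone cannot fire an age-limited single-case rule
  expect_equal(risk_of(list(rel("sibling", "breast")))$fh_cohort, "average")
  # two same-side breast cancers, one at <= 50
  expect_equal(risk_of(list(
    rel("aunt_uncle", "breast", 48, lineage = "maternal"),
    rel("grandparent", "breast", 62, lineage = "maternal")))$fh_cohort, "increased")
  # the same ages on opposite sides never pool
  expect_equal(risk_of(list(
    rel("aunt_uncle", "breast", 48, lineage = "maternal"),
    rel("grandparent", "breast", 62, lineage = "paternal")))$fh_cohort, "average")
  # a sibling counts toward either side
  expect_equal(risk_of(list(
    rel("sibling", "breast", 48),
    rel("grandparent", "breast", 62, lineage = "paternal")))$fh_cohort, "increased")
  # ovarian at any age; male breast at any age
  expect_equal(risk_of(list(rel("grandparent", "ovarian", 75,
                                lineage = "paternal")))$fh_cohort, "increased")
  expect_equal(risk_of(list(rel("father", "breast", 60, sex = "M")))$fh_cohort,
               "increased")
  # colorectal strictly before 50
  expect_equal(risk_of(list(rel("father", "colorectal", 49)))$fh_cohort, "increased")
  expect_equal(risk_of(list(rel("father", "colorectal", 50)))$fh_cohort, "average")
  # two unknown-type cancers under 50 on the same side
  expect_equal(risk_of(list(
    rel("aunt_uncle", "unknown_cancer", "40s", lineage = "maternal"),
    rel("grandparent", "unknown_cancer", "30s", lineage = "maternal")))$fh_cohort,
    "increased")
  # cousins are stored but do not count by default
  expect_equal(risk_of(list(rel("cousin", "ovarian", 40,
                                lineage = "maternal")))$fh_cohort, "average")
})

test_that("unknown-age relaxation fires count-based rules and flags ambiguity", {
  # two same-side Lynch-spectrum cancers, ages unknown: fires, ambiguous
  res <- risk_of(list(
    rel("grandparent", "colorectal", lineage = "maternal"),
    rel("aunt_uncle", "colorectal", lineage = "maternal")))
  expect_equal(res$fh_cohort, "increased")
  expect_true(res$ambiguous)
  expect_match(res$triggered_rules, "lynch_two_same_lineage")
  # both ages known and >= 50: does not fire
  res2 <- risk_of(list(
    rel("father", "bladder", 65, sex = "M"),
    rel("sibling", "colorectal", 76, sex = "M")))
  expect_equal(res2$fh_cohort, "average")
  # three same-side Lynch cancers fire at any age, unambiguously
  res3 <- risk_of(list(
    rel("grandparent", "colorectal", 70, lineage = "maternal"),
    rel("aunt_uncle", "gastric", 66, lineage = "maternal"),
    rel("mother", "endometrial", 61)))
  expect_equal(res3$fh_cohort, "increased")
  expect_false(res3$ambiguous)
})

test_that("empty or cancer-free histories are average; no history is not_available", {
  expect_equal(risk_of(list())$fh_cohort, "average")
  expect_equal(risk_of(list(rel("mother", "hypertension", 50)))$fh_cohort, "average")
  na <- assess_fh_risk(make_pedigree("X", fh_available = FALSE))
  expect_equal(na$fh_cohort, "not_available")
  expect_equal(na$triggered_rules, "")
})

test_that("risk is monotone in affected relatives and order-independent", {
  set.seed(42)
  pool <- list(
    rel("mother", "breast", 63), rel("father", "lung", 70),
    rel("aunt_uncle", "colorectal", 72, lineage = "maternal"),
    rel("grandparent", "breast", 44, lineage = "maternal"),
    rel("sibling", "ovarian", 50), rel("aunt_uncle", "unknown_cancer", "40s",
                                       lineage = "paternal"),
    rel("grandparent", "unknown_cancer", 45, lineage = "paternal"),
    rel("child", "hypertension", 30)
  )
  rank <- c(average = 1, increased = 2)
  for (i in 1:25) {
    k <- sample(0:(length(pool) - 1), 1)
    idx <- sample(seq_along(pool), k)
    base_rels <- pool[idx]
    rest <- setdiff(seq_along(pool), idx)
    extra <- rest[sample.int(length(rest), 1)]
    r0 <- risk_of(base_rels)
    r1 <- risk_of(c(base_rels, pool[extra]))
    expect_gte(rank[r1$fh_cohort], rank[r0$fh_cohort])
    # shuffling relatives never changes the call
    r2 <- risk_of(sample(c(base_rels, pool[extra])))
    expect_equal(r2$fh_cohort, r1$fh_cohort)
    expect_equal(sort(strsplit(r2$triggered_rules, ";")[[1]]),
                 sort(strsplit(r1$triggered_rules, ";")[[1]]))
  }
})

test_that("the packaged carrier histories are all average risk; the colorectal family is increased", {
  histories <- jsonlite::fromJSON(fhc_extdata("average_risk_carrier_histories.json"),
                                  simplifyVector = FALSE)
  expect_length(histories, 17)
  res <- vapply(histories, function(h) assess_fh_risk(parse_pedigree(h))$fh_cohort, "")
  expect_equal(unname(res), rep("average", 17))

  crc <- assess_fh_risk(parse_pedigree(fhc_extdata("increased_risk_colorectal_history.json")))
  expect_equal(crc$fh_cohort, "increased")
  expect_true(crc$ambiguous)
})

test_that("family cancer summaries count reports and multi-cancer families", {
  one <- make_pedigree("F1", list(rel("mother", "breast", 44)))$relatives
  s1 <- summarize_family_cancers(one)
  expect_equal(s1$cancer_table$condition, "breast")
  expect_equal(s1$cancer_table$pct, 100)
  expect_equal(s1$multi_cancer_family_fraction, 0)

  two <- dplyr::bind_rows(
    make_pedigree("F1", list(rel("mother", "breast", 44),
                             rel("aunt_uncle", "ovarian", 50, lineage = "maternal")))$relatives,
    make_pedigree("F2", list(rel("mother", "breast", 50),
                             rel("sibling", "ovarian", 45)))$relatives)
  s2 <- summarize_family_cancers(two)
  expect_equal(s2$multi_cancer_family_fraction, 1)
  expect_equal(s2$n_reports, 4)
  expect_equal(sort(s2$cancer_table$pct), c(50, 50))
  # per-family switch counts each (family, type) once
  s3 <- summarize_family_cancers(dplyr::bind_rows(two, two), per_family = FALSE)
  expect_equal(s3$n_reports, 8)
  s4 <- summarize_family_cancers(dplyr::bind_rows(two, two), per_family = TRUE)
  expect_equal(s4$n_reports, 4)

  empty <- summarize_family_cancers(make_pedigree("F0", list(
    rel("father", "hypertension", 60)))$relatives)
  expect_equal(empty$n_reports, 0)
  expect_true(is.na(empty$multi_cancer_family_fraction))
})
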