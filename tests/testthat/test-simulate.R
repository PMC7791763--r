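test_that("simulation is fully determined by its seed", {
  cfg <- simulation_config(mode = "designed", n_fh_available = 60,
                           n_fh_unavailable = 40, p_increased = 0.2,
                           n_decoy_sites = 60, seed = 11)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$cases, s2$cases)
  expect_identical(s1$ground_truth, s2$ground_truth)
  s3 <- simulate_cohort(simulation_config(mode = "designed", n_fh_available = 60,
                                          n_fh_unavailable = 40, p_increased = 0.2,
                                          n_decoy_sites = 60, seed = 12))
  expect_false(identical(s1$variants, s3$variants))
})

test_that("null scenario: no familial variants, no carriers, full concordance", {
  cfg <- simulation_config(mode = "designed", n_fh_available = 80,
                           n_fh_unavailable = 20, p_increased = 0,
                           p_carrier_increased = 0, p_carrier_average = 0,
                           p_carrier_unavailable = 0, n_decoy_sites = 80, seed = 5)
  sim <- simulate_cohort(cfg)
  panel <- load_panel()
  st <- assign_carrier_status(triage_cohort(sim$variants, panel), panel,
                              participants = sim$participants$participant_id)
  expect_equal(sum(st$is_carrier), 0)
  fh <- assess_fh_cohort(sim$cases, sim$fh)
  avail <- tibble::tibble(fh_cohort = fh$fh_cohort, is_carrier = st$is_carrier)
  avail <- avail[avail$fh_cohort != "not_available", ]
  expect_equal(concordance_table(avail)$discordant, 0)
  expect_equal(concordance_table(avail)$pct_concordant, 100)
})

test_that("golden preset realises its designed structure and triage recovers it exactly", {
  sim <- simulate_cohort(golden_cohort_config(seed = 3))
  gt <- sim$ground_truth
  expect_equal(nrow(gt), 1750)
  expect_equal(sum(gt$fh_intent == "increased"), 73)
  expect_equal(sum(gt$fh_intent == "average"), 793)
  expect_equal(sum(gt$fh_intent == "not_available"), 884)
  expect_equal(sum(gt$true_carrier), 44)
  expect_equal(sum(gt$sensitivity_exclude), 1)

  panel <- load_panel()
  st <- assign_carrier_status(triage_cohort(sim$variants, panel), panel,
                              participants = gt$participant_id)
  # sensitivity 1.0 and specificity 1.0 against ground truth
  expect_equal(st$is_carrier, gt$true_carrier)
  expect_equal(st$acmg_sf_carrier, gt$true_sf_carrier)
  # no participant carries more than one actionable variant
  expect_lte(max(st$n_actionable), 1)

  fh <- assess_fh_cohort(sim$cases, sim$fh)
  expect_equal(fh$fh_cohort, gt$fh_intent)
})

test_that("every average-history template is indeed average risk", {
  tpls <- fhconcord:::average_templates()
  for (t in tpls) {
    cases <- fhconcord:::template_cases("X", t$rows)
    fh <- tibble::tibble(participant_id = "X", fh_available = TRUE)
    expect_equal(assess_fh_cohort(cases, fh)$fh_cohort, "average")
  }
  # and every increased archetype fires at least one rule, unambiguously
  for (t in fhconcord:::increased_templates()) {
    cases <- fhconcord:::template_cases("X", t$rows)
    fh <- tibble::tibble(participant_id = "X", fh_available = TRUE)
    res <- assess_fh_cohort(cases, fh)
    expect_equal(res$fh_cohort, "increased")
    expect_false(res$ambiguous)
  }
})

test_that("ground truth is written alongside but never consumed by the pipeline", {
  d <- withr::local_tempdir()
  cfg <- simulation_config(mode = "designed", n_fh_available = 40,
                           n_fh_unavailable = 10, n_decoy_sites = 40, seed = 2)
  simulate_cohort(cfg, out_dir = d)
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  unlink(file.path(d, "ground_truth.json"))
  rep <- suppressMessages(run_pipeline(
    file.path(d, "cohort.vcf"), file.path(d, "annotation.tsv"),
    file.path(d, "pedigrees"), file.path(d, "out")))
  expect_s3_class(rep, "fhc_report")
})

test_that("penetrance mode segregates variants and enrichment grows with penetrance", {
  means <- vapply(c(0.15, 0.8), function(pen) {
    cfg <- simulation_config(mode = "penetrance", n_fh_available = 220,
                             n_fh_unavailable = 0, familial_variant_prob = 0.3,
                             carrier_penetrance = pen, decoy_rate = 1,
                             n_decoy_sites = 80, seed = 0)
    res <- recover_enrichment(cfg, n_replicates = 8, seed = 40)
    attr(res, "mean_rr")
  }, 1)
  expect_false(any(is.na(means)))
  expect_gt(means[2], means[1])
})
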