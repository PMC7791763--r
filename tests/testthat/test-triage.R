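test_that("candidate routes follow the three criteria in fixed priority order", {
  panel <- small_panel()
  v <- dplyr::bind_rows(
    make_variant(consequence = "stopgain", af_local = 0.001, gene = "BRCA1"),
    make_variant(revel = 0.85, af_gnomad = 1e-4, gene = "BRCA2"),
    make_variant(revel = 0.69, gene = "BRCA2"),
    make_variant(consequence = "stopgain", gene = "BRCA1",
                 clinvar_assertion = "likely_pathogenic", has_lp_or_p_entry = TRUE),
    make_variant(consequence = "stopgain", gene = "TERT", af_local = 0.001)
  )
  cand <- select_lp_candidates(v, panel)
  expect_equal(cand$route, c("lof_candidate", "insilico_candidate", "clinvar_lp_p"))
  # REVEL exactly at the boundary is not routed (strict >)
  expect_false(any(cand$revel %in% 0.69))
  # a database P/LP entry outranks the LoF route on the same variant
  expect_equal(cand$route[cand$has_lp_or_p_entry], "clinvar_lp_p")
  # LoF in a gene with unestablished haploinsufficiency goes to manual review
  expect_equal(attr(cand, "manual_review")$gene, "TERT")
  expect_error(select_lp_candidates(make_variant(gene = "NOSUCH"), panel),
               "NOSUCH", class = "fhc_data_error")
})

test_that("VUS pool selection flags potential pathogenicity", {
  panel <- small_panel()
  v <- dplyr::bind_rows(
    make_variant(revel = 0.9, af_local = 0.002, clinvar_assertion = "vus"),
    make_variant(revel = 0.3, af_local = 0.002, clinvar_assertion = "vus"),
    make_variant(consequence = "synonymous", af_local = 0.02),
    make_variant(revel = 0.1, af_local = 0.002, clinvar_assertion = "benign")
  )
  pool <- select_vus(v, panel)
  expect_equal(pool$final_class, rep("VUS", 2))
  expect_equal(pool$potential_pathogenic, c(TRUE, FALSE))
  # the rare benign record is classed out of the pool, the common one filtered
  expect_equal(attr(pool, "benign")$final_class, "LB")
})

test_that("full triage classifies, excludes and flags consistently", {
  panel <- small_panel()
  v <- dplyr::bind_rows(
    make_variant(participant_id = "A", consequence = "stopgain", gene = "BRCA1"),
    make_variant(participant_id = "A", revel = 0.5, af_local = 0.002),
    make_variant(participant_id = "B", af_gnomad = 0.2, revel = 0.1,
                 clinvar_assertion = "benign"),
    make_variant(participant_id = "B", gene = "BRCA2",
                 clinvar_assertion = "pathogenic", has_lp_or_p_entry = TRUE)
  )
  out <- triage_cohort(v, panel)
  expect_equal(nrow(out), nrow(v))
  expect_true(all(out$route %in% c("clinvar_lp_p", "lof_candidate",
                                   "insilico_candidate", "vus_pool", "excluded")))
  # excluded records carry no class; routed records carry exactly one
  expect_true(all(is.na(out$final_class[out$route == "excluded"])))
  expect_true(all(!is.na(out$final_class[out$route != "excluded"])))
  expect_equal(out$final_class[out$clinvar_assertion == "pathogenic"], "P")
  expect_equal(out$final_class[out$consequence == "stopgain"], "LP")
  expect_equal(out$exclusion_reason[out$af_gnomad %in% 0.2], "common_af")
  # triage is a pure function: identical input, identical output
  expect_identical(out, triage_cohort(v, panel))
  # stage outputs are subsets of the input keys
  expect_true(all(paste(out$participant_id, out$pos) %in% paste(v$participant_id, v$pos)))
})

test_that("carrier status distinguishes dominant, X-linked and recessive genotypes", {
  panel <- small_panel()
  classify <- function(v) assign_carrier_status(triage_cohort(v, panel), panel)

  # one LP het in an AD gene
  ad <- classify(make_variant(consequence = "stopgain", gene = "BRCA1"))
  expect_true(ad$is_carrier)
  expect_true(ad$acmg_sf_carrier)

  # het P in an AR gene: recessive carriage only
  ar <- classify(make_variant(gene = "MUTYH", consequence = "stopgain",
                              clinvar_assertion = "pathogenic", has_lp_or_p_entry = TRUE))
  expect_false(ar$is_carrier)
  expect_true(ar$recessive_carrier)
  expect_false(ar$acmg_sf_carrier)

  # homozygous P in the same AR gene: biallelic, a carrier
  arhom <- classify(make_variant(gene = "MUTYH", consequence = "stopgain",
                                 clinvar_assertion = "pathogenic",
                                 has_lp_or_p_entry = TRUE, zygosity = "hom"))
  expect_true(arhom$is_carrier)

  # two distinct hets in the same AR gene: assumed in trans, a carrier
  artrans <- classify(dplyr::bind_rows(
    make_variant(gene = "MUTYH", pos = 100, consequence = "stopgain",
                 clinvar_assertion = "pathogenic", has_lp_or_p_entry = TRUE),
    make_variant(gene = "MUTYH", pos = 200, consequence = "stopgain",
                 clinvar_assertion = "likely_pathogenic", has_lp_or_p_entry = TRUE)))
  expect_true(artrans$is_carrier)
  expect_false(artrans$recessive_carrier)

  # hemizygous LP in an XL gene
  xl <- classify(make_variant(gene = "GPC3", consequence = "stopgain",
                              zygosity = "hemi"))
  expect_true(xl$is_carrier)
  expect_false(xl$acmg_sf_carrier)

  # no P/LP variants at all
  none <- assign_carrier_status(
    triage_cohort(make_variant(revel = 0.2, af_local = 0.005), panel),
    panel, participants = c("P1", "P9"))
  expect_equal(none$is_carrier, c(FALSE, FALSE))
  expect_equal(none$participant_id, c("P1", "P9"))
})
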