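test_that("relative risk reproduces the reference contingency comparisons", {
  r1 <- relative_risk(10, 73, 17, 793)
  expect_equal(r1$display$rr_2dp, 6.39)
  expect_equal(r1$display$ci_1dp, "3.0-13.4")
  expect_lt(r1$p_value, 0.05)

  r2 <- relative_risk(5, 73, 4, 884)
  expect_equal(r2$display$rr_2dp, 15.13)
  expect_equal(r2$display$ci_1dp, "4.1-55.1")
})

test_that("relative risk obeys its structural invariants", {
  # symmetry: identical rates give RR 1 for any counts
  for (k in c(1, 5, 12)) expect_equal(relative_risk(k, 40, k, 40, p_value = FALSE)$rr, 1)
  # scale invariance of the point estimate
  a <- relative_risk(7, 50, 9, 200, p_value = FALSE)
  b <- relative_risk(70, 500, 90, 2000, p_value = FALSE)
  expect_equal(a$rr, b$rr)
  # ...but the interval tightens with more data
  expect_lt(b$ci_high - b$ci_low, a$ci_high - a$ci_low)
  # strictly increasing in a, decreasing in c; CI brackets the estimate
  rrs <- sapply(1:10, function(a) relative_risk(a, 50, 5, 100, p_value = FALSE)$rr)
  expect_true(all(diff(rrs) > 0))
  rrs2 <- sapply(1:10, function(c) relative_risk(5, 50, c, 100, p_value = FALSE)$rr)
  expect_true(all(diff(rrs2) < 0))
  r <- relative_risk(3, 30, 4, 70, p_value = FALSE)
  expect_true(r$ci_low <= r$rr && r$rr <= r$ci_high)
})

test_that("zero cells are undefined by default, Haldane-corrected on request", {
  r <- relative_risk(0, 50, 5, 100)
  expect_true(r$undefined)
  expect_true(is.na(r$rr))
  rc <- relative_risk(0, 50, 5, 100, correction = TRUE)
  expect_false(rc$undefined)
  expect_gt(rc$rr, 0)
  expect_error(relative_risk(-1, 10, 1, 10), class = "fhc_data_error")
  expect_error(relative_risk(11, 10, 1, 10), class = "fhc_data_error")
})

test_that("the exact test matches identical-margin and enumeration cases", {
  expect_equal(exact_test(1, 2, 1, 2), 1)
  expect_equal(exact_test(0, 10, 0, 10), 1)
  expect_equal(exact_test(3, 10, 1, 10), fisher_oracle(3, 10, 1, 10))
  # spot agreement with the reference implementation
  for (x in list(c(10, 73, 17, 793), c(5, 73, 3, 793), c(3, 10, 1, 10),
                 c(0, 5, 4, 9), c(12, 20, 3, 25))) {
    expect_equal(exact_test(x[1], x[2], x[3], x[4]),
                 stats::fisher.test(matrix(c(x[1], x[2] - x[1], x[3], x[4] - x[3]),
                                           2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("concordance partition conserves the cohort and rejects out-of-scope rows", {
  mk <- function(a, b, c, d) tibble::tibble(
    fh_cohort = rep(c("increased", "average", "increased", "average"), c(a, b, c, d)),
    is_carrier = rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c, d)))
  ct <- concordance_table(mk(10, 17, 63, 776))
  expect_equal(ct$concordant, 786)
  expect_equal(ct$discordant, 80)
  expect_equal(ct$concordant + ct$discordant, ct$total)

  expect_equal(concordance_table(mk(0, 0, 0, 50))$discordant, 0)
  ct2 <- concordance_table(mk(1, 1, 1, 1))
  expect_equal(ct2$concordant, 2)
  expect_equal(ct2$discordant, 2)

  bad <- tibble::tibble(fh_cohort = c("increased", "not_available"),
                        is_carrier = c(TRUE, FALSE))
  expect_error(concordance_table(bad), "not_available", class = "fhc_data_error")
})

test_that("display conventions: truncation for ratios, half-away rounding for percentages", {
  expect_equal(trunc_dec(c(3.386, 14.986, 74.275, 15.137), 1), c(3.3, 14.9, 74.2, 15.1))
  expect_equal(trunc_dec(15.137, 2), 15.13)
  expect_equal(pct(10, 73), 13.7)
  expect_equal(pct(3, 793), 0.4)
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  expect_equal(fmt_one_in(10, 73), "1 in 7")
  expect_equal(fmt_one_in(17, 793), "1 in 47")
  expect_true(is.na(fmt_one_in(0, 100)))
})

test_that("cohort report assembles counts, enrichment blocks and sensitivity rerun", {
  assessments <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:100),
    fh_cohort = rep(c("increased", "average", "not_available"), c(20, 50, 30)),
    is_carrier = c(rep(TRUE, 6), rep(FALSE, 14), rep(TRUE, 3), rep(FALSE, 47),
                   rep(TRUE, 2), rep(FALSE, 28)),
    acmg_sf_carrier = c(rep(TRUE, 2), rep(FALSE, 48), rep(FALSE, 50)))
  rep <- cohort_report(assessments, exclude_participants = "P001")
  expect_equal(rep$cohorts$carriers, c(6, 3, 2))
  expect_equal(rep$cohorts$n, c(20, 50, 30))
  r <- rep$rr$panel_increased_vs_average
  expect_equal(r$rr, (6 / 20) / (3 / 50))
  rs <- rep$sensitivity$panel_increased_vs_average
  expect_equal(c(rs$a, rs$n1), c(5, 19))
  expect_equal(rep$concordance$total, 70)

  # an empty cohort suppresses its comparisons and is flagged
  sub <- assessments[assessments$fh_cohort != "not_available", ]
  rep2 <- cohort_report(sub)
  expect_null(rep2$rr$panel_increased_vs_not_available)
  expect_equal(rep2$empty_cohorts, "not_available")
  # zero carriers everywhere: proportions zero, enrichment undefined
  zero <- assessments; zero$is_carrier <- FALSE; zero$acmg_sf_carrier <- FALSE
  rep3 <- cohort_report(zero)
  expect_equal(rep3$cohorts$pct_carriers, c(0, 0, 0))
  expect_true(rep3$rr$panel_increased_vs_average$undefined)
})
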