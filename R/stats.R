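#' Cohort statistics
#'
#' Relative risk for 2x2 cohort comparisons with the classical log-normal
#' confidence interval (Altman): for a carriers among n1 exposed and c among
#' n2 unexposed,
#' \deqn{RR = (a/n1)/(c/n2), \quad SE(\log RR) = \sqrt{1/a - 1/n1 + 1/c - 1/n2},}
#' \deqn{CI = \exp(\log RR \pm z\, SE).}
#' Significance uses Fisher's exact test (two-tailed, probability-summation
#' definition). Displayed relative risks and confidence limits are truncated
#' toward zero at the shown precision; displayed percentages are rounded
#' half away from zero.
#'
#' @name cohort-statistics
NULL

check_counts <- function(a, n1, c, n2) {
  if (any(c(a, n1, c, n2) < 0) || n1 <= 0 || n2 <= 0) {
    fhc_data_error("counts must be non-negative with positive totals")
  }
  if (a > n1 || c > n2) fhc_data_error("cell count exceeds its cohort total")
}

#' Relative risk with log-normal confidence interval
#'
#' @param a carriers in the exposed cohort.
#' @param n1 exposed cohort size.
#' @param c carriers in the unexposed cohort.
#' @param n2 unexposed cohort size.
#' @param z normal quantile for the interval (default 1.959964, 95\%).
#' @param correction add 0.5 to every cell when a zero cell makes the
#'   estimate undefined (Haldane); default FALSE, in which case a zero cell
#'   yields an undefined-flagged result.
#' @param p_value compute the Fisher exact p (default TRUE).
#' @return an object of class \code{fhc_rr}: counts, \code{rr},
#'   \code{ci_low}, \code{ci_high}, \code{se_log}, \code{p_value},
#'   \code{undefined}, risks per cohort, formatted "1 in N" strings and a
#'   \code{display} list with 1- and 2-decimal truncated renderings.
#' @export
#' @examples
#' r <- relative_risk(10, 73, 17, 793)
#' r$display$rr_2dp   # 6.39
#' r$display$ci_1dp   # "3.0-13.4"
relative_risk <- function(a, n1, c, n2, z = 1.959964, correction = FALSE,
                          p_value = TRUE) {
  check_counts(a, n1, c, n2)
  undefined <- (a == 0 || c == 0)
  a0 <- a; n10 <- n1; c0 <- c; n20 <- n2
  if (undefined && correction) {
    a0 <- a + 0.5; c0 <- c + 0.5; n10 <- n1 + 0.5; n20 <- n2 + 0.5
    undefined <- FALSE
  }
  if (undefined) {
    rr <- se <- lo <- hi <- NA_real_
  } else {
    rr <- (a0 / n10) / (c0 / n20)
    se <- sqrt(1 / a0 - 1 / n10 + 1 / c0 - 1 / n20)
    lo <- exp(log(rr) - z * se)
    hi <- exp(log(rr) + z * se)
  }
  structure(list(
    a = a, n1 = n1, c = c, n2 = n2, z = z,
    rr = rr, se_log = se, ci_low = lo, ci_high = hi,
    undefined = is.na(rr),
    p_value = if (p_value) exact_test(a, n1, c, n2) else NA_real_,
    risk_exposed = a / n1, risk_unexposed = c / n2,
    pct_exposed = pct(a, n1), pct_unexposed = pct(c, n2),
    one_in_exposed = fmt_one_in(a, n1), one_in_unexposed = fmt_one_in(c, n2),
    display = if (is.na(rr)) list() else list(
      rr_1dp = trunc_dec(rr, 1), rr_2dp = trunc_dec(rr, 2),
      ci_1dp = sprintf("%.1f-%.1f", trunc_dec(lo, 1), trunc_dec(hi, 1)),
      ci_2dp = sprintf("%.2f-%.2f", trunc_dec(lo, 2), trunc_dec(hi, 2))
    )
  ), class = "fhc_rr")
}

#' @export
print.fhc_rr <- function(x, ...) {
  cat(sprintf("Relative risk: %s/%s vs %s/%s\n", x$a, x$n1, x$c, x$n2))
  if (x$undefined) {
    cat("  RR undefined (zero cell; rerun with correction = TRUE for Haldane)\n")
  } else {
    cat(sprintf("  RR %.2f (95%% CI %s), p = %.3g\n",
                trunc_dec(x$rr, 2), x$display$ci_1dp, x$p_value))
  }
  invisible(x)
}

#' Fisher's exact test for a 2x2 cohort table
#'
#' Two-tailed p by summation: the probabilities of all tables (with the
#' observed margins) no more likely than the observed one, under the
#' hypergeometric null. Exact at the cohort sizes used here.
#'
#' @inheritParams relative_risk
#' @return two-tailed p-value.
#' @export
exact_test <- function(a, n1, c, n2) {
  check_counts(a, n1, c, n2)
  m <- a + c              # carriers overall
  n <- (n1 - a) + (n2 - c)
  k <- n1
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Concordance partition of carrier status against family-history risk
#'
#' For the family-history-available subset: carriers at increased risk and
#' non-carriers at average risk are concordant; the off-diagonal cells
#' (carrier/average, non-carrier/increased) are discordant.
#'
#' @param assessments tibble with \code{fh_cohort} (must be increased or
#'   average for every record) and \code{is_carrier}.
#' @return list: \code{cells} (2x2 matrix carriers x cohort), per-cell
#'   percentages of the subset total, \code{concordant}, \code{discordant},
#'   \code{total}.
#' @export
concordance_table <- function(assessments) {
  bad <- !assessments$fh_cohort %in% c("increased", "average")
  if (any(bad)) {
    fhc_data_error("concordance_table expects only FH-available records; ",
                   sum(bad), " record(s) have fh_cohort = not_available")
  }
  a <- sum(assessments$is_carrier & assessments$fh_cohort == "increased")
  b <- sum(assessments$is_carrier & assessments$fh_cohort == "average")
  c_ <- sum(!assessments$is_carrier & assessments$fh_cohort == "increased")
  d <- sum(!assessments$is_carrier & assessments$fh_cohort == "average")
  total <- nrow(assessments)
  cells <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                  dimnames = list(c("carrier", "non_carrier"),
                                  c("increased", "average")))
  list(cells = cells,
       pct = matrix(pct(c(a, c_, b, d), total), 2, 2,
                    dimnames = dimnames(cells)),
       concordant = a + d, discordant = b + c_,
       pct_concordant = pct(a + d, total), pct_discordant = pct(b + c_, total),
       total = total)
}

rr_block <- function(assessments, carrier_col, cohort_a, cohort_b, z, correction) {
  ga <- assessments$fh_cohort == cohort_a
  gb <- assessments$fh_cohort == cohort_b
  if (!any(ga) || !any(gb)) return(NULL)
  relative_risk(sum(assessments[[carrier_col]][ga]), sum(ga),
                sum(assessments[[carrier_col]][gb]), sum(gb),
                z = z, correction = correction)
}

#' Cohort report: carrier prevalence, enrichment and concordance
#'
#' Builds the analysis report for a cohort of participant assessments:
#' per-cohort carrier counts and percentages for the full panel and for the
#' ACMG SF subset, relative-risk comparisons (increased vs average and
#' increased vs FH-not-available), the concordance partition of the
#' FH-available subset, and an optional sensitivity comparison that removes
#' designated participants before recomputing the increased-vs-average
#' relative risk. Comparisons against an empty cohort are suppressed and the
#' cohort flagged.
#'
#' @param assessments tibble with one row per participant:
#'   \code{participant_id}, \code{fh_cohort}, \code{is_carrier},
#'   \code{acmg_sf_carrier}.
#' @param z normal quantile for intervals.
#' @param correction Haldane zero-cell correction flag, passed through.
#' @param exclude_participants participant ids removed (entirely) for the
#'   sensitivity comparison; NULL for none.
#' @return a list of class \code{fhc_report} (see sections \code{cohorts},
#'   \code{rr}, \code{concordance}, \code{sensitivity}).
#' @export
cohort_report <- function(assessments, z = 1.959964, correction = FALSE,
                          exclude_participants = NULL) {
  stopifnot(all(c("participant_id", "fh_cohort", "is_carrier", "acmg_sf_carrier")
                %in% names(assessments)))
  cohorts <- c("increased", "average", "not_available")
  sizes <- vapply(cohorts, function(g) sum(assessments$fh_cohort == g), 1L,
                  USE.NAMES = FALSE)
  carr <- vapply(cohorts, function(g)
    sum(assessments$is_carrier[assessments$fh_cohort == g]), 1L, USE.NAMES = FALSE)
  sfcarr <- vapply(cohorts, function(g)
    sum(assessments$acmg_sf_carrier[assessments$fh_cohort == g]), 1L,
    USE.NAMES = FALSE)
  cohort_tbl <- tibble::tibble(
    fh_cohort = cohorts, n = sizes,
    carriers = carr, pct_carriers = ifelse(sizes > 0, pct(carr, sizes), NA),
    one_in = mapply(fmt_one_in, carr, sizes, USE.NAMES = FALSE),
    sf_carriers = sfcarr, pct_sf_carriers = ifelse(sizes > 0, pct(sfcarr, sizes), NA),
    one_in_sf = mapply(fmt_one_in, sfcarr, sizes, USE.NAMES = FALSE)
  )
  empty <- cohorts[sizes == 0]

  rr <- list(
    panel_increased_vs_average =
      rr_block(assessments, "is_carrier", "increased", "average", z, correction),
    panel_increased_vs_not_available =
      rr_block(assessments, "is_carrier", "increased", "not_available", z, correction),
    sf_increased_vs_average =
      rr_block(assessments, "acmg_sf_carrier", "increased", "average", z, correction),
    sf_increased_vs_not_available =
      rr_block(assessments, "acmg_sf_carrier", "increased", "not_available", z, correction)
  )

  avail <- assessments[assessments$fh_cohort != "not_available", , drop = FALSE]
  conc <- if (nrow(avail)) concordance_table(avail) else NULL

  sens <- NULL
  if (!is.null(exclude_participants)) {
    kept <- assessments[!assessments$participant_id %in% exclude_participants, , drop = FALSE]
    sens <- list(
      excluded = intersect(exclude_participants, assessments$participant_id),
      panel_increased_vs_average =
        rr_block(kept, "is_carrier", "increased", "average", z, correction)
    )
  }

  structure(list(
    total = nrow(assessments),
    carriers_total = sum(assessments$is_carrier),
    pct_carriers_total = pct(sum(assessments$is_carrier), nrow(assessments)),
    cohorts = cohort_tbl, empty_cohorts = empty,
    rr = rr, concordance = conc, sensitivity = sens
  ), class = "fhc_report")
}

#' @export
print.fhc_report <- function(x, ...) {
  cat(sprintf("Cohort of %d participants, %d carriers (%.1f%%)\n",
              x$total, x$carriers_total, x$pct_carriers_total))
  print(x$cohorts)
  if (!is.null(x$rr$panel_increased_vs_average)) {
    cat("\nFull panel, increased vs average FH risk:\n")
    print(x$rr$panel_increased_vs_average)
  }
  if (!is.null(x$concordance)) {
    cat(sprintf("\nConcordant %d (%.1f%%), discordant %d (%.1f%%)\n",
                x$concordance$concordant, x$concordance$pct_concordant,
                x$concordance$discordant, x$concordance$pct_discordant))
  }
  invisible(x)
}

# JSON-serialisable view of a report (used by the pipeline writer)
report_to_list <- function(report) {
  rr_list <- function(r) {
    if (is.null(r)) return(NULL)
    list(a = r$a, n1 = r$n1, c = r$c, n2 = r$n2,
         rr = r$rr, ci_low = r$ci_low, ci_high = r$ci_high,
         rr_display = if (r$undefined) NULL else r$display$rr_2dp,
         ci_display = if (r$undefined) NULL else r$display$ci_1dp,
         p_value = r$p_value, undefined = r$undefined)
  }
  list(
    total = report$total, carriers_total = report$carriers_total,
    pct_carriers_total = report$pct_carriers_total,
    cohorts = report$cohorts,
    rr = lapply(report$rr, rr_list),
    concordance = if (is.null(report$concordance)) NULL else list(
      cells = report$concordance$cells,
      concordant = report$concordance$concordant,
      discordant = report$concordance$discordant,
      pct_concordant = report$concordance$pct_concordant,
      pct_discordant = report$concordance$pct_discordant
    ),
    sensitivity = if (is.null(report$sensitivity)) NULL else list(
      excluded = report$sensitivity$excluded,
      panel_increased_vs_average = rr_list(report$sensitivity$panel_increased_vs_average)
    )
  )
}
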