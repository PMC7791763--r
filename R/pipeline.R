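#' End-to-end pipeline orchestration
#'
#' \code{run_pipeline} ties the modules together on files: read and validate
#' the gene panel, read variants (VCF + annotation), triage and assign
#' carrier status, read pedigrees and assess family-history risk, join into
#' per-participant assessments and emit the concordance/relative-risk report
#' plus a run manifest (input checksums and thresholds) for provenance.
#' Per-stage record counts are logged as messages, mirroring a curation
#' funnel (input / retained / excluded).
#'
#' @name pipeline
NULL

#' Run the full triage + family-history + concordance pipeline
#'
#' @param vcf_path multi- or single-sample VCF v4.2.
#' @param annotation_path per-site annotation TSV.
#' @param pedigree_dir directory of pedigree JSON files (one per
#'   participant; participants without collected history have
#'   \code{fh_available = false}).
#' @param out_dir output directory; created if needed.
#' @param panel_path gene panel file (default: packaged 95-gene panel).
#' @param ruleset_path family-history ruleset YAML (default: packaged).
#' @param maf_threshold rarity bound for the frequency filter.
#' @param z normal quantile for confidence intervals.
#' @param correction Haldane zero-cell correction flag.
#' @param exclude_participants participant ids for the sensitivity
#'   comparison (removed entirely before recomputing the increased-vs-average
#'   relative risk); NULL to skip.
#' @return the \code{fhc_report}, invisibly. Side effects in \code{out_dir}:
#'   \code{classified_variants.tsv}, \code{carrier_status.json},
#'   \code{assessments.tsv}, \code{report.json}, \code{manifest.json}.
#' @export
run_pipeline <- function(vcf_path, annotation_path, pedigree_dir, out_dir,
                         panel_path = fhc_extdata("cancer_panel_95.tsv"),
                         ruleset_path = fhc_extdata("fh_rules.yaml"),
                         maf_threshold = 0.01, z = 1.959964,
                         correction = FALSE, exclude_participants = NULL) {
  for (p in c(vcf_path, annotation_path, pedigree_dir, panel_path, ruleset_path)) {
    if (!file.exists(p)) fhc_config_error("input path does not exist: ", p)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  panel <- load_panel(panel_path)
  ruleset <- load_fh_ruleset(ruleset_path)

  variants <- read_variants(vcf_path, annotation_path, panel)
  message("variants: ", nrow(variants), " on-panel records (",
          attr(variants, "off_panel") %||% 0, " off-panel dropped)")

  classified <- triage_cohort(variants, panel, maf_threshold)
  message("triage: ", sum(classified$route != "excluded"), " retained (",
          sum(classified$route %in% c("clinvar_lp_p", "lof_candidate", "insilico_candidate")),
          " candidates, ", sum(classified$route == "vus_pool"), " VUS pool), ",
          sum(classified$route == "excluded"), " excluded")

  peds <- read_pedigrees(pedigree_dir)
  message("pedigrees: ", nrow(peds$fh), " participants, ",
          sum(peds$fh$fh_available), " with family history")

  status <- assign_carrier_status(classified, panel,
                                  participants = peds$fh$participant_id)
  fh_res <- assess_fh_cohort(peds$cases, peds$fh, ruleset)

  assessments <- dplyr::inner_join(status, fh_res, by = "participant_id")
  message("assessments: ", nrow(assessments), " participants, ",
          sum(assessments$is_carrier), " carriers")

  report <- cohort_report(assessments, z = z, correction = correction,
                          exclude_participants = exclude_participants)

  readr::write_tsv(classified, file.path(out_dir, "classified_variants.tsv"), na = "")
  jsonlite::write_json(status, file.path(out_dir, "carrier_status.json"),
                       dataframe = "rows", auto_unbox = TRUE, na = "null")
  readr::write_tsv(assessments, file.path(out_dir, "assessments.tsv"), na = "")
  jsonlite::write_json(report_to_list(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, na = "null", digits = NA, matrix = "rowmajor")

  manifest <- list(
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(c(vcf_path, annotation_path, panel_path, ruleset_path))),
      c("vcf", "annotation", "panel", "ruleset"))),
    n_pedigrees = nrow(peds$fh),
    thresholds = list(maf = maf_threshold, z = z, correction = correction),
    excluded = exclude_participants,
    package_version = as.character(utils::packageVersion("fhconcord"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, na = "null")
  invisible(report)
}
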