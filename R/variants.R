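#' Variant input
#'
#' The pipeline starts from called, annotated variants: a VCF v4.2 file
#' (single- or multi-sample; carriage read from the GT field) joined to a
#' per-site annotation table keyed by chrom/pos/ref/alt. Annotation columns:
#' \code{chrom, pos, ref, alt, gene, hgvs_c, hgvs_p, consequence, af_local,
#' af_gnomad, clinvar_assertion, has_lp_or_p_entry, revel}. One variant
#' record is one annotated variant observed in one participant.
#'
#' @name variant-input
NULL

LOF_CONSEQUENCES <- c("frameshift_indel", "stopgain", "stoploss", "essential_splice")
CONSEQUENCE_LEVELS <- c("missense", LOF_CONSEQUENCES, "inframe_indel",
                        "synonymous", "intronic", "other")
CLINVAR_LEVELS <- c("pathogenic", "likely_pathogenic", "vus", "likely_benign",
                    "benign", "conflicting", "absent")

annotation_cols <- function() {
  readr::cols(
    chrom = readr::col_character(), pos = readr::col_double(),
    ref = readr::col_character(), alt = readr::col_character(),
    gene = readr::col_character(), hgvs_c = readr::col_character(),
    hgvs_p = readr::col_character(), consequence = readr::col_character(),
    af_local = readr::col_double(), af_gnomad = readr::col_double(),
    clinvar_assertion = readr::col_character(),
    has_lp_or_p_entry = readr::col_logical(), revel = readr::col_double()
  )
}

validate_variants <- function(v) {
  if (any(v$pos < 1)) fhc_data_error("variant positions must be >= 1")
  if (any(v$ref == v$alt)) fhc_data_error("ref and alt alleles must differ")
  for (col in c("af_local", "af_gnomad", "revel")) {
    x <- v[[col]]
    if (any(!is.na(x) & (x < 0 | x > 1))) fhc_data_error(col, " must lie in [0, 1]")
  }
  bad <- setdiff(unique(v$consequence), CONSEQUENCE_LEVELS)
  if (length(bad)) fhc_data_error("unknown consequence term(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(v$clinvar_assertion), CLINVAR_LEVELS)
  if (length(bad)) fhc_data_error("unknown clinvar_assertion term(s): ", paste(bad, collapse = ", "))
  invisible(v)
}

#' Read per-participant variant records from a VCF plus annotation table
#'
#' Joins VCF records to the annotation table by (chrom, pos, ref, alt) and
#' expands them to one record per carrying participant (GT containing at
#' least one alternate allele). Records in genes outside the panel are
#' dropped and counted in the \code{off_panel} attribute.
#'
#' @param vcf_path VCF v4.2 file.
#' @param annotation_path tab-separated annotation table.
#' @param panel validated gene panel scoping the analysis.
#' @return tibble of variant records (participant_id, gene, coordinates,
#'   annotations, zygosity het/hom/hemi), with attribute \code{off_panel}.
#' @export
read_variants <- function(vcf_path, annotation_path, panel) {
  if (!file.exists(vcf_path)) fhc_data_error("VCF file not found: ", vcf_path)
  if (!file.exists(annotation_path)) fhc_data_error("annotation file not found: ", annotation_path)
  ann <- readr::read_tsv(annotation_path, col_types = annotation_cols(), na = c("", "NA", "."))
  ann$clinvar_assertion[is.na(ann$clinvar_assertion)] <- "absent"
  ann$has_lp_or_p_entry[is.na(ann$has_lp_or_p_entry)] <- FALSE
  key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")
  ann$.key <- key(ann$chrom, ann$pos, ann$ref, ann$alt)
  dup <- unique(ann$.key[duplicated(ann$.key)])
  if (length(dup)) {
    fhc_data_error("duplicated annotation key(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) {
    out <- empty_variant_tbl()
    attr(out, "off_panel") <- 0L
    return(out)
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  vkey <- key(fix$CHROM, as.numeric(fix$POS), fix$REF, fix$ALT)
  missing_ann <- setdiff(vkey, ann$.key)
  if (length(missing_ann)) {
    fhc_data_error("VCF record(s) with no annotation row: ",
                   paste(utils::head(missing_ann, 5), collapse = ", "))
  }
  orphan <- setdiff(ann$.key, vkey)
  if (length(orphan)) {
    fhc_data_error("annotation row(s) with no matching VCF record: ",
                   paste(utils::head(orphan, 5), collapse = ", "))
  }

  gt <- vcfR::extract.gt(vcf)
  if (is.null(gt)) fhc_data_error("VCF has no GT genotypes: ", vcf_path)
  zyg <- gt_to_zygosity(gt)
  idx <- which(!is.na(zyg), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    out <- empty_variant_tbl()
    attr(out, "off_panel") <- 0L
    return(out)
  }
  obs <- tibble::tibble(
    participant_id = colnames(gt)[idx[, 2]],
    .key = vkey[idx[, 1]],
    zygosity = zyg[idx]
  )
  out <- dplyr::inner_join(obs, ann, by = ".key")
  off <- !(out$gene %in% panel$symbol)
  n_off <- sum(off)
  if (n_off) {
    message(n_off, " variant record(s) in off-panel genes dropped (",
            paste(unique(out$gene[off]), collapse = ", "), ")")
  }
  out <- out[!off, setdiff(names(out), ".key")]
  out <- out[, c("participant_id", setdiff(names(out), c("participant_id", "zygosity")), "zygosity")]
  validate_variants(out)
  attr(out, "off_panel") <- n_off
  out
}

gt_to_zygosity <- function(gt) {
  z <- matrix(NA_character_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  z[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
  z[gt %in% c("1/1", "1|1")] <- "hom"
  z[gt %in% "1"] <- "hemi"
  z
}

empty_variant_tbl <- function() {
  tibble::tibble(
    participant_id = character(), chrom = character(), pos = double(),
    ref = character(), alt = character(), gene = character(),
    hgvs_c = character(), hgvs_p = character(), consequence = character(),
    af_local = double(), af_gnomad = double(), clinvar_assertion = character(),
    has_lp_or_p_entry = logical(), revel = double(), zygosity = character()
  )
}

maf_below <- function(variants, threshold) {
  (is.na(variants$af_local) | variants$af_local < threshold) &
    (is.na(variants$af_gnomad) | variants$af_gnomad < threshold)
}

#' Retain rare variants
#'
#' A record passes when it is below \code{threshold} in BOTH frequency
#' sources (an absent frequency counts as a pass); the comparison is strict,
#' so a frequency exactly at the threshold is excluded. Idempotent.
#'
#' @param variants variant tibble.
#' @param threshold minor allele frequency bound in (0, 1]; default 0.01.
#' @return the retained subset.
#' @export
frequency_filter <- function(variants, threshold = 0.01) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    fhc_config_error("frequency threshold must lie in (0, 1]")
  }
  variants[maf_below(variants, threshold), , drop = FALSE]
}
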