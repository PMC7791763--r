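#' ACMG-AMP evidence codes and combining rules
#'
#' Variant classification follows the standard ACMG-AMP framework: a variant
#' accumulates evidence codes (pathogenic side: PVS1, PS1-PS4, PM1-PM6,
#' PP1-PP5; benign side: BA1, BS1-BS4, BP1-BP7) which a fixed rule table
#' combines into one of five classes: P (pathogenic), LP (likely pathogenic),
#' VUS (uncertain), LB (likely benign), B (benign). The rule table ships as
#' an editable YAML config; evidence meeting both a pathogenic-side and a
#' benign-side rule is conflicting and resolves to VUS, which is how a
#' deterministic pipeline renders classifications that a clinical team would
#' settle by discussion.
#'
#' @name acmg-evidence
NULL

#' The closed ACMG-AMP evidence vocabulary
#'
#' @return character vector of the 28 valid evidence codes.
#' @export
acmg_vocabulary <- function() {
  c("PVS1",
    paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
    "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
}

#' Load an ACMG combining-rule table
#'
#' @param path YAML rule table; defaults to the packaged standard table.
#' @return a named list of classes, each a list of minimal requirements.
#' @export
load_acmg_rules <- function(path = fhc_extdata("acmg_rules.yaml")) {
  rules <- yaml::read_yaml(path)
  need <- c("P", "LP", "B", "LB")
  if (!all(need %in% names(rules))) {
    fhc_config_error("ACMG rule table must define classes ", paste(need, collapse = ", "))
  }
  rules
}

# counts of each code kind in one evidence set
acmg_counts <- function(codes) {
  c(PVS1 = sum(codes == "PVS1"),
    PS = sum(startsWith(codes, "PS")),
    PM = sum(startsWith(codes, "PM")),
    PP = sum(startsWith(codes, "PP")),
    BA1 = sum(codes == "BA1"),
    BS = sum(startsWith(codes, "BS")),
    BP = sum(startsWith(codes, "BP")))
}

rule_met <- function(counts, reqs) {
  any(vapply(reqs, function(r) all(counts[names(r)] >= unlist(r)), TRUE))
}

#' Combine ACMG-AMP evidence codes into a final class
#'
#' Deterministic combination per the standard rule table: e.g. PVS1 plus one
#' strong code is Pathogenic, PVS1 plus one moderate code is Likely
#' pathogenic, BA1 alone is Benign, two supporting benign codes are Likely
#' benign; evidence meeting neither side, or meeting both sides
#' (conflicting), is VUS.
#'
#' @param codes character vector of evidence codes (possibly empty), or a
#'   single semicolon-separated string.
#' @param rules rule table from \code{\link{load_acmg_rules}}.
#' @return one of \code{"P"}, \code{"LP"}, \code{"VUS"}, \code{"LB"}, \code{"B"}.
#' @export
#' @examples
#' combine_acmg_evidence(c("PVS1", "PM2"))   # "LP"
#' combine_acmg_evidence("BA1")              # "B"
#' combine_acmg_evidence(character())        # "VUS"
combine_acmg_evidence <- function(codes, rules = load_acmg_rules()) {
  if (length(codes) == 1 && grepl(";", codes)) codes <- strsplit(codes, ";")[[1]]
  codes <- unique(codes[nzchar(codes)])
  bad <- setdiff(codes, acmg_vocabulary())
  if (length(bad)) {
    fhc_config_error("unknown ACMG evidence code(s): ", paste(bad, collapse = ", "))
  }
  n <- acmg_counts(codes)
  path_side <- rule_met(n, rules$P) || rule_met(n, rules$LP)
  benign_side <- rule_met(n, rules$B) || rule_met(n, rules$LB)
  if (path_side && benign_side) return("VUS")
  if (rule_met(n, rules$P)) return("P")
  if (rule_met(n, rules$LP)) return("LP")
  if (rule_met(n, rules$B)) return("B")
  if (rule_met(n, rules$LB)) return("LB")
  "VUS"
}

# vectorised combiner over semicolon-separated evidence strings
combine_acmg_many <- function(evidence_strings, rules = load_acmg_rules()) {
  vapply(strsplit(evidence_strings, ";", fixed = TRUE),
         combine_acmg_evidence, "", rules = rules)
}

#' Automated evidence assignment from variant annotations
#'
#' Assigns the subset of ACMG codes that can be derived mechanically from a
#' variant's annotations, emulating an automated pre-classifier:
#' \itemize{
#'   \item PVS1: loss-of-function consequence in a gene with established
#'     haploinsufficiency;
#'   \item PM2: absent or extremely rare (< \code{pm2_max_af}) in both
#'     population frequency sources;
#'   \item PP3 / BP4: in-silico ensemble score above \code{revel_pathogenic} /
#'     below \code{revel_benign};
#'   \item PP5 / BP6: a reported pathogenic-side / benign assertion in the
#'     variant database annotation;
#'   \item BA1: allele frequency above \code{ba1_af} in either source.
#' }
#' Manually curated codes (segregation, functional, de novo...) are outside
#' automation scope and are simply absent.
#'
#' @param variants variant tibble (see \code{\link{read_variants}}).
#' @param panel validated gene panel.
#' @param pm2_max_af PM2 rarity bound (default 1e-4).
#' @param revel_pathogenic PP3 threshold (default 0.7, strict >).
#' @param revel_benign BP4 threshold (default 0.3, strict <).
#' @param ba1_af BA1 stand-alone frequency bound (default 0.05, strict >).
#' @return character vector of semicolon-separated evidence codes, one per row.
#' @export
assign_evidence <- function(variants, panel, pm2_max_af = 1e-4,
                            revel_pathogenic = 0.7, revel_benign = 0.3,
                            ba1_af = 0.05) {
  hap <- panel$haploinsufficient[match(variants$gene, panel$symbol)]
  lof <- variants$consequence %in% LOF_CONSEQUENCES
  pvs1 <- lof & !is.na(hap) & hap == "yes"
  pm2 <- (is.na(variants$af_local) | variants$af_local < pm2_max_af) &
    (is.na(variants$af_gnomad) | variants$af_gnomad < pm2_max_af)
  pp3 <- !is.na(variants$revel) & variants$revel > revel_pathogenic
  bp4 <- !is.na(variants$revel) & variants$revel < revel_benign
  pp5 <- variants$has_lp_or_p_entry %in% TRUE
  bp6 <- variants$clinvar_assertion %in% c("benign", "likely_benign")
  ba1 <- (!is.na(variants$af_local) & variants$af_local > ba1_af) |
    (!is.na(variants$af_gnomad) & variants$af_gnomad > ba1_af)
  codes <- cbind(PVS1 = pvs1, PM2 = pm2, PP3 = pp3, BP4 = bp4,
                 PP5 = pp5, BP6 = bp6, BA1 = ba1)
  apply(codes, 1L, function(row) paste(colnames(codes)[row], collapse = ";"))
}
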