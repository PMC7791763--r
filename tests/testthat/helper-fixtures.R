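# shared fixtures and independent oracles

small_panel <- function() {
  validate_panel(tibble::tibble(
    symbol = c("BRCA1", "BRCA2", "MUTYH", "GPC3", "CDK4", "TERT"),
    inheritance = c("AD", "AD", "AR", "XL", "AD", "AD"),
    haploinsufficient = c("yes", "yes", "yes", "yes", "no", "unknown"),
    acmg_sf = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    cancer_types = c("breast;ovarian", "breast;ovarian", "colorectal",
                     "wilms", "melanoma", "melanoma"),
    transcript = NA_character_
  ))
}

# a variant record row with overridable fields
make_variant <- function(..., participant_id = "P1", gene = "BRCA1",
                         chrom = "17", pos = 100, ref = "C", alt = "T",
                         hgvs_c = NA_character_, hgvs_p = NA_character_,
                         consequence = "missense", af_local = NA_real_,
                         af_gnomad = NA_real_, clinvar_assertion = "absent",
                         has_lp_or_p_entry = FALSE, revel = NA_real_,
                         zygosity = "het") {
  tibble::tibble(participant_id = participant_id, chrom = chrom, pos = pos,
                 ref = ref, alt = alt, gene = gene, hgvs_c = hgvs_c,
                 hgvs_p = hgvs_p, consequence = consequence,
                 af_local = af_local, af_gnomad = af_gnomad,
                 clinvar_assertion = clinvar_assertion,
                 has_lp_or_p_entry = has_lp_or_p_entry, revel = revel,
                 zygosity = zygosity, ...)
}

make_pedigree <- function(id = "P1", relatives = list(), fh_available = TRUE) {
  parse_pedigree(list(participant_id = id, fh_available = fh_available,
                      relatives = relatives))
}

rel <- function(relation, condition = NULL, age = NULL, sex = "F",
                lineage = NULL, id = NULL) {
  dx <- if (is.null(condition)) list() else
    list(list(condition = condition, age = age))
  out <- list(relation = relation, sex = sex, diagnoses = dx)
  if (!is.null(lineage)) out$lineage <- lineage
  if (!is.null(id)) out$id <- id
  out
}

# --- independent ACMG oracle: a literal transcription of the combining
# rules as nested conditions, sharing no code with the implementation
acmg_oracle <- function(codes) {
  pvs <- sum(codes == "PVS1")
  ps <- length(grep("^PS[1-4]$", codes))
  pm <- length(grep("^PM[1-6]$", codes))
  pp <- length(grep("^PP[1-5]$", codes))
  ba <- sum(codes == "BA1")
  bs <- length(grep("^BS[1-4]$", codes))
  bp <- length(grep("^BP[1-7]$", codes))

  path <- (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp >= 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  lpath <- (pvs >= 1 && pm == 1) ||
    (ps == 1 && pm >= 1 && pm <= 2) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  ben <- ba >= 1 || bs >= 2
  lben <- (bs == 1 && bp >= 1) || bp >= 2

  if ((path || lpath) && (ben || lben)) return("VUS")
  if (path) return("P")
  if (lpath) return("LP")
  if (ben) return("B")
  if (lben) return("LB")
  "VUS"
}

# --- independent Fisher oracle: enumerate every 2x2 table with the observed
# margins via binomial coefficients and sum the probabilities of tables no
# more probable than the observed one
fisher_oracle <- function(a, n1, c, n2) {
  b <- n1 - a; d <- n2 - c
  r1 <- a + b; r2 <- c + d; m <- a + c; n <- r1 + r2
  xs <- max(0, m - r2):min(r1, m)
  lp <- lchoose(r1, xs) + lchoose(r2, m - xs) - lchoose(n, m)
  lp_obs <- lchoose(r1, a) + lchoose(r2, m - a) - lchoose(n, m)
  min(1, sum(exp(lp[lp <= lp_obs + 1e-7])))
}
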