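#' Variant triage
#'
#' Triage turns per-participant variant records into classified variants and
#' carrier calls, mirroring a curation flowchart:
#' \enumerate{
#'   \item frequency filter (strictly below 1\% in both population sources);
#'   \item candidate selection by three ordered routes — (1) a reported
#'     likely-pathogenic/pathogenic database entry, (2) loss-of-function
#'     consequence in a haploinsufficient panel gene with MAF < 1\%,
#'     (3) absent from the variant database, MAF < 1\% and a high in-silico
#'     score (REVEL > 0.7);
#'   \item ACMG-AMP evidence combination into P/LP/VUS/LB/B;
#'   \item the remaining rare variants form the VUS pool, with a
#'     potential-pathogenic flag (REVEL > 0.7 and database status absent or
#'     VUS).
#' }
#' Family history is never an input to any step here; the module boundary
#' enforces that classification is blind to pedigree data.
#'
#' @name variant-triage
NULL

ROUTE_LEVELS <- c("clinvar_lp_p", "lof_candidate", "insilico_candidate",
                  "vus_pool", "excluded")

check_panel_scope <- function(variants, panel) {
  off <- setdiff(unique(variants$gene), panel$symbol)
  if (length(off)) {
    fhc_data_error("variant(s) in gene(s) absent from panel: ",
                   paste(off, collapse = ", "))
  }
}

#' Select likely-pathogenic/pathogenic candidate variants
#'
#' Routes a variant for classification when it satisfies any of the three
#' criteria, checked in fixed order (database entry > loss-of-function >
#' in-silico), first match recorded:
#' \enumerate{
#'   \item \code{clinvar_lp_p}: at least one likely-pathogenic or pathogenic
#'     database entry (applies in exonic and intronic regions alike);
#'   \item \code{lof_candidate}: protein-disrupting consequence (small
#'     insertion/deletion, stopgain, stoploss, essential splice) with
#'     MAF < threshold in a gene with established haploinsufficiency;
#'   \item \code{insilico_candidate}: absent from the database, MAF <
#'     threshold, REVEL strictly > 0.7.
#' }
#' Loss-of-function variants in genes whose haploinsufficiency is not
#' established are not auto-routed; they are flagged \code{needs_review}.
#'
#' @param variants variant tibble (rare set for routes 2-3; the MAF test is
#'   applied internally so unfiltered input is handled correctly).
#' @param panel validated gene panel.
#' @param maf_threshold rarity bound, default 0.01.
#' @param revel_threshold in-silico bound, default 0.7 (strict >).
#' @return input rows that were routed, with columns \code{route} and
#'   \code{needs_review}; unrouted LoF variants needing manual review are
#'   attached as attribute \code{manual_review}.
#' @export
select_lp_candidates <- function(variants, panel, maf_threshold = 0.01,
                                 revel_threshold = 0.7) {
  check_panel_scope(variants, panel)
  hap <- panel$haploinsufficient[match(variants$gene, panel$symbol)]
  rare <- maf_below(variants, maf_threshold)
  lof <- variants$consequence %in% LOF_CONSEQUENCES

  r1 <- variants$has_lp_or_p_entry %in% TRUE
  r2 <- lof & rare & hap == "yes"
  r3 <- variants$clinvar_assertion == "absent" & rare &
    !is.na(variants$revel) & variants$revel > revel_threshold
  route <- rep(NA_character_, nrow(variants))
  route[r3] <- "insilico_candidate"
  route[r2] <- "lof_candidate"
  route[r1] <- "clinvar_lp_p"

  review <- lof & rare & hap == "unknown" & is.na(route)
  out <- variants[!is.na(route), , drop = FALSE]
  out$route <- route[!is.na(route)]
  out$needs_review <- FALSE
  attr(out, "manual_review") <- variants[review, , drop = FALSE]
  out
}

#' Select the pool of variants of uncertain significance
#'
#' From rare variants not already routed as candidates, keeps those whose
#' automated evidence class is VUS (emulating an automated pre-classifier
#' restricted to mechanically derivable codes; see
#' \code{\link{assign_evidence}}). Each pool member carries
#' \code{potential_pathogenic}: REVEL > 0.7 and database status absent or
#' VUS.
#'
#' @param variants rare, unrouted variant tibble.
#' @param panel validated gene panel.
#' @param maf_threshold rarity bound, default 0.01 (re-applied defensively).
#' @param revel_threshold potential-pathogenicity bound, default 0.7.
#' @param acmg_rules combining-rule table.
#' @return pool tibble with \code{route = "vus_pool"}, \code{evidence},
#'   \code{final_class = "VUS"} and \code{potential_pathogenic}; variants
#'   automatically classed LB/B are attached as attribute \code{benign}.
#' @export
select_vus <- function(variants, panel, maf_threshold = 0.01,
                       revel_threshold = 0.7, acmg_rules = load_acmg_rules()) {
  variants <- frequency_filter(variants, maf_threshold)
  if (nrow(variants) == 0) {
    variants$route <- character()
    variants$evidence <- character()
    variants$final_class <- character()
    variants$potential_pathogenic <- logical()
    return(variants)
  }
  ev <- assign_evidence(variants, panel)
  cls <- combine_acmg_many(ev, acmg_rules)
  pool <- cls == "VUS"
  out <- variants[pool, , drop = FALSE]
  out$route <- "vus_pool"
  out$evidence <- ev[pool]
  out$final_class <- "VUS"
  out$potential_pathogenic <- !is.na(out$revel) & out$revel > revel_threshold &
    out$clinvar_assertion %in% c("absent", "vus")
  benign <- variants[!pool, , drop = FALSE]
  benign$final_class <- cls[!pool]
  attr(out, "benign") <- benign
  out
}

#' Run the full variant triage on a cohort
#'
#' Applies the frequency filter, the three candidate-selection routes, ACMG
#' evidence combination and VUS-pool selection to every record, returning
#' one classified row per input record. Triage is a pure function of its
#' inputs and configuration: identical inputs give identical output.
#'
#' @param variants variant tibble from \code{\link{read_variants}} (or the
#'   simulator).
#' @param panel validated gene panel.
#' @param maf_threshold rarity bound, default 0.01.
#' @param acmg_rules combining-rule table.
#' @return classified tibble: all input columns plus \code{route},
#'   \code{evidence}, \code{final_class} (NA for excluded records),
#'   \code{clinically_actionable}, \code{potential_pathogenic},
#'   \code{needs_review}, \code{exclusion_reason}.
#' @export
triage_cohort <- function(variants, panel, maf_threshold = 0.01,
                          acmg_rules = load_acmg_rules()) {
  check_panel_scope(variants, panel)
  v <- variants
  v$.row <- seq_len(nrow(v))

  rare <- maf_below(v, maf_threshold)
  common <- v[!rare, , drop = FALSE]
  v_rare <- v[rare, , drop = FALSE]

  cand <- select_lp_candidates(v_rare, panel, maf_threshold)
  review_rows <- attr(cand, "manual_review")$.row %||% integer()
  if (nrow(cand)) {
    ev <- assign_evidence(cand, panel)
    cls <- character(nrow(cand))
    adopt <- cand$route == "clinvar_lp_p" &
      cand$clinvar_assertion %in% c("pathogenic", "likely_pathogenic")
    cls[adopt] <- ifelse(cand$clinvar_assertion[adopt] == "pathogenic", "P", "LP")
    cls[!adopt] <- combine_acmg_many(ev[!adopt], acmg_rules)
    cand$evidence <- ev
    cand$final_class <- cls
  } else {
    cand$evidence <- character()
    cand$final_class <- character()
  }

  rest <- v_rare[!(v_rare$.row %in% cand$.row), , drop = FALSE]
  pool <- select_vus(rest, panel, maf_threshold, acmg_rules = acmg_rules)
  benign <- attr(pool, "benign") %||% rest[0, ]

  out <- v
  out$route <- "excluded"
  out$evidence <- NA_character_
  out$final_class <- NA_character_
  out$potential_pathogenic <- FALSE
  out$needs_review <- FALSE
  out$exclusion_reason <- NA_character_

  set <- function(rows, col, val) {
    out[[col]][match(rows, out$.row)] <<- val
  }
  if (nrow(common)) set(common$.row, "exclusion_reason", "common_af")
  if (nrow(cand)) {
    set(cand$.row, "route", cand$route)
    set(cand$.row, "evidence", cand$evidence)
    set(cand$.row, "final_class", cand$final_class)
  }
  if (nrow(pool)) {
    set(pool$.row, "route", "vus_pool")
    set(pool$.row, "evidence", pool$evidence)
    set(pool$.row, "final_class", "VUS")
    set(pool$.row, "potential_pathogenic", pool$potential_pathogenic)
  }
  if (nrow(benign)) set(benign$.row, "exclusion_reason", "benign_automated")
  if (length(review_rows)) set(review_rows, "needs_review", TRUE)
  out$exclusion_reason[out$route == "excluded" & is.na(out$exclusion_reason)] <- "off_route"

  inh <- panel$inheritance[match(out$gene, panel$symbol)]
  plp <- !is.na(out$final_class) & out$final_class %in% c("P", "LP")
  out$clinically_actionable <- plp &
    (inh %in% c("AD", "XL") | (inh == "AR" & out$zygosity == "hom"))
  out$.row <- NULL
  out
}

#' Assign per-participant carrier status
#'
#' A participant is a carrier of a clinically actionable variant when they
#' hold at least one P/LP variant in an autosomal-dominant or X-linked panel
#' gene, or a biallelic P/LP genotype (homozygous, or two distinct
#' heterozygous P/LP variants, assumed in trans) in an autosomal-recessive
#' gene. A single heterozygous P/LP variant in an AR gene is reported as
#' recessive carriage only and does not make the participant a carrier.
#' \code{acmg_sf_carrier} is the same call restricted to the ACMG SF subset
#' of the panel.
#'
#' @param classified classified tibble from \code{\link{triage_cohort}}.
#' @param panel validated gene panel.
#' @param participants optional character vector of all participant ids;
#'   participants with no classified variants are filled in as non-carriers.
#' @return one row per participant: \code{is_carrier}, \code{acmg_sf_carrier},
#'   \code{recessive_carrier}, \code{n_actionable}, \code{actionable_genes}.
#' @export
assign_carrier_status <- function(classified, panel, participants = NULL) {
  sf_genes <- subset_acmg_sf(panel)$symbol
  inh <- panel$inheritance[match(classified$gene, panel$symbol)]
  plp <- !is.na(classified$final_class) & classified$final_class %in% c("P", "LP")

  hit <- classified[plp, , drop = FALSE]
  hit$inheritance <- inh[plp]
  groups <- split(hit, hit$participant_id)
  rows <- lapply(groups, function(g) {
    dom <- carrier_call(g$gene, g$inheritance, g$zygosity, NULL)
    sf <- carrier_call(g$gene, g$inheritance, g$zygosity, sf_genes)
    tibble::tibble(
      participant_id = g$participant_id[1],
      is_carrier = dom$carrier, acmg_sf_carrier = sf$carrier,
      recessive_carrier = any(g$inheritance == "AR" & g$zygosity == "het" &
                                !(g$gene %in% dom$biallelic)),
      n_actionable = dom$n, actionable_genes = dom$genes
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(participant_id = character(), is_carrier = logical(),
                          acmg_sf_carrier = logical(), recessive_carrier = logical(),
                          n_actionable = integer(), actionable_genes = character())
  }
  if (!is.null(participants)) {
    miss <- setdiff(participants, out$participant_id)
    if (length(miss)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        participant_id = miss, is_carrier = FALSE, acmg_sf_carrier = FALSE,
        recessive_carrier = FALSE, n_actionable = 0L, actionable_genes = ""
      ))
    }
    out <- out[match(participants, out$participant_id), , drop = FALSE]
  }
  out
}

# carrier logic for one participant's P/LP variants, optionally restricted
# to a gene subset; returns list(carrier, n, genes, biallelic)
carrier_call <- function(gene, inheritance, zygosity, gene_subset) {
  keep <- if (is.null(gene_subset)) rep(TRUE, length(gene)) else gene %in% gene_subset
  gene <- gene[keep]; inheritance <- inheritance[keep]; zygosity <- zygosity[keep]
  dom <- inheritance %in% c("AD", "XL")
  ar_hom <- inheritance == "AR" & zygosity == "hom"
  ar_het_counts <- table(gene[inheritance == "AR" & zygosity == "het"])
  biallelic_genes <- names(ar_het_counts)[ar_het_counts >= 2]
  actionable <- dom | ar_hom | (inheritance == "AR" & gene %in% biallelic_genes)
  list(carrier = any(actionable), n = sum(actionable),
       genes = paste(sort(unique(gene[actionable])), collapse = ";"),
       biallelic = biallelic_genes)
}
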