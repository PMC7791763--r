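#' Synthetic cohort generation
#'
#' Generates complete synthetic study inputs — participant roster, pedigree
#' JSONs with cancer phenotypes, a multi-sample VCF plus per-site annotation
#' table, and a write-only ground-truth file — so that every pipeline stage
#' and the headline family-history enrichment can be exercised without any
#' external data. Three generation modes:
#' \describe{
#'   \item{designed (exact)}{cohort sizes, carrier counts and carrier genes
#'     fixed by the configuration and realised exactly; this is how the
#'     golden preset reproduces its designed 2x2 cells by construction.}
#'   \item{designed (probabilistic)}{family-history intent and carrier
#'     status drawn per participant from configured probabilities; the
#'     designed relative risk is the ratio of the carrier probabilities.
#'     Used by the parameter-recovery harness.}
#'   \item{penetrance}{a latent familial variant segregates through a
#'     four-generation pedigree by Mendelian transmission; relatives develop
#'     cancer according to carrier/background penetrance with an onset-age
#'     model, and family-history risk emerges from the phenotypes rather
#'     than being assigned.}
#' }
#' Ground truth is emitted alongside the data and never read by the
#' pipeline, which consumes only the VCF/annotation/pedigree files.
#'
#' @name synthetic-cohort
NULL

#' Build a simulation configuration
#'
#' @param mode one of \code{"designed"}, \code{"penetrance"}.
#' @param n_fh_available,n_fh_unavailable cohort sizes.
#' @param exact_counts for designed mode: NULL (probabilistic) or a list
#'   with \code{n_increased}, \code{carriers_increased},
#'   \code{sf_carriers_increased}, \code{carriers_average},
#'   \code{sf_carriers_average}, \code{carriers_unavailable},
#'   \code{sf_carriers_unavailable} realised exactly.
#' @param p_increased probability a FH-available participant has an
#'   increased-risk family history (probabilistic designed mode).
#' @param p_carrier_increased,p_carrier_average,p_carrier_unavailable
#'   carrier probabilities per cohort (probabilistic designed mode); the
#'   designed relative risk is
#'   \code{p_carrier_increased / p_carrier_average}.
#' @param familial_variant_prob penetrance mode: probability a family
#'   segregates a pathogenic panel variant.
#' @param carrier_penetrance lifetime risk of the gene-associated cancer for
#'   a carrier relative (penetrance mode).
#' @param background_cancer_rate lifetime background cancer risk for any
#'   relative.
#' @param onset_mean_carrier,onset_sd_carrier onset-age model for
#'   carrier-associated cancers (years).
#' @param onset_mean_background,onset_sd_background onset-age model for
#'   background cancers.
#' @param decoy_rate mean number of benign/VUS decoy variant records per
#'   participant (Poisson).
#' @param n_decoy_sites size of the shared decoy variant pool.
#' @param seed integer seed; the seed fully determines the output.
#' @return a \code{fhc_sim_config} list.
#' @export
simulation_config <- function(mode = c("designed", "penetrance"),
                              n_fh_available = 866, n_fh_unavailable = 884,
                              exact_counts = NULL,
                              p_increased = 0.084,
                              p_carrier_increased = 0.137,
                              p_carrier_average = 0.021,
                              p_carrier_unavailable = 0.019,
                              familial_variant_prob = 0.1,
                              carrier_penetrance = 0.6,
                              background_cancer_rate = 0.08,
                              onset_mean_carrier = 42, onset_sd_carrier = 6,
                              onset_mean_background = 68, onset_sd_background = 9,
                              decoy_rate = 2, n_decoy_sites = 620,
                              seed = 1L) {
  mode <- match.arg(mode)
  for (p in c(p_increased, p_carrier_increased, p_carrier_average,
              p_carrier_unavailable, familial_variant_prob,
              carrier_penetrance, background_cancer_rate)) {
    stopifnot_prob(p, "simulation probability")
  }
  if (n_fh_available < 0 || n_fh_unavailable < 0 || decoy_rate < 0) {
    fhc_config_error("cohort sizes and decoy_rate must be non-negative")
  }
  structure(as.list(environment()), class = "fhc_sim_config")
}

#' The golden cohort preset
#'
#' A designed exact-counts configuration whose 1750 participants realise,
#' by construction, the reference cohort structure: 866 with family history
#' (73 increased risk, 10 of them carriers of whom 5 in ACMG SF genes;
#' 793 average risk, 17 carriers of whom 3 in SF genes) and 884 without
#' family history (17 carriers, 4 in SF genes). One designated carrier in
#' the increased cohort holds an AXIN2 variant and is marked for the
#' sensitivity exclusion.
#'
#' @param seed integer seed.
#' @return a \code{fhc_sim_config}.
#' @export
golden_cohort_config <- function(seed = 1L) {
  simulation_config(
    mode = "designed",
    n_fh_available = 866, n_fh_unavailable = 884,
    exact_counts = list(
      n_increased = 73,
      carriers_increased = 10, sf_carriers_increased = 5,
      carriers_average = 17, sf_carriers_average = 3,
      carriers_unavailable = 17, sf_carriers_unavailable = 4
    ),
    seed = seed
  )
}

# ---- variant catalogues --------------------------------------------------

# deterministic synthetic coordinates per panel gene
gene_coordinates <- function(panel) {
  idx <- seq_len(nrow(panel))
  chrom <- as.character((idx %% 22) + 1)
  chrom[panel$inheritance == "XL"] <- "X"
  tibble::tibble(gene = panel$symbol, chrom = chrom, base_pos = 1e6 * idx)
}

# designed carrier gene assignments for the golden preset; SF genes first
GOLDEN_GENES <- list(
  increased = c("BRCA1", "BRCA1", "BRCA2", "BRCA2", "MSH2",
                "AXIN2", "PALB2", "ATM", "CHEK2", "SUFU"),
  average = c("BRCA2", "BRCA2", "BRCA2",
              "ATM", "ATM", "BARD1", "BRIP1", "DICER1", "GPC3", "LZTR1",
              "LZTR1", "RAD50", "RAD51C", "RAD51D", "RAD51D", "RAD51D", "NBN"),
  unavailable = c("BRCA2", "BRCA2", "BRCA1", "MSH6",
                  "ATM", "ATM", "CHEK2", "CHEK2", "PALB2", "PALB2",
                  "BRIP1", "RAD51C", "DICER1", "LZTR1", "RAD50", "BARD1", "NBN")
)
GOLDEN_SF_N <- list(increased = 5, average = 3, unavailable = 4)
# genes whose pathogenic variant is emitted without a database assertion, so
# the loss-of-function candidate route is exercised end to end
LOF_ROUTE_GENES <- c("RAD51D", "BARD1")
# recurrent variants: all carriers of these genes share one site
RECURRENT_GENES <- "RAD51D"

# one pathogenic/likely-pathogenic variant record template per carrier;
# same-gene carriers get distinct sites unless the gene is recurrent
plp_catalog <- function(genes, panel, coords) {
  n <- length(genes)
  offset <- integer(n)
  seen <- list()
  for (i in seq_len(n)) {
    g <- genes[i]
    if (g %in% RECURRENT_GENES) {
      offset[i] <- 1L
    } else {
      seen[[g]] <- (seen[[g]] %||% 0L) + 1L
      offset[i] <- seen[[g]]
    }
  }
  j <- match(genes, coords$gene)
  lof_route <- genes %in% LOF_ROUTE_GENES
  tibble::tibble(
    chrom = coords$chrom[j],
    pos = coords$base_pos[j] + 100 * offset,
    ref = "C", alt = "T",
    gene = genes,
    hgvs_c = sprintf("c.%dC>T", 100 * offset),
    hgvs_p = sprintf("p.Q%dX", 34 * offset),
    consequence = ifelse(offset %% 2 == 0, "frameshift_indel", "stopgain"),
    af_local = NA_real_, af_gnomad = NA_real_,
    clinvar_assertion = ifelse(lof_route, "absent",
                               ifelse(offset %% 3 == 0, "pathogenic", "likely_pathogenic")),
    has_lp_or_p_entry = !lof_route,
    revel = NA_real_
  )
}

# shared pool of benign/VUS decoy sites exercising every non-carrier path
decoy_pool <- function(n_sites, panel, coords) {
  gene <- sample(panel$symbol, n_sites, replace = TRUE)
  j <- match(gene, coords$gene)
  hap <- panel$haploinsufficient[j]
  kind <- sample(c("rare_vus", "insilico_vus", "silent", "common_benign", "lof_no_hi"),
                 n_sites, replace = TRUE, prob = c(0.40, 0.15, 0.15, 0.20, 0.10))
  # loss-of-function decoys must avoid haploinsufficient genes so no decoy
  # can reach the LoF candidate route
  no_hi <- panel$symbol[panel$haploinsufficient != "yes"]
  swap <- kind == "lof_no_hi" & hap == "yes"
  gene[swap] <- sample(no_hi, sum(swap), replace = TRUE)
  j <- match(gene, coords$gene)

  af1 <- af2 <- rep(NA_real_, n_sites)
  revel <- rep(NA_real_, n_sites)
  cons <- character(n_sites)
  clin <- character(n_sites)

  rv <- kind == "rare_vus"
  cons[rv] <- "missense"
  af1[rv] <- stats::runif(sum(rv), 2e-4, 9e-3)
  af2[rv] <- stats::runif(sum(rv), 2e-4, 9e-3)
  revel[rv] <- stats::rbeta(sum(rv), 2, 5)
  clin[rv] <- sample(c("vus", "absent"), sum(rv), replace = TRUE)

  iv <- kind == "insilico_vus"
  cons[iv] <- "missense"
  af2[iv] <- stats::runif(sum(iv), 2e-4, 5e-3)
  revel[iv] <- stats::runif(sum(iv), 0.71, 0.95)
  clin[iv] <- "absent"

  sl <- kind == "silent"
  cons[sl] <- sample(c("synonymous", "intronic"), sum(sl), replace = TRUE)
  af1[sl] <- stats::runif(sum(sl), 2e-4, 9e-3)
  clin[sl] <- "absent"

  cb <- kind == "common_benign"
  cons[cb] <- "missense"
  af1[cb] <- stats::runif(sum(cb), 0.02, 0.45)
  af2[cb] <- af1[cb] * stats::runif(sum(cb), 0.8, 1.2)
  revel[cb] <- stats::rbeta(sum(cb), 1, 8)
  clin[cb] <- sample(c("benign", "likely_benign"), sum(cb), replace = TRUE)

  lf <- kind == "lof_no_hi"
  cons[lf] <- "stopgain"
  af1[lf] <- stats::runif(sum(lf), 2e-4, 9e-3)
  clin[lf] <- "absent"

  tibble::tibble(
    chrom = coords$chrom[j],
    pos = coords$base_pos[j] + 5000 + seq_len(n_sites),
    ref = "G", alt = "A",
    gene = gene, hgvs_c = sprintf("c.%d%s>%s", 5000 + seq_len(n_sites), "G", "A"),
    hgvs_p = NA_character_, consequence = cons,
    af_local = af1, af_gnomad = pmin(af2, 1),
    clinvar_assertion = clin, has_lp_or_p_entry = FALSE,
    revel = revel
  )
}

# ---- pedigree templates --------------------------------------------------

tpl_row <- function(relation, lineage, sex, condition, age) {
  data.frame(relation = relation, lineage = lineage, sex = sex,
             condition = condition, age = age, stringsAsFactors = FALSE)
}

# archetype histories that deterministically meet the increased-risk rules;
# weights approximate the reported familial cancer mix (breast most common,
# then ovarian and colorectal, with an unknown-type category)
increased_templates <- function() {
  list(
    list(w = 13, rows = tpl_row("mother", NA, "F", "breast", 40)),
    list(w = 8, rows = rbind(
      tpl_row("aunt_uncle", "maternal", "F", "breast", 48),
      tpl_row("grandparent", "maternal", "F", "breast", 62))),
    list(w = 13, rows = rbind(
      tpl_row("aunt_uncle", "maternal", "F", "ovarian", 52),
      tpl_row("mother", NA, "F", "breast", 45))),
    list(w = 7, rows = rbind(
      tpl_row("grandparent", "maternal", "F", "ovarian", 58),
      tpl_row("aunt_uncle", "maternal", "F", "endometrial", 50))),
    list(w = 6, rows = rbind(
      tpl_row("father", NA, "M", "colorectal", 45),
      tpl_row("aunt_uncle", "paternal", "M", "gastric", 60))),
    list(w = 4, rows = rbind(
      tpl_row("grandparent", "maternal", "F", "colorectal", 47),
      tpl_row("aunt_uncle", "maternal", "F", "colorectal", 55))),
    list(w = 8, rows = rbind(
      tpl_row("aunt_uncle", "maternal", "F", "unknown_cancer", 45),
      tpl_row("grandparent", "maternal", "F", "unknown_cancer", 38))),
    list(w = 4, rows = rbind(
      tpl_row("father", NA, "M", "prostate", 65),
      tpl_row("aunt_uncle", "paternal", "M", "prostate", 62),
      tpl_row("grandparent", "paternal", "M", "pancreatic", 68))),
    list(w = 4, rows = rbind(
      tpl_row("father", NA, "M", "breast", 58),
      tpl_row("sibling", NA, "F", "melanoma", 45))),
    list(w = 6, rows = rbind(
      tpl_row("mother", NA, "F", "breast", 42),
      tpl_row("aunt_uncle", "maternal", "F", "pancreatic", 55)))
  )
}

# histories that never meet any default rule (verified by test): either no
# cancer at all, or single late-onset cancers outside the rule scope
average_templates <- function() {
  list(
    list(w = 30, rows = tpl_row("father", NA, "M", "hypertension", 60)),
    list(w = 20, rows = rbind(
      tpl_row("mother", NA, "F", "diabetes", 62),
      tpl_row("grandparent", "maternal", "F", "stroke", 75))),
    list(w = 12, rows = tpl_row("grandparent", "paternal", "M", "lung", 72)),
    list(w = 10, rows = tpl_row("grandparent", "maternal", "F", "breast", 68)),
    list(w = 8, rows = rbind(
      tpl_row("father", NA, "M", "heart_attack", 65),
      tpl_row("aunt_uncle", "paternal", "F", "liver", 74))),
    list(w = 8, rows = tpl_row("aunt_uncle", "maternal", "M", "colorectal", 70)),
    list(w = 6, rows = tpl_row("mother", NA, "F", "cervical", 55)),
    list(w = 6, rows = tpl_row("grandparent", "maternal", "M", "unknown_cancer", 78))
  )
}

template_cases <- function(pid, rows) {
  n <- nrow(rows)
  age <- rows$age
  tibble::tibble(
    participant_id = pid, relative_id = paste0("r", seq_len(n)),
    relation = rows$relation, degree = unname(relation_degree(rows$relation)),
    lineage = resolve_lineage(rows$relation, rows$lineage),
    sex = rows$sex, deceased = FALSE,
    condition = rows$condition,
    is_cancer = rows$condition %in% cancer_terms(),
    age = as.numeric(age), age_known = !is.na(age)
  )
}

# draw template indices for a vector of participants (weighted), or exact
# multiset when exact = TRUE (weights are counts)
draw_templates <- function(templates, n, exact = FALSE) {
  w <- vapply(templates, `[[`, 1, "w")
  if (exact) {
    stopifnot(sum(w) == n)
    sample(rep(seq_along(templates), times = w))
  } else {
    sample(seq_along(templates), n, replace = TRUE, prob = w)
  }
}

cases_for <- function(ids, template_idx, templates) {
  tpl <- lapply(templates, function(t) template_cases("", t$rows))
  blocks <- lapply(seq_along(templates), function(j) {
    fam <- ids[template_idx == j]
    if (!length(fam)) return(NULL)
    n_t <- nrow(tpl[[j]])
    block <- tpl[[j]][rep(seq_len(n_t), times = length(fam)), ]
    block$participant_id <- rep(fam, each = n_t)
    block
  })
  dplyr::bind_rows(blocks)
}

# memoised package fixtures (parsed once per session)
.fhc_cache <- new.env(parent = emptyenv())

carrier_history_cases <- function() {
  if (is.null(.fhc_cache$carrier_histories)) {
    raw <- jsonlite::fromJSON(fhc_extdata("average_risk_carrier_histories.json"),
                              simplifyVector = FALSE)
    .fhc_cache$carrier_histories <- lapply(raw, function(h) parse_pedigree(h)$relatives)
  }
  .fhc_cache$carrier_histories
}

# ---- main generator ------------------------------------------------------

#' Simulate a synthetic screening cohort
#'
#' @param config a \code{fhc_sim_config}.
#' @param out_dir optional directory; when given, writes
#'   \code{cohort.vcf}, \code{annotation.tsv}, \code{participants.tsv},
#'   \code{pedigrees/<id>.json} and \code{ground_truth.json}.
#' @param panel gene panel used for gene assignments (default: packaged).
#' @return invisibly (and visibly when \code{out_dir} is NULL) a list:
#'   \code{participants}, \code{variants} (per-participant records in the
#'   \code{\link{read_variants}} schema), \code{cases} + \code{fh}
#'   (pedigree data), \code{ground_truth}, \code{config}.
#' @export
simulate_cohort <- function(config, out_dir = NULL, panel = load_panel()) {
  stopifnot(inherits(config, "fhc_sim_config"))
  set.seed(config$seed)
  coords <- gene_coordinates(panel)

  sim <- if (config$mode == "designed") {
    simulate_designed(config, panel, coords)
  } else {
    simulate_penetrance(config, panel, coords)
  }
  sim$config <- config
  if (!is.null(out_dir)) write_cohort(sim, out_dir)
  invisible(sim)
}

simulate_designed <- function(config, panel, coords) {
  n_fh <- config$n_fh_available
  n_no <- config$n_fh_unavailable
  n <- n_fh + n_no
  ids <- sprintf("P%04d", seq_len(n))
  fh_avail <- c(rep(TRUE, n_fh), rep(FALSE, n_no))

  ec <- config$exact_counts
  if (!is.null(ec)) {
    fh_intent <- c(rep("increased", ec$n_increased),
                   rep("average", n_fh - ec$n_increased),
                   rep("not_available", n_no))
    carrier <- rep(FALSE, n)
    sf <- rep(FALSE, n)
    pick <- function(cohort, k, k_sf) {
      rows <- which(fh_intent == cohort)
      chosen <- rows[seq_len(k)]
      carrier[chosen] <<- TRUE
      sf[chosen[seq_len(k_sf)]] <<- TRUE
      chosen
    }
    inc_car <- pick("increased", ec$carriers_increased, ec$sf_carriers_increased)
    avg_car <- pick("average", ec$carriers_average, ec$sf_carriers_average)
    no_car <- pick("not_available", ec$carriers_unavailable, ec$sf_carriers_unavailable)
    gene_of <- rep(NA_character_, n)
    gene_of[inc_car] <- GOLDEN_GENES$increased[seq_along(inc_car)]
    gene_of[avg_car] <- GOLDEN_GENES$average[seq_along(avg_car)]
    gene_of[no_car] <- GOLDEN_GENES$unavailable[seq_along(no_car)]
    sensitivity_exclude <- !is.na(gene_of) & gene_of == "AXIN2" &
      fh_intent == "increased"
  } else {
    fh_intent <- ifelse(!fh_avail, "not_available",
                        ifelse(stats::runif(n) < config$p_increased,
                               "increased", "average"))
    p_car <- c(increased = config$p_carrier_increased,
               average = config$p_carrier_average,
               not_available = config$p_carrier_unavailable)[fh_intent]
    carrier <- stats::runif(n) < p_car
    plp_genes <- unique(unlist(GOLDEN_GENES))
    gene_of <- rep(NA_character_, n)
    gene_of[carrier] <- sample(plp_genes, sum(carrier), replace = TRUE)
    sf <- carrier & gene_of %in% subset_acmg_sf(panel)$symbol
    sensitivity_exclude <- rep(FALSE, n)
  }

  # participant metadata emulating the study's baseline margins
  age <- pmin(pmax(round(stats::rnorm(n, 45.5, 12)), 16), 88)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.521, 0.479))
  ethnicity <- sample(c("chinese", "indian", "malay", "other"), n,
                      replace = TRUE, prob = c(0.892, 0.043, 0.039, 0.026))

  # pedigrees: increased-risk archetypes; average histories from the safe
  # pool, except designated average carriers who reuse the packaged
  # carrier histories
  inc_rows <- which(fh_intent == "increased")
  avg_rows <- which(fh_intent == "average")
  inc_tpl <- increased_templates()
  avg_tpl <- average_templates()
  exact_inc <- !is.null(ec) && sum(vapply(inc_tpl, `[[`, 1, "w")) == length(inc_rows)
  cases_inc <- if (length(inc_rows)) {
    cases_for(ids[inc_rows], draw_templates(inc_tpl, length(inc_rows), exact_inc), inc_tpl)
  } else empty_cases_tbl()

  avg_car_rows <- intersect(avg_rows, which(carrier))
  carrier_histories <- carrier_history_cases()
  cases_avg_car <- empty_cases_tbl()
  if (length(avg_car_rows)) {
    hist_idx <- rep(seq_along(carrier_histories), length.out = length(avg_car_rows))
    cases_avg_car <- dplyr::bind_rows(lapply(seq_along(avg_car_rows), function(i) {
      rel <- carrier_histories[[hist_idx[i]]]
      rel$participant_id <- ids[avg_car_rows[i]]
      rel
    }))
  }
  avg_other <- setdiff(avg_rows, avg_car_rows)
  cases_avg <- if (length(avg_other)) {
    cases_for(ids[avg_other], draw_templates(avg_tpl, length(avg_other)), avg_tpl)
  } else empty_cases_tbl()
  cases <- dplyr::bind_rows(cases_inc, cases_avg_car, cases_avg)

  variants <- build_variant_records(ids, carrier, sf, gene_of, fh_intent,
                                    panel, coords, config)

  list(
    participants = tibble::tibble(participant_id = ids, age = age, sex = sex,
                                  ethnicity = ethnicity, fh_available = fh_avail),
    variants = variants,
    cases = cases,
    fh = tibble::tibble(participant_id = ids, fh_available = fh_avail),
    ground_truth = tibble::tibble(
      participant_id = ids, true_carrier = carrier, true_sf_carrier = sf,
      carrier_gene = gene_of, fh_intent = fh_intent,
      sensitivity_exclude = sensitivity_exclude
    )
  )
}

build_variant_records <- function(ids, carrier, sf, gene_of, fh_intent,
                                  panel, coords, config) {
  # carrier variants: SF carriers must get an SF gene, others a non-SF gene;
  # in exact mode the gene assignment already encodes this
  car_idx <- which(carrier)
  plp <- if (length(car_idx)) {
    cat_tbl <- plp_catalog(gene_of[car_idx], panel, coords)
    cat_tbl$participant_id <- ids[car_idx]
    cat_tbl$zygosity <- "het"
    cat_tbl
  } else NULL

  pool <- decoy_pool(config$n_decoy_sites, panel, coords)
  n_dec <- stats::rpois(length(ids), config$decoy_rate)
  who <- rep(seq_along(ids), n_dec)
  site <- sample(nrow(pool), sum(n_dec), replace = TRUE)
  # one record per (participant, site)
  dup <- duplicated(paste(who, site))
  who <- who[!dup]; site <- site[!dup]
  decoys <- pool[site, ]
  decoys$participant_id <- ids[who]
  decoys$zygosity <- ifelse(stats::runif(nrow(decoys)) < 0.05 &
                              decoys$clinvar_assertion %in% c("benign", "likely_benign"),
                            "hom", "het")
  out <- dplyr::bind_rows(plp, decoys)
  out <- out[, c("participant_id", "chrom", "pos", "ref", "alt", "gene",
                 "hgvs_c", "hgvs_p", "consequence", "af_local", "af_gnomad",
                 "clinvar_assertion", "has_lp_or_p_entry", "revel", "zygosity")]
  out[order(out$participant_id, out$chrom, out$pos), ]
}

# ---- penetrance mode -----------------------------------------------------

PENETRANCE_GENES <- c("BRCA1", "BRCA2", "MLH1", "MSH2", "RAD51C")

simulate_penetrance <- function(config, panel, coords) {
  n_fh <- config$n_fh_available
  n_no <- config$n_fh_unavailable
  n <- n_fh + n_no
  ids <- sprintf("P%04d", seq_len(n))
  fh_avail <- c(rep(TRUE, n_fh), rep(FALSE, n_no))

  seg <- stats::runif(n) < config$familial_variant_prob
  fam_gene <- rep(NA_character_, n)
  fam_gene[seg] <- sample(PENETRANCE_GENES, sum(seg), replace = TRUE)

  res <- lapply(seq_len(n), function(i) {
    simulate_family(ids[i], fh_avail[i], seg[i], fam_gene[i], panel, config)
  })
  carrier <- vapply(res, `[[`, TRUE, "proband_carrier")
  cases <- dplyr::bind_rows(lapply(res, `[[`, "cases"))

  gene_of <- ifelse(carrier, fam_gene, NA_character_)
  sf_genes <- subset_acmg_sf(panel)$symbol
  variants <- build_variant_records(ids, carrier, carrier & gene_of %in% sf_genes,
                                    gene_of, NULL, panel, coords, config)
  list(
    participants = tibble::tibble(participant_id = ids, age = 45, sex = "F",
                                  ethnicity = "chinese", fh_available = fh_avail),
    variants = variants,
    cases = cases,
    fh = tibble::tibble(participant_id = ids, fh_available = fh_avail),
    ground_truth = tibble::tibble(
      participant_id = ids, true_carrier = carrier,
      true_sf_carrier = carrier & gene_of %in% sf_genes,
      carrier_gene = gene_of, fh_intent = NA_character_,
      sensitivity_exclude = FALSE
    )
  )
}

# four-generation template: 4 grandparents, parents, aunts/uncles, siblings;
# the familial variant starts in one grandparent and segregates by Mendelian
# halving; phenotypes are drawn from the penetrance/onset model
simulate_family <- function(pid, fh_available, segregates, gene, panel, config) {
  side <- if (segregates) sample(c("maternal", "paternal"), 1) else NA
  members <- list(
    list(relation = "grandparent", lineage = "maternal", sex = "F", age = stats::rnorm(1, 78, 6)),
    list(relation = "grandparent", lineage = "maternal", sex = "M", age = stats::rnorm(1, 78, 6)),
    list(relation = "grandparent", lineage = "paternal", sex = "F", age = stats::rnorm(1, 78, 6)),
    list(relation = "grandparent", lineage = "paternal", sex = "M", age = stats::rnorm(1, 78, 6)),
    list(relation = "mother", lineage = "maternal", sex = "F", age = stats::rnorm(1, 55, 7)),
    list(relation = "father", lineage = "paternal", sex = "M", age = stats::rnorm(1, 55, 7))
  )
  for (s in c("maternal", "paternal")) {
    for (k in seq_len(sample(0:3, 1))) {
      members[[length(members) + 1]] <- list(relation = "aunt_uncle", lineage = s,
                                             sex = sample(c("M", "F"), 1),
                                             age = stats::rnorm(1, 55, 8))
    }
  }
  for (k in seq_len(sample(0:2, 1))) {
    members[[length(members) + 1]] <- list(relation = "sibling", lineage = "both",
                                           sex = sample(c("M", "F"), 1),
                                           age = stats::rnorm(1, 47, 8))
  }

  # genotype descent: founder grandmother on the segregating side carries
  carries <- vapply(members, function(m) FALSE, TRUE)
  if (segregates) {
    founder <- which(vapply(members, function(m)
      m$relation == "grandparent" && m$lineage == side && m$sex == "F", TRUE))
    carries[founder] <- TRUE
    parent_i <- which(vapply(members, function(m)
      m$relation %in% c("mother", "father") && m$lineage == side, TRUE))
    carries[parent_i] <- stats::runif(1) < 0.5
    for (i in which(vapply(members, function(m)
      m$relation == "aunt_uncle" && m$lineage == side, TRUE))) {
      carries[i] <- stats::runif(1) < 0.5
    }
    proband_carrier <- carries[parent_i] && stats::runif(1) < 0.5
    sib_i <- which(vapply(members, function(m) m$relation == "sibling", TRUE))
    carries[sib_i] <- carries[parent_i] & stats::runif(length(sib_i)) < 0.5
  } else {
    proband_carrier <- FALSE
  }

  cancer_of_gene <- function(g) strsplit(panel$cancer_types[panel$symbol == g], ";")[[1]][1]
  bg_types <- c("lung", "liver", "colorectal", "breast", "gastric", "prostate")
  n_m <- length(members)
  cur_age <- vapply(members, `[[`, 1, "age")
  # carrier-associated cancers (early-onset model) and background cancers
  fam_dx <- carries & stats::runif(n_m) < config$carrier_penetrance
  fam_onset <- stats::rnorm(n_m, config$onset_mean_carrier, config$onset_sd_carrier)
  fam_dx <- fam_dx & fam_onset <= cur_age
  bg_dx <- stats::runif(n_m) < config$background_cancer_rate
  bg_onset <- stats::rnorm(n_m, config$onset_mean_background, config$onset_sd_background)
  bg_dx <- bg_dx & bg_onset <= cur_age
  bg_type <- sample(bg_types, n_m, replace = TRUE)

  # one row per (relative, diagnosis); relatives without any diagnosis keep
  # a single placeholder row
  no_dx <- which(!(fam_dx | bg_dx))
  idx <- c(no_dx, which(fam_dx), which(bg_dx))
  cond <- c(rep(NA_character_, length(no_dx)),
            rep(cancer_of_gene(gene), sum(fam_dx)), bg_type[bg_dx])
  age_dx <- c(rep(NA_real_, length(no_dx)), round(fam_onset[fam_dx]),
              round(bg_onset[bg_dx]))

  relation <- vapply(members, `[[`, "", "relation")[idx]
  lineage <- vapply(members, function(m) m$lineage %||% "both", "")[idx]
  cases <- tibble::tibble(
    participant_id = pid, relative_id = paste0("r", idx),
    relation = relation, degree = unname(relation_degree(relation)),
    lineage = ifelse(relation %in% c("sibling", "child"), "both", lineage),
    sex = vapply(members, `[[`, "", "sex")[idx],
    deceased = FALSE,
    condition = cond, is_cancer = cond %in% cancer_terms(),
    age = age_dx, age_known = !is.na(age_dx)
  )
  if (!fh_available) cases <- cases[0, ]
  list(proband_carrier = proband_carrier, cases = cases)
}

# ---- on-disk output ------------------------------------------------------

#' Write a simulated cohort as pipeline input files
#'
#' Emits exactly what \code{\link{run_pipeline}} consumes: a multi-sample
#' VCF v4.2 (genotypes in GT), a per-site annotation TSV, one pedigree JSON
#' per participant, a participant roster, and the write-only
#' \code{ground_truth.json}.
#'
#' @param sim result of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pedigrees"), showWarnings = FALSE)

  v <- sim$variants
  site_key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  sites <- v[!duplicated(site_key), c("chrom", "pos", "ref", "alt", "gene",
                                      "hgvs_c", "hgvs_p", "consequence",
                                      "af_local", "af_gnomad",
                                      "clinvar_assertion", "has_lp_or_p_entry",
                                      "revel")]
  ord <- order(suppressWarnings(as.integer(sites$chrom)), sites$chrom, sites$pos)
  sites <- sites[ord, ]
  readr::write_tsv(sites, file.path(dir, "annotation.tsv"), na = "")

  # genotype matrix, sites x participants
  skey <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  pids <- sim$participants$participant_id
  gmat <- matrix("0/0", nrow(sites), length(pids))
  gt_code <- c(het = "0/1", hom = "1/1", hemi = "1")
  gmat[cbind(match(site_key, skey), match(v$participant_id, pids))] <-
    gt_code[v$zygosity]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fhconcord_simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pids), collapse = "\t")
  )
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "GT",
                apply(gmat, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), file.path(dir, "cohort.vcf"))

  readr::write_tsv(sim$participants, file.path(dir, "participants.tsv"))

  cases_by <- split(sim$cases, sim$cases$participant_id)
  for (i in seq_len(nrow(sim$fh))) {
    pid <- sim$fh$participant_id[i]
    ped <- new_pedigree(pid, sim$fh$fh_available[i],
                        cases_by[[pid]] %||% empty_cases_tbl())
    write_pedigree(ped, file.path(dir, "pedigrees", paste0(pid, ".json")))
  }

  jsonlite::write_json(sim$ground_truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE)
  invisible(dir)
}
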