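# fhconcord

Concordance of family-history cancer risk and clinically actionable germline
variants in population genomic screening.

## The problem

Population screening programs increasingly sequence unselected, healthy
participants and look for pathogenic variants in a predefined cancer gene
panel — a genome-first strategy in which systematically collected family
history plays no selection role. `fhconcord` implements the complementary
analysis: given (i) called and annotated germline variants for every
participant, (ii) up to four generations of family health history per
participant, and (iii) a cancer gene panel configuration, it asks how
strongly a family history meeting clinical testing criteria enriches for
carriers of clinically actionable variants.

Three cohorts are compared: **increased FH risk** (family history meets the
configured clinical testing rules), **average FH risk** (history available,
rules not met) and **FH not available**. For carriers `a/n1` in one cohort
versus `c/n2` in another, enrichment is the classical relative risk with a
log-normal confidence interval:

```
RR = (a/n1) / (c/n2)
SE(log RR) = sqrt(1/a - 1/n1 + 1/c - 1/n2)
95% CI = exp(log RR ± 1.959964 · SE)
```

with two-tailed Fisher exact tests for significance. Variant triage follows
a standard curation flowchart: strict rarity filtering (MAF < 1% in both a
local and a reference population database), three ordered candidate routes
(a likely-pathogenic/pathogenic ClinVar-style entry; a protein-disrupting
variant in a haploinsufficient panel gene; a database-absent variant with
REVEL > 0.7), ACMG-AMP evidence combination into P/LP/VUS/LB/B, and carrier
calls that respect inheritance mode (heterozygous P/LP in an
autosomal-recessive gene is recessive carriage, not an actionable finding).
Family history never feeds back into variant classification.

A synthetic cohort generator (Mendelian segregation, penetrance and
onset-age models, benign/VUS decoy variants) makes the whole pipeline
runnable and testable with no external data; its *golden preset* realises a
1750-participant cohort with a designed carrier-by-cohort structure.

## Worked example

```r
library(fhconcord)

dir <- tempfile()
sim <- simulate_cohort(golden_cohort_config(seed = 1), out_dir = dir)
excl <- sim$ground_truth$participant_id[sim$ground_truth$sensitivity_exclude]

report <- run_pipeline(
  vcf_path        = file.path(dir, "cohort.vcf"),
  annotation_path = file.path(dir, "annotation.tsv"),
  pedigree_dir    = file.path(dir, "pedigrees"),
  out_dir         = file.path(dir, "out"),
  exclude_participants = excl)

report
#> Cohort of 1750 participants, 44 carriers (2.5%)
#> # A tibble: 3 x 8
#>   fh_cohort         n carriers pct_carriers one_in  sf_carriers pct_sf_carriers
#>   <chr>         <int>    <int>        <dbl> <chr>         <int>           <dbl>
#> 1 increased        73       10         13.7 1 in 7            5             6.8
#> 2 average         793       17          2.1 1 in 47           3             0.4
#> 3 not_available   884       17          1.9 1 in 52           4             0.5
#> # i 1 more variable: one_in_sf <chr>
#>
#> Full panel, increased vs average FH risk:
#> Relative risk: 10/73 vs 17/793
#>   RR 6.39 (95% CI 3.0-13.4), p = 2.59e-05
#>
#> Concordant 786 (90.8%), discordant 80 (9.2%)
```

Reading: 13.7% (1 in 7) of participants whose family history met the
testing criteria carried a clinically actionable variant, a 6.39-fold
enrichment over the average-risk cohort (2.1%, 1 in 47). Restricting to the
25 ACMG secondary-findings cancer genes sharpens the enrichment (RR 18.1 vs
the average cohort, 15.13 vs the no-history cohort). 786 of the 866
history-available participants are concordant (carrier with increased risk,
or non-carrier with average risk). Removing the one increased-risk AXIN2
carrier — a gene whose breast-cancer association is still emerging — leaves
a 5.8-fold enrichment (`report$sensitivity`).

A thin command-line wrapper with `simulate` / `triage` / `fh-assess` /
`concord` / `run` subcommands ships in `inst/cli/fhconcord.R`.

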