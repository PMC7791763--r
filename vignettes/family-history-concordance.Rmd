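---
title: "Family history and actionable germline variants: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family history and actionable germline variants: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhconcord)
```

This vignette is the package's account of its methods: the models and rules
it implements, the parameters that matter, the numerical and design choices
made where the design was genuinely open, and what the synthetic cohorts
can and cannot tell you about real data.

## The analysis in one paragraph

Each participant in an unselected screening cohort contributes two
independent assessments. From genomic data: does the participant carry a
*clinically actionable* variant — pathogenic (P) or likely pathogenic (LP)
— in a cancer gene panel? From family health history: does the pedigree
meet clinical testing criteria for hereditary cancer risk? The cohort-level
question is whether the second predicts the first, quantified as the
relative risk of carriage between the increased-risk and average-risk
family-history cohorts (and versus participants with no history collected),
together with a concordance partition of the history-available cohort.

## Gene panel

The unit of scope is a 95-gene panel (`load_panel()`), each entry carrying
inheritance mode (AD/AR/XL), a reviewed haploinsufficiency verdict
(yes/no/unknown), membership in the 25-gene ACMG secondary-findings (SF)
cancer subset, and associated cancer types. The shipped panel is a
*synthetic reconstruction* of a typical germline cancer panel — suitable as
a default and for simulation, but a clinical deployment should supply its
own reviewed file. Haploinsufficiency is a config verdict rather than
something the pipeline infers, because it is the gatekeeper for treating
loss-of-function variants as pathogenic candidates: genes marked `unknown`
send their LoF variants to a manual-review list rather than auto-routing
them (conservative), and genes marked `no` (gain-of-function/missense
mechanisms such as CDK4 or RET) demote LoF variants to the VUS pool.

## Variant triage

Triage operates on per-participant records joined from a VCF (GT genotypes)
and a per-site annotation table, and is deliberately blind to pedigree
data. Steps and tunable thresholds:

1. **Frequency filter** — retain records strictly below `maf_threshold`
   (default 0.01) in *both* the local population database and the reference
   database; an absent frequency passes. The joint rule is conservative in
   the direction of rarity; the strict inequality means an allele at
   exactly 1% is excluded.
2. **Candidate routes**, checked in fixed priority order with the first
   match recorded: (a) at least one P/LP database entry; (b) protein-
   disrupting consequence (frameshift indel, stopgain, stoploss, essential
   splice) in a haploinsufficient gene; (c) database-absent with
   REVEL > 0.7 (strict). The ordering renders "one of the following
   criteria" deterministic when a variant satisfies several.
3. **Classification.** Route (a) variants with an unambiguous P or LP
   assertion adopt that class, modelling concordant expert review of a
   well-asserted variant; everything else is classified by combining
   automated ACMG-AMP evidence codes (PVS1 from consequence +
   haploinsufficiency, PM2 from rarity below `1e-4`, PP3/BP4 from REVEL
   above 0.7 / below 0.3, PP5/BP6 from database assertions, BA1 above 5%).
   The combining-rule table ships as editable YAML; evidence satisfying
   both a pathogenic-side and a benign-side rule is *conflicting* and
   resolves to VUS, which is how a deterministic pipeline renders a case a
   clinical team would settle by discussion. Manually curated codes
   (segregation, functional, de novo) are outside automation scope, so
   automated classes are conservative: an in-silico-route missense variant
   typically lands in the VUS pool with a `potential_pathogenic` flag
   (REVEL > 0.7, database-absent or VUS) rather than reaching LP.
4. **Carrier calls.** P/LP in an AD or XL gene makes a carrier; in an AR
   gene only a biallelic genotype does (homozygous, or two distinct
   heterozygous P/LP variants assumed in trans — phase is not modelled).
   Single AR hets are reported as recessive carriage. `acmg_sf_carrier` is
   the same call restricted to the SF subset.

## Family-history rules engine

Pedigrees cover up to four generations (children to grandparents and
cousins). Relation determines degree and lineage; siblings and children
count toward both parental sides, and maternal/paternal cancers are never
pooled for "same side" counts. The shipped ruleset approximates clinical
testing criteria for hereditary breast/ovarian and colorectal cancer:
early-onset breast cancer (≤ 45), two same-side breast cancers with one
≤ 50, ovarian cancer at any age, male breast cancer, three same-side
breast/prostate/pancreatic cancers, colorectal/endometrial cancer before
50, two same-side Lynch-spectrum cancers with one before 50, three
same-side Lynch-spectrum cancers at any age, and two same-side unknown-type
cancers before 50. Every fired rule is recorded, so stratifications are
auditable; the ruleset YAML is fully configurable.

Numerical conventions the rules depend on:

* **Decade bands** ("50s") map to their midpoint (55). Histories are often
  reported at decade resolution; the midpoint is the least-biased single
  representative.
* **Unknown ages** never satisfy an age bound on their own. For count-based
  rules (two or more cases) an unknown age may stand in for the age
  requirement, and the assessment is then flagged `ambiguous` — the
  deterministic rendering of a borderline pedigree that a clinical team
  would resolve by consensus. This design keeps a family with two
  unknown-age same-side colorectal cancers in the increased cohort while a
  family with two same-side Lynch cancers both known to be late-onset stays
  average; requiring an early diagnosis in the two-cancer Lynch rule (with
  a separate any-age three-cancer rule) is what the underlying criteria
  intend, and without it late-onset bladder + colorectal pairs would be
  over-called.
* **Cousins** (third degree) are stored but excluded from rule counts by
  default (`include_third_degree` option), as guidelines are ambiguous at
  this degree.
* Non-cancer diagnoses (hypertension, diabetes, strokes...) are stored and
  ignored by the cancer ruleset.

The engine is monotone — adding an affected relative can move a family from
average to increased but never the reverse — and order-independent, both
property-tested.

## Cohort statistics

Relative risk uses the classical log-normal interval:
`SE(log RR) = sqrt(1/a − 1/n1 + 1/c − 1/n2)`, `CI = exp(log RR ± z·SE)`
with `z = 1.959964` by default. A zero cell makes the estimate undefined
rather than silently corrected; a Haldane 0.5 correction is available by
flag. Significance uses Fisher's exact test in its probability-summation
form (the p-value sums hypergeometric probabilities of all tables, with the
observed margins, no more likely than the observed table); it is verified
against a full fixed-margin enumeration for every table with total ≤ 60.
The sensitivity comparison removes designated participants entirely (both
numerator and denominator) before recomputing the enrichment.

Display conventions: relative risks and confidence limits are **truncated
toward zero** at the shown precision (so 3.386 renders as 3.3), while
percentages and "1 in N" strings **round half away from zero** (so 10/73
renders as 13.7%). These conventions reproduce the reporting style of
clinical enrichment tables; all underlying values are kept at full
precision and the "1 in N" strings are display-only.

## Synthetic cohorts

`simulate_cohort()` generates the complete input surface — multi-sample
VCF, annotation table, one pedigree JSON per participant, roster — plus a
ground-truth table that the pipeline never reads (it consumes files only).

* **Designed, exact counts** (the *golden preset*,
  `golden_cohort_config()`): 1750 participants; 866 with family history, of
  whom 73 increased risk (10 carriers, 5 in SF genes — one of them the
  designated AXIN2 carrier used by the sensitivity rerun) and 793 average
  (17 carriers, 3 in SF genes); 884 without history (17 carriers, 4 SF).
  Cohort sizes and carrier counts are realised exactly by construction:
  increased-risk families draw from archetype histories that each fire at
  least one rule unambiguously (weighted so breast cancer is the most
  common familial report, then ovarian and colorectal, with an unknown-type
  category); average families draw from a safe pool verified rule-free;
  the 17 average-risk carriers reuse the packaged carrier family histories.
  Carrier variants are emitted with P/LP annotation profiles (most via the
  database route; a recurrent RAD51D frameshift and a BARD1 variant via
  the LoF route, so that path is exercised end to end), and every
  participant receives Poisson-distributed benign/VUS decoy records drawn
  from a shared pool that exercises the frequency filter, the in-silico
  route, the manual-review path and the benign auto-class — none of which
  can reach P/LP by construction.
* **Designed, probabilistic**: family-history intent and carrier status are
  drawn per participant from configured probabilities; the designed
  relative risk is the ratio of carrier probabilities. This mode drives the
  parameter-recovery harness (`recover_enrichment()`), which runs the full
  triage + rules + relative-risk pipeline per replicate and reports
  interval coverage of the designed value.
* **Penetrance mode**: a latent familial variant segregates from a founder
  grandparent by Mendelian halving through a four-generation template;
  carrier relatives develop the gene-associated cancer with configurable
  penetrance and an early-onset age model (normal, mean 42, SD 6, truncated
  at current age), on top of a late-onset background cancer rate. Here
  enrichment *emerges* from phenotypes: family-history risk responds to the
  early-onset cancers of carrier relatives, so increasing carrier
  penetrance strictly raises the recovered enrichment (property-tested).

Problem sizes used by the shipped tests were chosen to exercise the
statistics at realistic counts while keeping the default suite fast: the
golden cohort runs at its full 1750 participants; the recovery harness uses
200 replicates of 600-participant cohorts (expected cell counts ≈ 30 and
24, where the log-normal interval is well behaved); the penetrance
monotonicity sweep uses smaller cohorts because it only compares means.

What the simulations do **not** emulate: haplotype/LD structure and phase,
de novo mutation, oligogenic and polygenic effects, gene–environment
interaction, recall error and incompleteness of self-reported histories,
and real per-gene carrier spectra. Passing the packaged tests therefore
demonstrates that the *pipeline machinery* is correct and calibrated under
its own generative assumptions — not that those assumptions describe any
particular population.

## Degenerate inputs and tie-breaks

Empty VCFs yield empty (not failing) record sets; duplicated annotation
keys, orphan annotation rows and unannotated VCF records are errors naming
the offending keys; two fathers, unknown relation terms and missing
lineages are pedigree structure errors; a pedigree marked
`fh_available = false` must have no relatives. A variant matching several
candidate routes records only the highest-priority route. Comparisons
against an empty cohort are suppressed and the cohort flagged rather than
producing NaNs.

## Known limitations

* The ruleset is an approximation of clinical testing criteria, not a
  transcription of any guideline edition; borderline pedigrees that a
  clinical team would debate are flagged `ambiguous`, and the flag cannot
  reproduce the outcome of human consensus.
* Automated ACMG evidence covers only mechanically derivable codes, so
  classifications that in practice rest on curated literature evidence will
  be under-called (this is why the VUS pool carries a
  `potential_pathogenic` flag instead).
* Compound-heterozygous AR calls assume trans phase.
* Copy-number variation is out of scope; inputs are small variants only.
* The statistics module treats participants as unrelated; it does not model
  relatedness between study participants.
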