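# a small two-sample VCF + annotation fixture built in code
write_fixture_vcf <- function(dir, genes, n_off_panel = 0) {
  n <- length(genes) + n_off_panel
  gene <- c(genes, rep("OFFPANEL1", n_off_panel))
  chrom <- rep("1", n); pos <- 1000 + seq_len(n) * 10
  gt_a <- rep(c("0/1", "0/0"), length.out = n)
  gt_b <- rep(c("0/0", "1/1"), length.out = n)
  vcf <- file.path(dir, "f.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(chrom, pos, ".", "C", "T", ".", "PASS", ".", "GT", gt_a, gt_b, sep = "\t")
  ), vcf)
  ann <- tibble::tibble(
    chrom = chrom, pos = pos, ref = "C", alt = "T", gene = gene,
    hgvs_c = NA, hgvs_p = NA, consequence = "missense",
    af_local = 0.001, af_gnomad = 0.001, clinvar_assertion = "vus",
    has_lp_or_p_entry = FALSE, revel = 0.5
  )
  ann_path <- file.path(dir, "f.tsv")
  readr::write_tsv(ann, ann_path, na = "")
  list(vcf = vcf, ann = ann_path)
}

test_that("VCF + annotation join yields one record per carrying sample, panel-scoped", {
  d <- withr::local_tempdir()
  fx <- write_fixture_vcf(d, genes = rep(c("BRCA1", "BRCA2", "MUTYH"), 3),
                          n_off_panel = 3)
  v <- suppressMessages(read_variants(fx$vcf, fx$ann, small_panel()))
  # 12 sites, each carried by exactly one of the two samples; 3 off panel
  expect_equal(nrow(v), 9)
  expect_equal(attr(v, "off_panel"), 3)
  expect_setequal(unique(v$gene), c("BRCA1", "BRCA2", "MUTYH"))
  expect_setequal(unique(v$zygosity), c("het", "hom"))
  expect_true(all(v$participant_id %in% c("S1", "S2")))
})

test_that("an empty VCF yields an empty record set", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "e.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1"), collapse = "\t")), vcf)
  ann <- file.path(d, "e.tsv")
  readr::write_tsv(tibble::tibble(
    chrom = character(), pos = double(), ref = character(), alt = character(),
    gene = character(), hgvs_c = character(), hgvs_p = character(),
    consequence = character(), af_local = double(), af_gnomad = double(),
    clinvar_assertion = character(), has_lp_or_p_entry = logical(),
    revel = double()), ann)
  v <- read_variants(vcf, ann, small_panel())
  expect_equal(nrow(v), 0)
})

test_that("annotation join errors name the offending keys", {
  d <- withr::local_tempdir()
  fx <- write_fixture_vcf(d, genes = c("BRCA1", "BRCA2"))
  ann <- readr::read_tsv(fx$ann,
                         col_types = readr::cols(.default = readr::col_character()))
  # duplicated key
  readr::write_tsv(rbind(ann, ann[1, ]), fx$ann, na = "")
  expect_error(read_variants(fx$vcf, fx$ann, small_panel()),
               "duplicated annotation key", class = "fhc_data_error")
  # orphan annotation row
  extra <- ann[1, ]; extra$pos <- 999999
  readr::write_tsv(rbind(ann, extra), fx$ann, na = "")
  expect_error(read_variants(fx$vcf, fx$ann, small_panel()),
               "999999", class = "fhc_data_error")
  # VCF record with no annotation
  readr::write_tsv(ann[-1, ], fx$ann, na = "")
  expect_error(read_variants(fx$vcf, fx$ann, small_panel()),
               "no annotation row", class = "fhc_data_error")
})

test_that("frequency filter keeps records strictly below threshold in both sources", {
  v <- dplyr::bind_rows(
    make_variant(af_gnomad = 0.05),                      # above
    make_variant(af_local = 5e-4),                       # below, other absent
    make_variant(af_gnomad = 0.01),                      # exactly at: excluded
    make_variant(af_local = 0.005, af_gnomad = 0.0099),  # both below
    make_variant()                                       # both absent
  )
  kept <- frequency_filter(v)
  expect_equal(nrow(kept), 3)
  expect_true(all(is.na(kept$af_gnomad) | kept$af_gnomad < 0.01))
  # idempotent, and a subset of its input
  expect_equal(frequency_filter(kept), kept)
  expect_error(frequency_filter(v, 0), class = "fhc_config_error")
  expect_error(frequency_filter(v, 1.5), class = "fhc_config_error")
})
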