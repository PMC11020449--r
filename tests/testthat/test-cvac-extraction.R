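make_vcf <- function(rows, ...) {
  write_test_vcf(withr::local_tempfile(fileext = ".vcf",
                                       .local_envir = parent.frame()),
                 rows, ...)
}

test_that("het-site filtering enforces depth, quality, filter and allele
          rules", {
  vcf <- make_vcf(c(
    vcf_row(3000010, "C", "T", dp = 11, gq = 20),              # boundary keep
    vcf_row(3000020, "C", "T", dp = 10, gq = 60),              # depth strict
    vcf_row(3000030, "C", "T", dp = 50, gq = 19),              # GQ too low
    vcf_row(3000040, "C", "T", dp = 50, gq = 60,
            filter = "VQSRTrancheSNP99.90to100.00"),           # failed VQSR
    vcf_row(3000050, "C", "T", gt = "1/1"),                    # hom alt
    vcf_row(3000060, "C", "T", gt = "0/0"),                    # hom ref
    vcf_row(3000070, "C", "CA"),                               # 1bp ins: keep
    vcf_row(3000080, "CAT", "C"),                              # 2bp del: drop
    vcf_row(3000090, "AT", "GC"),                              # MNV: drop
    vcf_row(3000100, "G", "A", chrom = "1")                    # not X: drop
  ))
  sites <- filter_het_sites(vcf)
  expect_equal(sites$pos, c(3000010, 3000070))
  expect_equal(sites$alt_allele, c("T", "CA"))
})

test_that("multi-allelic records decompose and only 0/k genotypes are het", {
  vcf <- make_vcf(c(
    vcf_row(3000010, "C", "T,G", gt = "0/2"),   # het on second alt
    vcf_row(3000020, "C", "T,G", gt = "1/2")    # no ref allele: not het
  ))
  sites <- filter_het_sites(vcf)
  expect_equal(sites$pos, 3000010)
  expect_equal(sites$alt_allele, "G")
})

test_that("missing FORMAT fields skip the record with a warning; '.' FILTER
          obeys strict mode", {
  vcf <- make_vcf(c(
    sprintf("X\t%d\t.\tC\tT\t100\tPASS\t.\tGT\t0/1", 3000010),
    vcf_row(3000020, "C", "T", filter = ".")
  ))
  expect_warning(sites <- filter_het_sites(vcf), "missing GQ or DP")
  expect_equal(sites$pos, 3000020)
  suppressWarnings({
    strict <- filter_het_sites(vcf, strict_filter = TRUE)
  })
  expect_equal(nrow(strict), 0)
})

test_that("PAR exclusion removes inside sites, keeps outside, warns when
          nothing is left", {
  sites <- rbind(het_site(1000000), het_site(3000000), het_site(154931050))
  suppressMessages(out <- exclude_regions(sites, par_regions_hg19()))
  expect_equal(out$pos, 3000000)
  suppressMessages(expect_warning(
    exclude_regions(het_site(1000000), par_regions_hg19()),
    "all sites fell inside"))
  expect_warning(exclude_regions(sites, GenomicRanges::GRanges()), "empty")
})

test_that("coding restriction respects the BED half-open convention", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("X\t99\t200\texon1", bed)   # covers 1-based 100..200
  coding <- read_intervals(bed, "coding")
  sites <- rbind(het_site(100), het_site(200), het_site(201))
  out <- restrict_to_coding(sites, coding)
  expect_equal(out$pos, c(100, 200))
  # absent coding set: documented bypass
  expect_message(out2 <- restrict_to_coding(sites, NULL), "skipped")
  expect_equal(nrow(out2), 3)
})

test_that("filtering steps commute (region exclusion vs quality filter)", {
  vcf <- make_vcf(c(
    vcf_row(1000000, "C", "T"),             # in PAR1, good quality
    vcf_row(3000000, "C", "T"),             # keep
    vcf_row(3000010, "C", "T", dp = 5),     # low depth
    vcf_row(1000010, "C", "T", gq = 10)     # in PAR1 and low GQ
  ))
  a <- suppressMessages(exclude_regions(filter_het_sites(vcf),
                                        par_regions_hg19()))
  all_sites <- filter_het_sites(vcf, min_dna_depth = 0, min_gq = 0)
  b0 <- suppressMessages(exclude_regions(all_sites, par_regions_hg19()))
  b <- b0[b0$dna_depth > 10 & b0$genotype_quality >= 20, , drop = FALSE]
  rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("sites_to_bed converts to 0-based half-open and deduplicates", {
  expect_equal(sites_to_bed(het_site(100)), "X\t99\t100")
  expect_equal(sites_to_bed(het_site(100)[0, ]), character(0))
  two <- rbind(het_site(100, alt = "T"), het_site(100, alt = "G"))
  expect_equal(sites_to_bed(two), "X\t99\t100")
})

test_that("gene annotation fills symbols, sentinels and deterministic
          tie-breaks", {
  gm <- make_intervals(c("X", "X", "X"), c(100, 500, 450),
                       c(400, 900, 600),
                       name = c("GENE_A", "GENE_B", "GENE_C"),
                       role = "gene_map")
  cv <- data.frame(sample_id = "S", chrom = "X",
                   pos = c(200, 550, 1000), ref_allele = "C",
                   alt_allele = "T", ref_count = 5L, alt_count = 5L,
                   total_depth = 10L, stringsAsFactors = FALSE)
  out <- suppressMessages(annotate_genes(cv, gm))
  # pos 550 overlaps GENE_B (500-900) and GENE_C (450-600):
  # first-by-coordinate wins
  expect_equal(out$gene_symbol, c("GENE_A", "GENE_C", "."))
})

test_that("CVAC TSV writing and reading round-trips exactly", {
  cv <- data.frame(sample_id = "S1", chrom = "X",
                   pos = c(100L, 200L), ref_allele = c("C", "G"),
                   alt_allele = c("T", "GA"), ref_count = c(7L, 0L),
                   alt_count = c(3L, 12L), total_depth = c(10L, 12L),
                   gene_symbol = c("GENE_A", "."), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cvac(cv, path)
  expect_equal(read_cvac(path), cv)
  # invariant: total_depth recomputed equals ref + alt
  rt <- read_cvac(path)
  expect_equal(rt$total_depth, rt$ref_count + rt$alt_count)
})
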