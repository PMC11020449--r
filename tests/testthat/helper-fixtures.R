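## shared helpers: independent oracles and tiny in-code fixtures

## beta-binomial pmf by an independent route: pmf(0) from log-gamma, then
## the one-step recurrence pmf(x+1)/pmf(x) = (n-x)(x+a) / ((x+1)(n-x-1+b))
oracle_bb_pmf <- function(n, mu, sigma) {
  a <- mu / sigma; b <- (1 - mu) / sigma
  p <- numeric(n + 1)
  # pmf(0) = B(a, n + b) / B(a, b), via log-gamma
  p[1] <- exp(lgamma(n + b) - lgamma(n + a + b) + lgamma(a + b) - lgamma(b))
  for (x in 0:(n - 1)) {
    p[x + 2] <- p[x + 1] * (n - x) * (x + a) / ((x + 1) * (n - x - 1 + b))
  }
  p
}

## two-sided doubled-minimum-tail p-value from the oracle pmf
oracle_two_sided_p <- function(x, n, mu, sigma) {
  pmf <- oracle_bb_pmf(n, mu, sigma)
  min(1, 2 * min(sum(pmf[1:(x + 1)]), sum(pmf[(x + 1):(n + 1)])))
}

## Clopper-Pearson interval by root-finding on binomial tail probabilities
oracle_clopper_pearson <- function(k, n, conf = 0.95) {
  alpha <- 1 - conf
  lower <- if (k == 0) 0 else
    stats::uniroot(function(p) 1 - stats::pbinom(k - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (k == n) 1 else
    stats::uniroot(function(p) stats::pbinom(k, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower, upper)
}

## minimal VCF writer for extraction tests
write_test_vcf <- function(path, rows, sample = "S1",
                           chrom = "X", extra_header = character()) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=X,length=155270560>",
    "##contig=<ID=1,length=249250621>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    extra_header,
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    rows), path)
  path
}

vcf_row <- function(pos, ref, alt, gt = "0/1", gq = 60, dp = 50,
                    filter = "PASS", chrom = "X") {
  sprintf("%s\t%d\t.\t%s\t%s\t100\t%s\t.\tGT:GQ:DP\t%s:%d:%d",
          chrom, pos, ref, alt, filter, gt, gq, dp)
}

## a het-site data.frame row without going through a VCF
het_site <- function(pos, ref = "C", alt = "T", gq = 60, dp = 50) {
  data.frame(chrom = "X", pos = pos, ref_allele = ref, alt_allele = alt,
             genotype_quality = gq, dna_depth = dp, filter_status = "PASS",
             stringsAsFactors = FALSE)
}

## small null cohort CVAC table: n_samples x n_sites, all truly 50:50
make_null_cohort <- function(n_samples = 20, n_sites = 30, depth = 40,
                             seed = 11, sigma = 0.02) {
  withr::with_seed(seed, {
    pos <- sort(sample(3e6:1.5e8, n_sites))
    do.call(rbind, lapply(seq_len(n_samples), function(j) {
      r <- rbetabinom(n_sites, depth, 0.5, sigma)
      data.frame(sample_id = sprintf("N%02d", j), chrom = "X", pos = pos,
                 ref_allele = "C", alt_allele = "T",
                 ref_count = r, alt_count = depth - r,
                 total_depth = depth,
                 gene_symbol = paste0("G", rep(1:ceiling(n_sites / 5),
                                               each = 5)[seq_len(n_sites)]),
                 stringsAsFactors = FALSE)
    }))
  })
}
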