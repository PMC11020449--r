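## Synthetic cohorts with known XCI skew. Cellular mosaicism is collapsed to
## a site-level beta-binomial around the sample's XCI ratio rho: each site's
## expected reference fraction is rho or 1 - rho (unphased; fair coin per
## site), escape sites express biallelically (0.5) regardless of rho.

#' Specify a synthetic XCI cohort
#'
#' The defaults emulate the study conditions used throughout the package's
#' tests: a 135-female reference cohort in which 90% of samples have near-
#' random XCI ratios (rho ~ U(0.5, 0.65)) and 10% are strongly skewed
#' (rho ~ U(0.85, 0.99)); 150 shared heterozygous coding sites grouped into
#' genes of ~5 sites; per-site RNA depth ~ NB(mean 50, size 5) capped at
#' 500; site-level beta-binomial overdispersion 0.02; 5% of sites in escape
#' genes.
#'
#' @param n_samples number of samples.
#' @param n_sites number of sites in the shared cohort site map.
#' @param rho per-sample XCI ratio(s) in \[0.5, 1\] (fraction of cells with
#'   the same X active); a scalar is recycled. `NULL` draws from the
#'   mixture below.
#' @param mixture list(`weight_skewed`, `random_range`, `skewed_range`) used
#'   when `rho` is `NULL`.
#' @param depth_mean,depth_size negative-binomial RNA depth model.
#' @param depth_min,depth_max clamp for drawn depths.
#' @param sigma_site site-level beta-binomial overdispersion around rho.
#' @param escape_fraction fraction of sites in escape genes (biallelic
#'   expression regardless of rho).
#' @param site_observed_prob probability that a cohort-map site is
#'   heterozygous (hence observed) in a given sample.
#' @param phase_randomization if `TRUE` (default) the reference allele lands
#'   on either haplotype with probability 1/2 per site; if `FALSE` the
#'   expected reference fraction is always `rho`.
#' @param genes_per_block sites per synthetic gene.
#' @param seed master seed; all randomness flows from it.
#' @return a `simulation_spec` list including the resolved per-sample `rho`,
#'   the site map (`chrom, pos, ref, alt, gene, escape`) and all parameters.
#' @export
simulation_spec <- function(n_samples = 135, n_sites = 150, rho = NULL,
                            mixture = list(weight_skewed = 0.1,
                                           random_range = c(0.5, 0.65),
                                           skewed_range = c(0.85, 0.99)),
                            depth_mean = 50, depth_size = 5,
                            depth_min = 0, depth_max = 500,
                            sigma_site = 0.02, escape_fraction = 0.05,
                            site_observed_prob = 0.7,
                            phase_randomization = TRUE,
                            genes_per_block = 5, seed = 1) {
  spec <- with_local_seed(seed, {
    if (is.null(rho)) {
      skewed <- stats::runif(n_samples) < mixture$weight_skewed
      rho <- ifelse(skewed,
                    stats::runif(n_samples, mixture$skewed_range[1],
                                 mixture$skewed_range[2]),
                    stats::runif(n_samples, mixture$random_range[1],
                                 mixture$random_range[2]))
    } else {
      rho <- rep_len(rho, n_samples)
    }
    if (any(rho < 0.5 | rho > 1)) stop("rho must lie in [0.5, 1]")
    ## site map: sorted positions on X between the PARs, blocked into genes
    pos <- sort(sample(2700000:154900000, n_sites))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1),
                  character(1))
    n_genes <- max(1L, ceiling(n_sites / genes_per_block))
    gene <- paste0("GENE", rep(seq_len(n_genes),
                               each = genes_per_block)[seq_len(n_sites)])
    ## whole genes are flagged escape until ~escape_fraction of sites covered
    esc_genes <- character(0)
    if (escape_fraction > 0) {
      target <- escape_fraction * n_sites
      for (g in sample(unique(gene))) {
        if (sum(gene %in% esc_genes) >= target) break
        esc_genes <- c(esc_genes, g)
      }
    }
    list(rho = rho,
         site_map = data.frame(chrom = "X", pos = pos, ref = ref, alt = alt,
                               gene = gene, escape = gene %in% esc_genes,
                               stringsAsFactors = FALSE))
  })
  structure(list(
    n_samples = n_samples, n_sites = n_sites, rho = spec$rho,
    site_map = spec$site_map,
    depth_mean = depth_mean, depth_size = depth_size,
    depth_min = depth_min, depth_max = depth_max,
    sigma_site = sigma_site, escape_fraction = escape_fraction,
    site_observed_prob = site_observed_prob,
    phase_randomization = phase_randomization, seed = seed),
    class = "simulation_spec")
}

#' Simulate one sample's CVAC records with known truth
#'
#' Deterministic given `spec$seed` and `sample_index` (each sample draws
#' from its own derived RNG stream, so samples can be regenerated
#' independently).
#'
#' @param spec a [simulation_spec()].
#' @param sample_index which sample (1-based; selects `spec$rho`).
#' @return list with `cvac` (CVAC data.frame incl. `gene_symbol`) and
#'   `truth` (per-site `sample_id, chrom, pos, rho, p_ref, escape` plus the
#'   sample's true status at rho > 0.75).
#' @export
simulate_sample <- function(spec, sample_index) {
  stopifnot(inherits(spec, "simulation_spec"),
            sample_index >= 1, sample_index <= spec$n_samples)
  rho <- spec$rho[sample_index]
  sid <- sprintf("SIM_%03d", sample_index)
  with_local_seed(derive_seed(spec$seed, sample_index), {
    m <- spec$site_map
    obs <- which(stats::runif(nrow(m)) < spec$site_observed_prob)
    m <- m[obs, , drop = FALSE]
    k <- nrow(m)
    flip <- if (spec$phase_randomization) stats::runif(k) < 0.5
            else rep(TRUE, k)
    p_ref <- ifelse(m$escape, 0.5, ifelse(flip, rho, 1 - rho))
    depth <- pmin(pmax(stats::rnbinom(k, mu = spec$depth_mean,
                                      size = spec$depth_size),
                       spec$depth_min), spec$depth_max)
    ref <- integer(k)
    pos_depth <- depth > 0
    if (spec$sigma_site > 0) {
      ref[pos_depth] <- rbetabinom(sum(pos_depth), depth[pos_depth],
                                   pmin(pmax(p_ref[pos_depth], 1e-9),
                                        1 - 1e-9),
                                   spec$sigma_site)
    } else {
      ref[pos_depth] <- stats::rbinom(sum(pos_depth), depth[pos_depth],
                                      p_ref[pos_depth])
    }
    cvac <- data.frame(sample_id = sid, chrom = m$chrom, pos = m$pos,
                       ref_allele = m$ref, alt_allele = m$alt,
                       ref_count = as.integer(ref),
                       alt_count = as.integer(depth - ref),
                       total_depth = as.integer(depth),
                       gene_symbol = m$gene, stringsAsFactors = FALSE,
                       row.names = NULL)
    truth <- data.frame(sample_id = sid, chrom = m$chrom, pos = m$pos,
                        rho = rho, p_ref = p_ref, escape = m$escape,
                        true_status = ifelse(rho > 0.75, "skewed", "random"),
                        stringsAsFactors = FALSE, row.names = NULL)
    list(cvac = cvac, truth = truth)
  })
}

#' Simulate a full reference cohort sharing one site map
#'
#' @param spec a [simulation_spec()].
#' @return list with `cvac` (all samples' records, rbind-ed), `truth`
#'   (per-sample `sample_id, rho, true_status`) and the `spec`.
#' @export
simulate_reference_cohort <- function(spec) {
  sims <- lapply(seq_len(spec$n_samples), function(i)
    simulate_sample(spec, i))
  cvac <- do.call(rbind, lapply(sims, `[[`, "cvac"))
  truth <- do.call(rbind, lapply(sims, function(s)
    s$truth[1, c("sample_id", "rho", "true_status"), drop = FALSE]))
  rownames(truth) <- NULL
  list(cvac = cvac, truth = truth, spec = spec)
}

#' Write a synthetic VCF + mpileup + BED fixture bundle
#'
#' Emits, for one simulated sample: a minimal VCF v4.2 of heterozygous
#' genotypes (GT/DP/GQ), an mpileup text file whose hand-countable base
#' strings reproduce the simulated allele counts exactly, and BED files for
#' the PARs, a coding envelope around the site map, the gene map and the
#' escape genes. All files are synthetic and labelled as such in their
#' headers. With `include_decoys = TRUE`, three decoy records exercise the
#' extraction filters: a site inside PAR1, a site with GQ = 19 and a site
#' with DNA depth 10.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if needed).
#' @param sample_index which sample to emit.
#' @param include_decoys add filter-exercising decoy records?
#' @return named list of file paths, plus the emitted `cvac`/`truth` tables.
#' @export
emit_fixtures <- function(spec, dir, sample_index = 1,
                          include_decoys = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_sample(spec, sample_index)
  cvac <- sim$cvac
  sid <- cvac$sample_id[1]
  vcf_rows <- data.frame(pos = cvac$pos, ref = cvac$ref_allele,
                         alt = cvac$alt_allele, gq = 99L, dp = 50L,
                         filter = "PASS", stringsAsFactors = FALSE)
  pile_rows <- cvac
  if (include_decoys) {
    decoys <- data.frame(pos = c(70000L, 5000000L, 5000100L),
                         ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                         gq = c(99L, 19L, 99L), dp = c(50L, 50L, 10L),
                         filter = "PASS", stringsAsFactors = FALSE)
    vcf_rows <- rbind(vcf_rows, decoys)
  }
  vcf_rows <- vcf_rows[order(vcf_rows$pos), , drop = FALSE]
  vcf_path <- file.path(dir, paste0(sid, ".synthetic.vcf"))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=xciskew synthetic fixture generator",
    "##contig=<ID=X,length=155270560>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sid),
    sprintf("X\t%d\t.\t%s\t%s\t100\t%s\t.\tGT:GQ:DP\t0/1:%d:%d",
            vcf_rows$pos, vcf_rows$ref, vcf_rows$alt, vcf_rows$filter,
            vcf_rows$gq, vcf_rows$dp)), vcf_path)
  ## mpileup: ref reads as '.' (fwd) and ',' (rev), alt reads as letters;
  ## all base qualities 'J' (phred 41)
  mp_path <- file.path(dir, paste0(sid, ".synthetic.mpileup"))
  mp <- vapply(seq_len(nrow(pile_rows)), function(i) {
    r <- pile_rows$ref_count[i]; a <- pile_rows$alt_count[i]
    nf <- ceiling(r / 2)
    bases <- paste0(strrep(".", nf), strrep(",", r - nf),
                    strrep(pile_rows$alt_allele[i], ceiling(a / 2)),
                    strrep(tolower(pile_rows$alt_allele[i]), floor(a / 2)))
    if (r + a == 0) bases <- "*"
    sprintf("X\t%d\t%s\t%d\t%s\t%s", pile_rows$pos[i],
            pile_rows$ref_allele[i], r + a, bases,
            strrep("J", max(1L, r + a)))
  }, character(1))
  writeLines(mp, mp_path)
  ## BEDs (0-based half-open)
  par_path <- file.path(dir, "par.synthetic.bed")
  writeLines(c("X\t60000\t2699520\tPAR1", "X\t154931043\t155260560\tPAR2"),
             par_path)
  m <- spec$site_map
  coding_path <- file.path(dir, "coding.synthetic.bed")
  gene_path <- file.path(dir, "genes.synthetic.bed")
  escape_path <- file.path(dir, "escape.synthetic.bed")
  gene_bed <- do.call(rbind, lapply(split(m, m$gene), function(g) {
    data.frame(start = min(g$pos) - 1L, end = max(g$pos),
               gene = g$gene[1], escape = g$escape[1])
  }))
  gene_bed <- gene_bed[order(gene_bed$start), , drop = FALSE]
  writeLines(sprintf("X\t%d\t%d\t%s", gene_bed$start, gene_bed$end,
                     gene_bed$gene), gene_path)
  writeLines(sprintf("X\t%d\t%d\t%s", gene_bed$start, gene_bed$end,
                     gene_bed$gene), coding_path)
  esc <- gene_bed[gene_bed$escape, , drop = FALSE]
  writeLines(sprintf("X\t%d\t%d\t%s", esc$start, esc$end, esc$gene),
             escape_path)
  list(vcf = vcf_path, mpileup = mp_path, par = par_path,
       coding = coding_path, genes = gene_path, escape = escape_path,
       cvac = cvac, truth = sim$truth)
}
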