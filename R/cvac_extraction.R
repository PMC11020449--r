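## CVAC extraction: exome heterozygous calls + RNA-seq pileups -> filtered,
## gene-annotated allele-count tables.

#' Extract filtered heterozygous X-linked sites from a VCF
#'
#' Keeps biallelic heterozygous genotypes (exactly one reference plus one
#' alternate allele) on chromosome X that pass the variant filter, carry more
#' than `min_dna_depth` reads (strict) and genotype quality of at least
#' `min_gq`. Multi-allelic records are decomposed into ref/alt pairings and
#' each pairing evaluated. Only SNVs and 1-bp indels are retained. Records
#' with missing GQ or DP are skipped with a warning.
#'
#' @param vcf path to a VCF file, or a `VariantAnnotation::CollapsedVCF`.
#' @param sample_id sample column to use; default the first sample.
#' @param min_dna_depth exome read-depth threshold, kept if `DP > min_dna_depth`.
#' @param min_gq genotype-quality threshold, kept if `GQ >= min_gq`.
#' @param strict_filter if `TRUE`, a missing FILTER (".") is rejected rather
#'   than treated as PASS.
#' @return data.frame of het sites with columns
#'   `chrom, pos, ref_allele, alt_allele, genotype_quality, dna_depth,
#'   filter_status`.
#' @export
filter_het_sites <- function(vcf, sample_id = NULL,
                             min_dna_depth = 10, min_gq = 20,
                             strict_filter = FALSE) {
  if (is.character(vcf)) {
    if (!file.exists(vcf)) stop("VCF file not found: ", vcf)
    vcf <- VariantAnnotation::readVcf(vcf, genome = "unknown")
  }
  geno <- VariantAnnotation::geno(vcf)
  samples <- colnames(geno$GT)
  if (is.null(sample_id)) sample_id <- samples[1]
  if (!sample_id %in% samples) {
    stop("sample '", sample_id, "' not found in VCF (has: ",
         paste(samples, collapse = ", "), ")")
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- normalize_chrom(as.character(GenomicRanges::seqnames(rr)))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt_list <- rr$ALT  # DNAStringSetList (or CharacterList)
  filt <- as.character(rr$FILTER)
  gt <- geno$GT[, sample_id]
  gq <- if ("GQ" %in% names(geno)) geno$GQ[, sample_id] else
    rep(NA_real_, length(gt))
  dp <- if ("DP" %in% names(geno)) geno$DP[, sample_id] else
    rep(NA_real_, length(gt))

  n_missing <- 0L
  out <- vector("list", length(gt))
  for (i in seq_along(gt)) {
    if (chrom[i] != "X") next
    pass <- filt[i] == "PASS" || (!strict_filter && filt[i] %in% c(".", ""))
    if (!pass) next
    if (is.na(gq[i]) || is.na(dp[i])) { n_missing <- n_missing + 1L; next }
    if (!(dp[i] > min_dna_depth) || gq[i] < min_gq) next
    alleles <- strsplit(gt[i], "[/|]")[[1]]
    if (length(alleles) != 2 || any(alleles == ".")) next
    alleles <- suppressWarnings(as.integer(alleles))
    if (any(is.na(alleles))) next
    # heterozygous = exactly one ref (0) and one alt (>0) allele
    if (sum(alleles == 0) != 1 || sum(alleles > 0) != 1) next
    k <- alleles[alleles > 0]
    alts <- as.character(alt_list[[i]])
    if (k > length(alts)) next
    alt <- alts[k]
    if (!is_snv_or_1bp_indel(ref[i], alt)) next
    out[[i]] <- data.frame(
      chrom = "X", pos = pos[i],
      ref_allele = ref[i], alt_allele = alt,
      genotype_quality = as.numeric(gq[i]), dna_depth = as.numeric(dp[i]),
      filter_status = filt[i], stringsAsFactors = FALSE)
  }
  if (n_missing > 0L) {
    warning(n_missing, " record(s) skipped for missing GQ or DP")
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- empty_het_sites()
  rownames(res) <- NULL
  res
}

empty_het_sites <- function() {
  data.frame(chrom = character(), pos = integer(),
             ref_allele = character(), alt_allele = character(),
             genotype_quality = numeric(), dna_depth = numeric(),
             filter_status = character(), stringsAsFactors = FALSE)
}

## SNV, or 1-bp insertion/deletion with a 1-bp anchor
is_snv_or_1bp_indel <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (ref == alt) return(FALSE)
  (lr == 1 && la == 1) || (abs(lr - la) == 1 && min(lr, la) == 1 &&
                             max(lr, la) == 2)
}

#' Drop sites falling inside excluded regions (e.g. the PARs)
#'
#' @param sites het-site or CVAC data.frame with `chrom`/`pos` columns.
#' @param regions a `GRanges` of regions to exclude
#'   (default [par_regions_hg19()]).
#' @return the sites outside every excluded interval; the number removed is
#'   reported via `message()`.
#' @export
exclude_regions <- function(sites, regions = par_regions_hg19()) {
  if (length(regions) == 0) {
    warning("empty exclusion region set; returning sites unchanged")
    return(sites)
  }
  if (nrow(sites) == 0) return(sites)
  hits <- GenomicRanges::findOverlaps(sites_as_granges(sites), regions)
  drop <- unique(S4Vectors::queryHits(hits))
  message(length(drop), " site(s) removed by region exclusion")
  out <- if (length(drop)) sites[-drop, , drop = FALSE] else sites
  if (nrow(out) == 0) warning("all sites fell inside excluded regions")
  rownames(out) <- NULL
  out
}

#' Keep only sites overlapping coding intervals
#'
#' @param sites het-site or CVAC data.frame with `chrom`/`pos`.
#' @param coding a `GRanges` of coding intervals, or `NULL` to skip the
#'   restriction (logged).
#' @return the subset of sites inside a coding interval.
#' @export
restrict_to_coding <- function(sites, coding) {
  if (is.null(coding)) {
    message("no coding interval set supplied; coding restriction skipped")
    return(sites)
  }
  if (nrow(sites) == 0) {
    warning("restrict_to_coding: empty site list")
    return(sites)
  }
  hits <- GenomicRanges::findOverlaps(sites_as_granges(sites), coding)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write het sites as a BED file of 1-bp query intervals
#'
#' Emits one 0-based half-open BED line per distinct position
#' (`start = pos - 1`, `end = pos`); positions duplicated by multi-allelic
#' decomposition are collapsed.
#'
#' @param sites het-site data.frame.
#' @param path output path, or `NULL` to return the lines invisibly only.
#' @return (invisibly) the BED lines as a character vector.
#' @export
sites_to_bed <- function(sites, path = NULL) {
  if (nrow(sites) == 0) {
    lines <- character()
  } else {
    u <- unique(sites[, c("chrom", "pos")])
    u <- u[order(u$chrom, u$pos), , drop = FALSE]
    lines <- sprintf("%s\t%d\t%d", u$chrom, u$pos - 1L, u$pos)
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Annotate CVAC records with containing gene symbols
#'
#' Positions inside a gene interval get that gene's symbol; intergenic
#' positions get the sentinel `"."` (they remain usable by the position and
#' global models but are excluded from gene models). Overlapping genes are
#' resolved deterministically: first by interval start, then by name; a note
#' is logged when this happens.
#'
#' @param cvacs CVAC data.frame (see [count_alleles_mpileup()]).
#' @param gene_map a `GRanges` with a `name` metadata column of gene symbols.
#' @return the CVAC data.frame with a `gene_symbol` column filled in.
#' @export
annotate_genes <- function(cvacs, gene_map) {
  if (nrow(cvacs) == 0) {
    cvacs$gene_symbol <- character(0)
    return(cvacs)
  }
  if (is.null(S4Vectors::mcols(gene_map)$name)) {
    stop("gene_map must carry gene symbols in a 'name' column")
  }
  ## deterministic tie-break: order genes by start coordinate then name
  ord <- order(GenomicRanges::start(gene_map),
               S4Vectors::mcols(gene_map)$name)
  gene_map <- gene_map[ord]
  hits <- GenomicRanges::findOverlaps(sites_as_granges(cvacs), gene_map)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (anyDuplicated(qh)) {
    message("position(s) overlapping multiple genes resolved ",
            "first-by-coordinate-then-name")
    keep <- !duplicated(qh)
    qh <- qh[keep]; sh <- sh[keep]
  }
  sym <- rep(".", nrow(cvacs))
  sym[qh] <- S4Vectors::mcols(gene_map)$name[sh]
  cvacs$gene_symbol <- sym
  cvacs
}

#' Write / read a CVAC allele-count table (TSV)
#'
#' Tab-separated with header
#' `sample_id chrom pos ref alt ref_count alt_count gene`; round-trips
#' exactly.
#'
#' @param cvacs CVAC data.frame.
#' @param path file path.
#' @return `read_cvac` returns the CVAC data.frame with internal column
#'   names (`ref_allele`, `alt_allele`, `gene_symbol`, `total_depth`).
#' @export
write_cvac <- function(cvacs, path) {
  out <- data.frame(sample_id = cvacs$sample_id,
                    chrom = cvacs$chrom, pos = cvacs$pos,
                    ref = cvacs$ref_allele, alt = cvacs$alt_allele,
                    ref_count = cvacs$ref_count, alt_count = cvacs$alt_count,
                    gene = if (!is.null(cvacs$gene_symbol)) cvacs$gene_symbol
                           else ".",
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cvac
#' @export
read_cvac <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(sample_id = "character",
                                        chrom = "character",
                                        ref = "character",
                                        alt = "character",
                                        gene = "character"))
  need <- c("sample_id", "chrom", "pos", "ref", "alt",
            "ref_count", "alt_count", "gene")
  if (!all(need %in% names(d))) {
    stop("CVAC file missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  if (any(d$ref_count < 0) || any(d$alt_count < 0)) {
    stop("CVAC file contains negative allele counts")
  }
  data.frame(sample_id = d$sample_id, chrom = normalize_chrom(d$chrom),
             pos = as.integer(d$pos),
             ref_allele = d$ref, alt_allele = d$alt,
             ref_count = as.integer(d$ref_count),
             alt_count = as.integer(d$alt_count),
             total_depth = as.integer(d$ref_count + d$alt_count),
             gene_symbol = d$gene, stringsAsFactors = FALSE)
}
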