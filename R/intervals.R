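#' Build an interval set from 1-based closed coordinates
#'
#' Intervals are carried as [GenomicRanges::GRanges] throughout the package
#' (1-based, closed). BED input/output is converted by [read_intervals()] /
#' [rtracklayer::export()], which handle BED's 0-based half-open dialect.
#'
#' @param chrom character vector of chromosome names (normalized to "X").
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param name optional feature names (e.g. gene symbols).
#' @param role one of `"coding"`, `"PAR"`, `"escape_genes"`,
#'   `"editing_sites"`, `"gene_map"`, `"other"`.
#' @return a `GRanges` with a `role` attribute and (if given) a `name`
#'   metadata column.
#' @export
make_intervals <- function(chrom, start, end,
                           name = NULL,
                           role = c("other", "coding", "PAR", "escape_genes",
                                    "editing_sites", "gene_map")) {
  role <- match.arg(role)
  if (any(start > end)) stop("interval with start > end")
  gr <- GenomicRanges::GRanges(normalize_chrom(chrom),
                               IRanges::IRanges(start = start, end = end))
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- as.character(name)
  attr(gr, "role") <- role
  gr
}

#' Read a BED file as an interval set
#'
#' BED3/BED6 via [rtracklayer::import()]; the 0-based half-open BED
#' convention is converted to 1-based closed `GRanges` coordinates.
#' Chromosome names are normalized ("chrX" -> "X").
#'
#' @param path BED file path.
#' @param role declared role of the intervals (see [make_intervals()]).
#' @return a `GRanges`.
#' @export
read_intervals <- function(path, role = "other") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  GenomeInfoDb::seqlevels(gr) <- normalize_chrom(GenomeInfoDb::seqlevels(gr))
  if (is.null(S4Vectors::mcols(gr)$name) ||
      all(is.na(S4Vectors::mcols(gr)$name))) {
    S4Vectors::mcols(gr)$name <- NULL
  }
  attr(gr, "role") <- role
  gr
}

#' GRCh37 pseudoautosomal regions on chromosome X
#'
#' PAR1 X:60,001-2,699,520 and PAR2 X:154,931,044-155,260,560 (GRCh37/hg19,
#' 1-based closed). These regions escape XCI and are excluded from analysis;
#' override with a BED file for other genome builds.
#'
#' @return a `GRanges` of the two PARs.
#' @export
par_regions_hg19 <- function() {
  make_intervals(c("X", "X"),
                 start = c(60001L, 154931044L),
                 end = c(2699520L, 155260560L),
                 name = c("PAR1", "PAR2"),
                 role = "PAR")
}

## GRanges of 1-bp positions for a site table (chrom/pos columns, 1-based)
sites_as_granges <- function(sites) {
  GenomicRanges::GRanges(normalize_chrom(sites$chrom),
                         IRanges::IRanges(start = sites$pos, width = 1L))
}
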