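## samtools-mpileup text parser. RNA allele counts at het sites are taken
## from the 6-column pileup format; mapping-quality filtering (MQ >= 20) is
## assumed to have been applied by the pileup producer (samtools mpileup
## -q 20 -Q 0 ...); this parser enforces base quality only.

#' Tokenize one mpileup base string against its quality string
#'
#' Handles the pileup grammar: `^X` read start (the mapping-quality
#' character is skipped), `$` read end, `./,` reference matches,
#' `ACGTN`/`acgtn` mismatches, `+N<seq>` / `-N<seq>` indels attached to the
#' preceding base, `*` deletion placeholders and `>`/`<` reference skips.
#' Each base-consuming token takes one character from the quality string.
#'
#' @param bases pileup base string (column 5).
#' @param quals pileup base-quality string (column 6), phred+33.
#' @return data.frame with one row per base-consuming token: `base` (the
#'   token character, upper-cased for letters), `indel` (attached inserted or
#'   deleted sequence, prefixed "+"/"-", or `NA`) and `qual` (phred score).
#' @export
parse_pileup_bases <- function(bases, quals) {
  bc <- strsplit(bases, "")[[1]]
  qc <- strsplit(quals, "")[[1]]
  base <- character(0); indel <- character(0)
  i <- 1L; nq <- 0L
  nb <- length(bc)
  while (i <= nb) {
    ch <- bc[i]
    if (ch == "^") {
      if (i + 1L > nb) stop("malformed pileup: trailing '^'")
      i <- i + 2L  # skip the mapping-quality character
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch %in% c("+", "-")) {
      if (length(base) == 0L) stop("malformed pileup: leading indel token")
      j <- i + 1L
      while (j <= nb && grepl("[0-9]", bc[j])) j <- j + 1L
      if (j == i + 1L) stop("malformed pileup: indel without length")
      len <- as.integer(paste(bc[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > nb) stop("malformed pileup: truncated indel sequence")
      seq <- paste(bc[j:(j + len - 1L)], collapse = "")
      indel[length(indel)] <- paste0(ch, toupper(seq))
      i <- j + len
    } else if (ch %in% c(".", ",", "*", ">", "<") ||
               grepl("[ACGTNacgtn]", ch)) {
      nq <- nq + 1L
      base <- c(base, if (grepl("[a-z]", ch)) toupper(ch) else ch)
      indel <- c(indel, NA_character_)
      i <- i + 1L
    } else {
      stop("malformed pileup: unexpected character '", ch, "'")
    }
  }
  if (nq != length(qc)) {
    stop("pileup base/quality length mismatch: ", nq, " bases vs ",
         length(qc), " quality characters")
  }
  data.frame(base = base, indel = indel,
             qual = as.integer(vapply(qc, function(q) utf8ToInt(q) - 33L,
                                      integer(1))),
             stringsAsFactors = FALSE)
}

#' Count reference/alternate alleles for one site from an mpileup line
#'
#' For SNV alleles, reference support is `.`/`,` (attached indels belong to a
#' different variant and do not disqualify the match) and alternate support
#' is a case-insensitive letter match. For a 1-bp insertion allele
#' (`C -> CA`), reads showing `.`/`,` followed by `+1A` count as alternate
#' and plain matches as reference; symmetrically `-1X` tokens support a 1-bp
#' deletion allele. `N`, `*` placeholders and `>`/`<` reference skips count
#' for neither allele. Only bases with quality `>= min_baseq` are counted.
#'
#' @param line one mpileup text line (6 columns), or a character vector of
#'   the already-split fields.
#' @param site one-row het-site data.frame (`chrom`, `pos`, `ref_allele`,
#'   `alt_allele`).
#' @param min_baseq minimum phred base quality (default 30).
#' @param line_number optional line number used in error messages.
#' @return one-row CVAC data.frame (without `sample_id`).
#' @export
count_alleles_from_mpileup <- function(line, site, min_baseq = 30,
                                       line_number = NA) {
  fields <- if (length(line) == 1L) strsplit(line, "\t")[[1]] else line
  if (length(fields) < 6L) {
    stop("mpileup line ", line_number, ": expected 6 columns, got ",
         length(fields))
  }
  chrom <- normalize_chrom(fields[1]); pos <- as.integer(fields[2])
  if (chrom != normalize_chrom(site$chrom) || pos != site$pos) {
    stop("mpileup line ", line_number, ": position ", chrom, ":", pos,
         " does not match site ", site$chrom, ":", site$pos)
  }
  tok <- tryCatch(parse_pileup_bases(fields[5], fields[6]),
                  error = function(e) {
                    stop("mpileup line ", line_number, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  tok <- tok[tok$qual >= min_baseq, , drop = FALSE]
  ref <- toupper(site$ref_allele); alt <- toupper(site$alt_allele)
  is_refmatch <- tok$base %in% c(".", ",") | tok$base == substr(ref, 1, 1)
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    ref_n <- sum(is_refmatch & tok$base %in% c(".", ","))
    ## explicit ref base letters also support ref (some pileup producers)
    ref_n <- ref_n + sum(tok$base == ref)
    alt_n <- sum(tok$base == alt)
  } else if (nchar(alt) > nchar(ref)) {
    ins <- paste0("+", substr(alt, 2, nchar(alt)))
    alt_n <- sum(is_refmatch & !is.na(tok$indel) & tok$indel == ins)
    ref_n <- sum(is_refmatch & (is.na(tok$indel) | tok$indel != ins))
  } else {
    del <- paste0("-", substr(ref, 2, nchar(ref)))
    alt_n <- sum(is_refmatch & !is.na(tok$indel) & tok$indel == del)
    ref_n <- sum(is_refmatch & (is.na(tok$indel) | tok$indel != del))
  }
  data.frame(chrom = chrom, pos = pos,
             ref_allele = site$ref_allele, alt_allele = site$alt_allele,
             ref_count = as.integer(ref_n), alt_count = as.integer(alt_n),
             total_depth = as.integer(ref_n + alt_n),
             stringsAsFactors = FALSE)
}

#' Build a CVAC table from an mpileup file and a het-site list
#'
#' Sites with no pileup line receive zero counts for both alleles.
#'
#' @param path mpileup text file.
#' @param sites het-site data.frame (see [filter_het_sites()]).
#' @param sample_id sample identifier stamped on every record.
#' @param min_baseq minimum phred base quality.
#' @return CVAC data.frame with columns `sample_id, chrom, pos, ref_allele,
#'   alt_allele, ref_count, alt_count, total_depth`.
#' @export
count_alleles_mpileup <- function(path, sites, sample_id, min_baseq = 30) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t")
  keys <- vapply(fields, function(f) {
    paste0(normalize_chrom(f[1]), ":", f[2])
  }, character(1))
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, , drop = FALSE]
    key <- paste0(normalize_chrom(site$chrom), ":", site$pos)
    j <- which(keys == key)
    if (length(j) == 0) {
      rec <- data.frame(chrom = normalize_chrom(site$chrom), pos = site$pos,
                        ref_allele = site$ref_allele,
                        alt_allele = site$alt_allele,
                        ref_count = 0L, alt_count = 0L, total_depth = 0L,
                        stringsAsFactors = FALSE)
    } else {
      rec <- count_alleles_from_mpileup(fields[[j[1]]], site, min_baseq,
                                        line_number = j[1])
    }
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  cbind(data.frame(sample_id = rep(sample_id, nrow(res)),
                   stringsAsFactors = FALSE), res)
}
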