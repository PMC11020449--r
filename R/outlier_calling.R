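## Outlier scoring of patient sites against the reference hierarchy.

#' Two-sided beta-binomial outlier p-value
#'
#' `p = min(1, 2 * min(P(X <= x), P(X >= x)))` under `BB(n, mu, sigma)`,
#' both tails inclusive of the observed point mass. Computed by exact
#' summation of the probability mass function.
#'
#' @param x observed reference-allele count, `0 <= x <= n`.
#' @param n total depth at the site, `n >= 1`.
#' @param params a [betabin_params()] (or anything with `$mu`, `$sigma`).
#' @return p-value in (0, 1].
#' @export
two_sided_pvalue <- function(x, n, params) {
  if (length(x) != 1 || length(n) != 1 || n < 1 || x < 0 || x > n) {
    stop("two_sided_pvalue: need scalar 0 <= x <= n with n >= 1")
  }
  pmf <- dbetabinom(0:n, n, params$mu, params$sigma)
  lower <- sum(pmf[seq_len(x + 1)])
  upper <- sum(pmf[seq.int(x + 1, n + 1)])
  min(1, 2 * min(lower, upper))
}

#' Select the most specific available model tier for a site
#'
#' Position model if one is keyed at `chrom:pos`; otherwise the gene model
#' for `gene_symbol`; otherwise the global model (always present).
#'
#' @param model an `xci_reference_model`.
#' @param chrom,pos site coordinates.
#' @param gene_symbol annotated gene symbol (`"."` or `NA` for intergenic).
#' @return list with `params` ([betabin_params()]) and `tier`.
#' @export
select_model <- function(model, chrom, pos, gene_symbol = ".") {
  key <- position_key(chrom, pos)
  p <- model$position_models[[key]]
  if (!is.null(p)) return(list(params = p, tier = "position"))
  if (!is.null(gene_symbol) && !is.na(gene_symbol) && gene_symbol != ".") {
    g <- model$gene_models[[gene_symbol]]
    if (!is.null(g)) return(list(params = g, tier = "gene"))
  }
  list(params = model$global_model, tier = "global")
}

#' Score one sample's CVAC records against the reference model
#'
#' Sites with `total_depth > min_test_depth` (strict) are tested with the
#' two-sided outlier p-value of the reference-allele count under the most
#' specific available model tier; patient counts are not smoothed and no
#' multiple-testing correction is applied. The per-sample summary reports
#' the percentage of significantly skewed sites over tested sites.
#'
#' @param cvacs CVAC data.frame for one sample (PAR-excluded).
#' @param model an `xci_reference_model`.
#' @param min_test_depth RNA depth threshold; a site is tested if
#'   `total_depth > min_test_depth`.
#' @param alpha significance level for the per-site call (raw p-values).
#' @return list of class `xci_sample_result` with elements `sites`
#'   (per-site data.frame: `chrom, pos, gene_symbol, ref_count, alt_count,
#'   total_depth, p_value, model_used, significant`) and `summary` (list:
#'   `sample_id, status, n_sites_tested, n_significant, pct_skewed,
#'   model_usage, alpha, min_test_depth`). When no site is eligible,
#'   `status` is `"unreportable"` and `pct_skewed` is `NA`.
#' @export
test_sample <- function(cvacs, model, min_test_depth = 10, alpha = 0.05) {
  stopifnot(inherits(model, "xci_reference_model"))
  sample_id <- if (nrow(cvacs)) unique(cvacs$sample_id)[1] else NA_character_
  if (nrow(cvacs) && length(unique(cvacs$sample_id)) > 1) {
    stop("test_sample expects records from a single sample")
  }
  eligible <- cvacs[cvacs$total_depth > min_test_depth, , drop = FALSE]
  gene <- if (!is.null(eligible$gene_symbol)) eligible$gene_symbol
          else rep(".", nrow(eligible))
  if (nrow(eligible) == 0) {
    warning("no site exceeds the test depth; sample is unreportable")
    return(structure(list(
      sites = data.frame(),
      summary = list(sample_id = sample_id, status = "unreportable",
                     n_sites_tested = 0L, n_significant = 0L,
                     pct_skewed = NA_real_, model_usage = c(
                       position = NA_real_, gene = NA_real_,
                       global = NA_real_),
                     alpha = alpha, min_test_depth = min_test_depth)),
      class = "xci_sample_result"))
  }
  pv <- numeric(nrow(eligible))
  tier <- character(nrow(eligible))
  for (i in seq_len(nrow(eligible))) {
    sel <- select_model(model, eligible$chrom[i], eligible$pos[i], gene[i])
    pv[i] <- two_sided_pvalue(eligible$ref_count[i],
                              eligible$total_depth[i], sel$params)
    tier[i] <- sel$tier
  }
  sig <- pv < alpha
  sites <- data.frame(
    chrom = eligible$chrom, pos = eligible$pos, gene_symbol = gene,
    ref_count = eligible$ref_count, alt_count = eligible$alt_count,
    total_depth = eligible$total_depth,
    p_value = pv, model_used = tier, significant = sig,
    stringsAsFactors = FALSE, row.names = NULL)
  usage <- vapply(c("position", "gene", "global"),
                  function(t) mean(tier == t), numeric(1))
  structure(list(
    sites = sites,
    summary = list(sample_id = sample_id, status = "reportable",
                   n_sites_tested = nrow(sites),
                   n_significant = sum(sig),
                   pct_skewed = 100 * mean(sig),
                   model_usage = usage,
                   alpha = alpha, min_test_depth = min_test_depth)),
    class = "xci_sample_result")
}

#' @export
print.xci_sample_result <- function(x, ...) {
  s <- x$summary
  if (s$status == "unreportable") {
    cat("sample", s$sample_id, ": unreportable (no eligible sites)\n")
  } else {
    cat(sprintf("sample %s: %d/%d sites skewed (%.2f%%)\n", s$sample_id,
                s$n_significant, s$n_sites_tested, s$pct_skewed))
  }
  invisible(x)
}

#' Recompute the percent-skewed summary after excluding site lists
#'
#' Removes tested sites inside escape-gene intervals and/or matching known
#' RNA-editing positions, then recomputes both numerator and denominator of
#' the percentage. The original and recomputed figures are reported side by
#' side.
#'
#' @param result an `xci_sample_result` from [test_sample()].
#' @param escape optional `GRanges` of escape-gene intervals.
#' @param editing_sites optional `GRanges` (or data.frame with
#'   `chrom`/`pos`) of RNA-editing positions to drop by exact coordinate.
#' @return list with `pct_skewed` (original), `pct_skewed_excluded`,
#'   `n_removed`, `n_sites_tested`, `n_significant` (both after exclusion)
#'   and `status`.
#' @export
exclude_site_lists <- function(result, escape = NULL, editing_sites = NULL) {
  stopifnot(inherits(result, "xci_sample_result"))
  s <- result$summary
  if (s$status == "unreportable") {
    return(list(pct_skewed = NA_real_, pct_skewed_excluded = NA_real_,
                n_removed = 0L, n_sites_tested = 0L, n_significant = 0L,
                status = "unreportable"))
  }
  sites <- result$sites
  drop <- rep(FALSE, nrow(sites))
  if (!is.null(escape) && length(escape) > 0) {
    hits <- GenomicRanges::findOverlaps(sites_as_granges(sites), escape)
    drop[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  if (!is.null(editing_sites)) {
    ed <- if (is.data.frame(editing_sites)) {
      position_key(editing_sites$chrom, editing_sites$pos)
    } else {
      position_key(as.character(GenomicRanges::seqnames(editing_sites)),
                   GenomicRanges::start(editing_sites))
    }
    drop[position_key(sites$chrom, sites$pos) %in% ed] <- TRUE
  }
  kept <- sites[!drop, , drop = FALSE]
  list(pct_skewed = s$pct_skewed,
       pct_skewed_excluded = if (nrow(kept)) 100 * mean(kept$significant)
                             else NA_real_,
       n_removed = sum(drop),
       n_sites_tested = nrow(kept),
       n_significant = sum(kept$significant),
       status = if (nrow(kept)) "reportable" else "unreportable")
}

#' Pairwise significance agreement between model tiers
#'
#' For every eligible site, significance is evaluated under each tier whose
#' model exists for that site; the agreement of two tiers is the percentage
#' of co-evaluable sites on which they make the same significant /
#' not-significant call.
#'
#' @inheritParams test_sample
#' @return named numeric vector
#'   `c(position_gene =, gene_global =, position_global =)` of agreement
#'   percentages (`NA` with a warning where no site is co-evaluable).
#' @export
model_usage_agreement <- function(cvacs, model, min_test_depth = 10,
                                  alpha = 0.05) {
  eligible <- cvacs[cvacs$total_depth > min_test_depth, , drop = FALSE]
  gene <- if (!is.null(eligible$gene_symbol)) eligible$gene_symbol
          else rep(".", nrow(eligible))
  n <- nrow(eligible)
  sig <- matrix(NA, nrow = n, ncol = 3,
                dimnames = list(NULL, c("position", "gene", "global")))
  for (i in seq_len(n)) {
    key <- position_key(eligible$chrom[i], eligible$pos[i])
    tiers <- list(position = model$position_models[[key]],
                  gene = if (gene[i] != ".")
                    model$gene_models[[gene[i]]] else NULL,
                  global = model$global_model)
    for (t in names(tiers)) {
      if (!is.null(tiers[[t]])) {
        sig[i, t] <- two_sided_pvalue(eligible$ref_count[i],
                                      eligible$total_depth[i],
                                      tiers[[t]]) < alpha
      }
    }
  }
  agree <- function(a, b) {
    both <- !is.na(sig[, a]) & !is.na(sig[, b])
    if (!any(both)) return(NA_real_)
    100 * mean(sig[both, a] == sig[both, b])
  }
  out <- c(position_gene = agree("position", "gene"),
           gene_global = agree("gene", "global"),
           position_global = agree("position", "global"))
  if (anyNA(out)) warning("some tier pairs share no co-evaluable sites")
  out
}
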