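## Cohort-level thresholding, classification and concordance with the
## clinical AR methylation assay.

#' Threshold configuration for skew classification
#'
#' @param mode `"fixed"` (use `fixed_value`) or `"density_minimum"` (derive
#'   from the cohort's density of per-sample percentages).
#' @param fixed_value fixed threshold percentage (default 14, the
#'   reference-cohort value; 12 is the combined-patient-cohort preset).
#' @param search_range percentage interval searched for density minima.
#' @param kde_bandwidth `"silverman"` or a numeric bandwidth.
#' @param expected_population_rate expected population skew-call rate
#'   interval, in percent (default 10-20).
#' @return a `threshold_config` list.
#' @export
threshold_config <- function(mode = c("density_minimum", "fixed"),
                             fixed_value = 14,
                             search_range = c(5, 25),
                             kde_bandwidth = "silverman",
                             expected_population_rate = c(10, 20)) {
  mode <- match.arg(mode)
  if (fixed_value <= 0 || fixed_value >= 100) {
    stop("fixed_value must be in (0, 100)")
  }
  if (length(search_range) != 2 || diff(search_range) <= 0) {
    stop("search_range must be a non-empty interval")
  }
  structure(list(mode = mode, fixed_value = fixed_value,
                 search_range = search_range, kde_bandwidth = kde_bandwidth,
                 expected_population_rate = expected_population_rate),
            class = "threshold_config")
}

#' Classify a sample as skewed or random XCI
#'
#' A sample is skewed if its percentage of significantly skewed sites
#' strictly exceeds the threshold; a percentage exactly at the threshold is
#' random.
#'
#' @param pct_skewed percentage(s) in \[0, 100\].
#' @param threshold threshold percentage (default 14).
#' @return character vector of `"skewed"` / `"random"`.
#' @export
#' @examples
#' classify_sample(c(73.04, 2.35, 14), threshold = 14)
classify_sample <- function(pct_skewed, threshold = 14) {
  if (any(pct_skewed < 0 | pct_skewed > 100, na.rm = TRUE)) {
    stop("percentages must lie in [0, 100]")
  }
  ifelse(pct_skewed > threshold, "skewed", "random")
}

#' Derive the cohort skew threshold from a density minimum
#'
#' Fits a Gaussian KDE (Silverman's rule by default, 512 grid points over
#' `[0, max(pct) + 5]`) to the cohort's per-sample percentages, finds local
#' minima of the density inside `search_range`, and picks the minimum whose
#' implied skew-call rate falls inside `expected_population_rate` (the
#' closest candidate if none does). Falls back to `fixed_value` with a
#' warning when fewer than 20 samples are given or no local minimum exists
#' in range.
#'
#' @param cohort_pcts per-sample percentages of significantly skewed sites.
#' @param config a [threshold_config()].
#' @return list with `threshold`, `mode_used` (`"density_minimum"` or
#'   `"fixed_fallback"`), `candidates` (all in-range minima with their
#'   implied call rates) and `density` (the KDE grid as a data.frame).
#' @export
derive_threshold <- function(cohort_pcts, config = threshold_config()) {
  pcts <- cohort_pcts[!is.na(cohort_pcts)]
  fallback <- function(msg, dens = NULL) {
    warning(msg, "; falling back to fixed threshold ", config$fixed_value)
    list(threshold = config$fixed_value, mode_used = "fixed_fallback",
         candidates = data.frame(threshold = numeric(),
                                 implied_rate = numeric()),
         density = dens)
  }
  if (config$mode == "fixed") {
    return(list(threshold = config$fixed_value, mode_used = "fixed",
                candidates = data.frame(), density = NULL))
  }
  if (length(pcts) < 20) return(fallback("fewer than 20 samples"))
  bw <- if (identical(config$kde_bandwidth, "silverman")) {
    stats::bw.nrd0(pcts)
  } else config$kde_bandwidth
  d <- stats::density(pcts, bw = bw, n = 512, from = 0, to = max(pcts) + 5)
  dens <- data.frame(x = d$x, y = d$y)
  ## interior local minima of the density curve that are genuine valleys:
  ## a mode must exist on each side with at least twice the valley density
  ## (tail wiggles of a unimodal KDE are not separating minima)
  dy <- diff(d$y)
  is_min <- which(dy[-length(dy)] < 0 & dy[-1] > 0) + 1L
  valley <- vapply(is_min, function(i) {
    max(d$y[seq_len(i)]) > 2 * d$y[i] &&
      max(d$y[seq.int(i, length(d$y))]) > 2 * d$y[i]
  }, logical(1))
  is_min <- is_min[valley]
  cand_x <- d$x[is_min]
  keep <- cand_x >= config$search_range[1] &
    cand_x <= config$search_range[2] &
    ## a separating minimum must actually separate samples
    vapply(cand_x, function(t) any(pcts > t), logical(1))
  is_min <- is_min[keep]
  cand_x <- cand_x[keep]
  if (length(cand_x) == 0) {
    return(fallback("no density local minimum inside the search range", dens))
  }
  implied <- vapply(cand_x, function(t) 100 * mean(pcts > t), numeric(1))
  lo <- config$expected_population_rate[1]
  hi <- config$expected_population_rate[2]
  in_rate <- implied >= lo & implied <= hi
  pick <- if (any(in_rate)) {
    ## deepest density minimum among rate-consistent candidates
    ok <- which(in_rate)
    ok[which.min(d$y[is_min][ok])]
  } else {
    which.min(pmin(abs(implied - lo), abs(implied - hi)))
  }
  list(threshold = cand_x[pick], mode_used = "density_minimum",
       candidates = data.frame(threshold = cand_x, implied_rate = implied),
       density = dens)
}

normalize_assay_call <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[grepl("random", x)] <- "random"
  out[grepl("skew|high|moderate", x)] <- "skewed"
  out[grepl("uninformative|inconclusive|ui|^na$", x) | x == ""] <-
    "uninformative"
  if (anyNA(out)) {
    stop("unrecognized assay call(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Concordance of NGS skew calls with an orthogonal assay
#'
#' Builds the 2x3 confusion table (NGS random/skewed against assay
#' random/skewed/uninformative; high and moderate assay skew collapse to
#' "skewed"), computes the concordance percentage over informative pairs,
#' and attaches the exact Clopper-Pearson 95% binomial confidence interval.
#'
#' @param ngs_calls character vector of `"random"`/`"skewed"` NGS calls.
#' @param assay_calls paired assay calls; labels containing "random",
#'   "skew"/"high"/"moderate" or "uninformative"/"inconclusive" are
#'   recognized.
#' @return list of class `xci_concordance`: `table` (2x3 counts),
#'   `n_informative`, `n_concordant`, `concordance_pct`, `ci95`
#'   (lower/upper on the proportion scale).
#' @export
concordance_stats <- function(ngs_calls, assay_calls) {
  if (length(ngs_calls) != length(assay_calls)) {
    stop("ngs_calls and assay_calls must be paired (equal length)")
  }
  ngs <- tolower(ngs_calls)
  if (!all(ngs %in% c("random", "skewed"))) {
    stop("ngs_calls must be 'random' or 'skewed'")
  }
  assay <- normalize_assay_call(assay_calls)
  tab <- table(factor(ngs, levels = c("random", "skewed")),
               factor(assay, levels = c("random", "skewed",
                                        "uninformative")))
  names(dimnames(tab)) <- c("NGS", "assay")
  informative <- assay != "uninformative"
  n_inf <- sum(informative)
  if (n_inf == 0) stop("no informative assay results to compare against")
  n_conc <- sum(ngs[informative] == assay[informative])
  ci <- stats::binom.test(n_conc, n_inf)$conf.int
  structure(list(table = tab, n_informative = n_inf,
                 n_concordant = n_conc,
                 concordance_pct = 100 * n_conc / n_inf,
                 ci95 = c(lower = ci[1], upper = ci[2])),
            class = "xci_concordance")
}

#' @export
print.xci_concordance <- function(x, ...) {
  print(x$table)
  cat(sprintf("concordance: %d/%d = %.1f%% (95%% CI %.2f-%.2f)\n",
              x$n_concordant, x$n_informative, x$concordance_pct,
              x$ci95["lower"], x$ci95["upper"]))
  invisible(x)
}

#' Summarize a cohort of per-sample skew results
#'
#' @param results list of `xci_sample_result` objects (or a data.frame with
#'   `sample_id` and `pct_skewed`).
#' @param threshold classification threshold percentage.
#' @return list with `table` (per-sample `sample_id, pct_skewed, status`),
#'   `n_reportable`, `n_skewed` and `skew_rate_pct`; unreportable samples
#'   are listed with status `"unreportable"` and excluded from the rate.
#' @export
summarize_cohort <- function(results, threshold = 14) {
  if (is.data.frame(results)) {
    df <- data.frame(sample_id = results$sample_id,
                     pct_skewed = results$pct_skewed,
                     stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, lapply(results, function(r) {
      s <- r$summary
      data.frame(sample_id = s$sample_id, pct_skewed = s$pct_skewed,
                 stringsAsFactors = FALSE)
    }))
  }
  reportable <- !is.na(df$pct_skewed)
  if (!any(reportable)) stop("no reportable sample in cohort")
  df$status <- "unreportable"
  df$status[reportable] <- classify_sample(df$pct_skewed[reportable],
                                           threshold)
  n_skewed <- sum(df$status == "skewed")
  list(table = df, n_reportable = sum(reportable), n_skewed = n_skewed,
       skew_rate_pct = 100 * n_skewed / sum(reportable),
       threshold = threshold)
}
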