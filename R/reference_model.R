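## The three-tier reference model: beta-binomial nulls fitted per position,
## per gene, and once globally over a random sample of positions.

position_key <- function(chrom, pos) {
  paste0(normalize_chrom(chrom), ":", pos)
}

## split a cohort CVAC table into eligible (ref, alt) pair sets per key.
## Eligibility rule: a pair contributes if its total depth is
## >= min_reads; a key is modelled if >= min_samples distinct samples
## contribute at least one such pair.
eligible_groups <- function(cohort, keys, min_reads, min_samples) {
  ok <- cohort$total_depth >= min_reads
  cohort <- cohort[ok, , drop = FALSE]
  keys <- keys[ok]
  split_idx <- split(seq_len(nrow(cohort)), keys)
  keep <- vapply(split_idx, function(i) {
    length(unique(cohort$sample_id[i])) >= min_samples
  }, logical(1))
  lapply(split_idx[keep], function(i) cohort[i, , drop = FALSE])
}

#' Fit position-specific beta-binomial models from a reference cohort
#'
#' A model is fitted for exactly those positions covered by `min_reads` or
#' more reads in `min_samples` or more samples; each model uses the
#' Laplace-smoothed (ref, alt) pairs of the qualifying samples.
#'
#' @param cohort CVAC data.frame pooling all reference samples (must carry
#'   `sample_id`); a list of per-sample tables is rbind-ed.
#' @param min_reads minimum RNA depth for a pair to contribute (default 3,
#'   inclusive).
#' @param min_samples minimum number of contributing samples (default 10,
#'   inclusive).
#' @param k_smooth Laplace pseudo-count.
#' @return named list of [betabin_params()], keyed `"X:pos"`.
#' @export
build_position_models <- function(cohort, min_reads = 3, min_samples = 10,
                                  k_smooth = 1) {
  cohort <- as_cohort(cohort)
  groups <- eligible_groups(cohort, position_key(cohort$chrom, cohort$pos),
                            min_reads, min_samples)
  out <- lapply(names(groups), function(k) {
    g <- groups[[k]]
    fit_betabinom(g$ref_count, g$alt_count, k_smooth = k_smooth,
                  min_pairs = min_samples, tier = "position", key = k)
  })
  stats::setNames(out, names(groups))
}

#' Fit gene-specific beta-binomial models
#'
#' Pools all (position, sample) pairs within each annotated gene; the
#' depth/sample eligibility rule of the position models is applied to the
#' pooled observations. Records with the sentinel gene symbol `"."` are
#' ignored.
#'
#' @inheritParams build_position_models
#' @return named list of [betabin_params()], keyed by gene symbol.
#' @export
build_gene_models <- function(cohort, min_reads = 3, min_samples = 10,
                              k_smooth = 1) {
  cohort <- as_cohort(cohort)
  if (is.null(cohort$gene_symbol)) {
    stop("cohort records lack gene_symbol; run annotate_genes() first")
  }
  cohort <- cohort[cohort$gene_symbol != ".", , drop = FALSE]
  ok <- cohort$total_depth >= min_reads
  cohort <- cohort[ok, , drop = FALSE]
  split_idx <- split(seq_len(nrow(cohort)), cohort$gene_symbol)
  keep <- vapply(split_idx, function(i) length(i) >= min_samples, logical(1))
  groups <- lapply(split_idx[keep], function(i) cohort[i, , drop = FALSE])
  out <- lapply(names(groups), function(k) {
    g <- groups[[k]]
    fit_betabinom(g$ref_count, g$alt_count, k_smooth = k_smooth,
                  min_pairs = min_samples, tier = "gene", key = k)
  })
  stats::setNames(out, names(groups))
}

#' Fit the global beta-binomial model
#'
#' Samples `n_positions` distinct qualifying positions without replacement
#' (deterministically under `seed`), pools all their depth-eligible
#' (ref, alt) pairs and fits one model. If fewer positions are available,
#' all are used with a warning.
#'
#' @inheritParams build_position_models
#' @param n_positions number of positions to sample (default 2000).
#' @param seed RNG seed for the position sample.
#' @return a [betabin_params()] with `tier = "global"`; the sampled keys are
#'   attached as attribute `"positions"`.
#' @export
build_global_model <- function(cohort, n_positions = 2000, seed = 7,
                               min_reads = 3, k_smooth = 1) {
  cohort <- as_cohort(cohort)
  cohort <- cohort[cohort$total_depth >= min_reads, , drop = FALSE]
  if (nrow(cohort) == 0) stop("no depth-eligible records in cohort")
  keys <- position_key(cohort$chrom, cohort$pos)
  uk <- sort(unique(keys))
  if (length(uk) <= n_positions) {
    if (length(uk) < n_positions) {
      warning("only ", length(uk), " distinct positions available; ",
              "using all of them for the global model")
    }
    chosen <- uk
  } else {
    chosen <- with_local_seed(seed, sort(sample(uk, n_positions)))
  }
  sel <- cohort[keys %in% chosen, , drop = FALSE]
  fit <- fit_betabinom(sel$ref_count, sel$alt_count, k_smooth = k_smooth,
                       min_pairs = 1, tier = "global", key = "global")
  attr(fit, "positions") <- chosen
  fit
}

as_cohort <- function(cohort) {
  if (is.data.frame(cohort)) return(cohort)
  if (is.list(cohort)) return(do.call(rbind, cohort))
  stop("cohort must be a CVAC data.frame or a list of them")
}

#' Build the full three-tier reference model
#'
#' @inheritParams build_position_models
#' @param global_n positions sampled for the global model.
#' @param seed seed for the global-position sample.
#' @return an `xci_reference_model`: position models, gene models, global
#'   model and reproducibility metadata.
#' @export
build_reference_model <- function(cohort, min_reads = 3, min_samples = 10,
                                  k_smooth = 1, global_n = 2000, seed = 7) {
  cohort <- as_cohort(cohort)
  if (nrow(cohort) == 0) stop("empty cohort")
  pos_models <- build_position_models(cohort, min_reads, min_samples,
                                      k_smooth)
  gene_models <- if (!is.null(cohort$gene_symbol)) {
    build_gene_models(cohort, min_reads, min_samples, k_smooth)
  } else list()
  global <- build_global_model(cohort, n_positions = global_n, seed = seed,
                               min_reads = min_reads, k_smooth = k_smooth)
  structure(list(
    position_models = pos_models,
    gene_models = gene_models,
    global_model = global,
    metadata = list(
      schema_version = "1.0",
      parameterization = "gamlss_bb (alpha = mu/sigma, beta = (1-mu)/sigma)",
      n_cohort_samples = length(unique(cohort$sample_id)),
      min_reads = min_reads, min_samples = min_samples,
      k_smooth = k_smooth, global_n = global_n, seed = seed,
      global_positions_used = length(attr(global, "positions"))
    )), class = "xci_reference_model")
}

#' @export
print.xci_reference_model <- function(x, ...) {
  cat("XCI reference model (schema ", x$metadata$schema_version, ")\n",
      "  ", length(x$position_models), " position models, ",
      length(x$gene_models), " gene models, 1 global model\n",
      "  cohort: ", x$metadata$n_cohort_samples, " samples; global mu = ",
      signif(x$global_model$mu, 4), ", sigma = ",
      signif(x$global_model$sigma, 4), "\n", sep = "")
  invisible(x)
}

params_to_df <- function(models) {
  if (length(models) == 0) {
    return(data.frame(key = character(), mu = numeric(), sigma = numeric(),
                      n_obs = integer(), loglik = numeric(),
                      stringsAsFactors = FALSE))
  }
  data.frame(key = vapply(models, `[[`, character(1), "key"),
             mu = vapply(models, `[[`, numeric(1), "mu"),
             sigma = vapply(models, `[[`, numeric(1), "sigma"),
             n_obs = vapply(models, `[[`, integer(1), "n_obs"),
             loglik = vapply(models, `[[`, numeric(1), "loglik"),
             stringsAsFactors = FALSE, row.names = NULL)
}

df_to_params <- function(df, tier) {
  out <- lapply(seq_len(nrow(df)), function(i) {
    betabin_params(df$mu[i], df$sigma[i], df$n_obs[i], tier, df$key[i],
                   df$loglik[i])
  })
  stats::setNames(out, df$key)
}

#' Serialize / restore a reference model (versioned JSON)
#'
#' Parameters round-trip at full IEEE double precision, so p-values computed
#' from a reloaded model are bit-identical. Loading a file with a different
#' schema version, or a truncated/corrupt file, is an explicit error.
#'
#' @param model an `xci_reference_model`.
#' @param path file path (conventionally `.json`).
#' @return `load_model` returns the restored `xci_reference_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "xci_reference_model"))
  doc <- list(
    schema_version = model$metadata$schema_version,
    metadata = model$metadata,
    position_models = params_to_df(model$position_models),
    gene_models = params_to_df(model$gene_models),
    global_model = list(mu = model$global_model$mu,
                        sigma = model$global_model$sigma,
                        n_obs = model$global_model$n_obs,
                        loglik = model$global_model$loglik,
                        positions = attr(model$global_model, "positions"))
  )
  ## digits = I(17): significant-digit mode, exact IEEE double round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("corrupt model file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  need <- c("schema_version", "metadata", "position_models", "gene_models",
            "global_model")
  if (!all(need %in% names(doc))) {
    stop("model file '", path, "' is missing section(s): ",
         paste(setdiff(need, names(doc)), collapse = ", "))
  }
  if (!identical(doc$schema_version, "1.0")) {
    stop("unsupported model schema version: ", doc$schema_version)
  }
  gm <- doc$global_model
  global <- betabin_params(gm$mu, gm$sigma, gm$n_obs, "global", "global",
                           if (is.null(gm$loglik)) NA_real_ else gm$loglik)
  attr(global, "positions") <- gm$positions
  pm <- as.data.frame(doc$position_models, stringsAsFactors = FALSE)
  ge <- as.data.frame(doc$gene_models, stringsAsFactors = FALSE)
  structure(list(
    position_models = if (nrow(pm)) df_to_params(pm, "position") else list(),
    gene_models = if (nrow(ge)) df_to_params(ge, "gene") else list(),
    global_model = global,
    metadata = doc$metadata), class = "xci_reference_model")
}
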