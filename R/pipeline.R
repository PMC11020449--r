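## Pipeline chaining and input validation. Each stage is a thin wrapper over
## the module functions; a manifest (version, parameters, input checksums,
## seed) is written next to the outputs so any run can be reproduced.

#' Validate pipeline input files
#'
#' Checks existence and basic well-formedness of declared inputs: VCF header
#' present, BED `start < end` with no negative coordinates, CVAC TSV columns
#' and non-negative counts, mpileup column count, and chromosome-name
#' consistency (aliases like "chrX" are accepted and normalized with a
#' warning).
#'
#' @param paths named list; recognized names are `vcf`, `mpileup`, `cvac`
#'   and `bed` (the latter may be a vector of paths).
#' @return data.frame report with columns `file`, `format`, `ok`, `detail`;
#'   attribute `"n_errors"` gives the number of failed checks.
#' @export
validate_inputs <- function(paths) {
  rows <- list()
  note <- function(file, format, ok, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      file = file, format = format, ok = ok, detail = detail,
      stringsAsFactors = FALSE)
  }
  check_chrom <- function(chroms, file, format) {
    raw <- unique(chroms)
    norm <- normalize_chrom(raw)
    if (any(raw != norm)) {
      warning(file, ": chromosome alias(es) ",
              paste(setdiff(raw, norm), collapse = ", "),
              " normalized to ", paste(unique(norm), collapse = ", "))
    }
  }
  if (!is.null(paths$vcf)) {
    f <- paths$vcf
    if (!file.exists(f)) note(f, "vcf", FALSE, "file not found")
    else {
      head_lines <- readLines(f, n = 200)
      if (!any(grepl("^##fileformat=VCF", head_lines))) {
        note(f, "vcf", FALSE, "missing ##fileformat header")
      } else note(f, "vcf", TRUE)
    }
  }
  for (f in paths$bed) {
    if (!file.exists(f)) { note(f, "bed", FALSE, "file not found"); next }
    d <- tryCatch(utils::read.delim(f, header = FALSE,
                                    stringsAsFactors = FALSE),
                  error = function(e) NULL)
    if (is.null(d) || ncol(d) < 3) {
      note(f, "bed", FALSE, "fewer than 3 columns"); next
    }
    if (any(d[[2]] < 0) || any(d[[2]] >= d[[3]])) {
      note(f, "bed", FALSE, "interval with start >= end or negative start")
    } else {
      check_chrom(d[[1]], f, "bed")
      note(f, "bed", TRUE)
    }
  }
  if (!is.null(paths$cvac)) {
    f <- paths$cvac
    if (!file.exists(f)) note(f, "cvac", FALSE, "file not found")
    else {
      d <- tryCatch(read_cvac(f), error = function(e) {
        note(f, "cvac", FALSE, conditionMessage(e)); NULL
      })
      if (!is.null(d)) { check_chrom(d$chrom, f, "cvac"); note(f, "cvac", TRUE) }
    }
  }
  if (!is.null(paths$mpileup)) {
    f <- paths$mpileup
    if (!file.exists(f)) note(f, "mpileup", FALSE, "file not found")
    else {
      ln <- readLines(f, n = 50)
      ncols <- lengths(strsplit(ln[nzchar(ln)], "\t"))
      if (length(ncols) && any(ncols < 6)) {
        note(f, "mpileup", FALSE, "line with fewer than 6 columns")
      } else note(f, "mpileup", TRUE)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(), format = character(), ok = logical(),
               detail = character(), stringsAsFactors = FALSE)
  attr(report, "n_errors") <- sum(!report$ok)
  report
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the extract -> build-ref / call-skew -> classify pipeline
#'
#' Stages requested in `config$stages` are executed in order; any stage
#' failure aborts with a stage-tagged error. A JSON manifest capturing the
#' package version, parameters, input checksums and seed is written to the
#' output directory; identical manifests yield identical outputs.
#'
#' @param config named list. Common fields: `out_dir`, `stages` (subset of
#'   `c("extract", "build_ref", "call_skew", "classify")`), `seed`.
#'   extract: `vcf`, `mpileup`, `sample_id`, `par_bed`, `coding_bed`,
#'   `gene_bed`, `min_dna_depth`, `min_gq`, `min_baseq`. build_ref:
#'   `cvac_files` (vector of CVAC TSVs), `min_reads`, `min_samples`,
#'   `k_smooth`, `global_n`. call_skew: `cvac` (or the extract output),
#'   `model` (path or object), `min_test_depth`, `alpha`, `escape_bed`.
#'   classify: `threshold` (number or `"auto"`).
#' @return named list of stage outputs (paths and in-memory objects),
#'   invisibly includes the manifest path.
#' @export
run_pipeline <- function(config) {
  out_dir <- config[["out_dir"]]
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config[["stages"]]
  results <- list()

  if ("extract" %in% stages) {
    results$cvac <- run_stage("extract", {
      sites <- filter_het_sites(config[["vcf"]], config[["sample_id"]],
                                min_dna_depth = config[["min_dna_depth"]] %||% 10,
                                min_gq = config[["min_gq"]] %||% 20)
      par <- if (!is.null(config[["par_bed"]]))
        read_intervals(config[["par_bed"]], "PAR") else par_regions_hg19()
      sites <- exclude_regions(sites, par)
      coding <- if (!is.null(config[["coding_bed"]]))
        read_intervals(config[["coding_bed"]], "coding") else NULL
      sites <- restrict_to_coding(sites, coding)
      cvac <- count_alleles_mpileup(config[["mpileup"]], sites,
                                    sample_id = config[["sample_id"]] %||%
                                      "sample",
                                    min_baseq = config[["min_baseq"]] %||% 30)
      if (!is.null(config[["gene_bed"]])) {
        cvac <- annotate_genes(cvac,
                               read_intervals(config[["gene_bed"]], "gene_map"))
      }
      write_cvac(cvac, file.path(out_dir, "cvac.tsv"))
      cvac
    })
  }

  if ("build_ref" %in% stages) {
    results$model <- run_stage("build-ref", {
      cohort <- do.call(rbind, lapply(config[["cvac_files"]], read_cvac))
      model <- build_reference_model(
        cohort,
        min_reads = config[["min_reads"]] %||% 3,
        min_samples = config[["min_samples"]] %||% 10,
        k_smooth = config[["k_smooth"]] %||% 1,
        global_n = config[["global_n"]] %||% 2000,
        seed = config[["seed"]] %||% 7)
      save_model(model, file.path(out_dir, "model.json"))
      model
    })
  }

  if ("call_skew" %in% stages) {
    results$skew <- run_stage("call-skew", {
      model <- config[["model"]] %||% results$model
      if (is.character(model)) model <- load_model(model)
      if (is.null(model)) stop("no reference model supplied")
      cvac <- if (!is.null(config[["cvac"]])) {
        if (is.character(config[["cvac"]])) read_cvac(config[["cvac"]])
        else config[["cvac"]]
      } else results$cvac
      if (is.null(cvac)) stop("no CVAC input supplied")
      res <- lapply(split(cvac, cvac$sample_id), test_sample, model = model,
                    min_test_depth = config[["min_test_depth"]] %||% 10,
                    alpha = config[["alpha"]] %||% 0.05)
      per_site <- do.call(rbind, lapply(res, function(r) {
        if (nrow(r$sites))
          cbind(sample_id = r$summary$sample_id, r$sites) else NULL
      }))
      if (!is.null(per_site)) {
        utils::write.table(per_site, file.path(out_dir, "sites.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      summ <- do.call(rbind, lapply(res, function(r) {
        s <- r$summary
        data.frame(sample_id = s$sample_id, status = s$status,
                   n_sites_tested = s$n_sites_tested,
                   n_significant = s$n_significant,
                   pct_skewed = round(s$pct_skewed, 2),
                   stringsAsFactors = FALSE)
      }))
      rownames(summ) <- NULL
      utils::write.table(summ, file.path(out_dir, "summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(results = res, summary = summ)
    })
  }

  if ("classify" %in% stages) {
    results$report <- run_stage("classify", {
      summ <- results$skew$summary %||%
        utils::read.delim(config[["summaries"]], stringsAsFactors = FALSE)
      pcts <- summ$pct_skewed[summ$status == "reportable"]
      thr <- config[["threshold"]] %||% 14
      if (identical(thr, "auto")) {
        thr <- derive_threshold(pcts)$threshold
      }
      rep <- summarize_cohort(
        data.frame(sample_id = summ$sample_id, pct_skewed = ifelse(
          summ$status == "reportable", summ$pct_skewed, NA_real_)),
        threshold = thr)
      utils::write.table(rep$table, file.path(out_dir, "report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rep
    })
  }

  manifest <- list(
    package = "xciskew",
    version = as.character(utils::packageVersion("xciskew")),
    timestamp = format(Sys.time(), tz = "UTC"),
    stages = stages,
    seed = config[["seed"]] %||% NA,
    parameters = config[setdiff(names(config), c("model"))],
    input_checksums = local({
      files <- unlist(config[c("vcf", "mpileup", "cvac", "cvac_files",
                               "par_bed", "coding_bed", "gene_bed",
                               "escape_bed")])
      files <- files[!vapply(files, is.null, logical(1))]
      files <- files[vapply(files, function(f)
        is.character(f) && file.exists(f), logical(1))]
      if (length(files)) as.list(tools::md5sum(unlist(files))) else list()
    }))
  manifest$parameters <- lapply(manifest$parameters, function(x)
    if (is.data.frame(x)) "<in-memory table>" else x)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  results$manifest <- file.path(out_dir, "manifest.json")
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
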