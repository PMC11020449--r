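test_that("position-model eligibility: >= 3 reads in >= 10 samples,
          boundaries exact", {
  base <- make_null_cohort(n_samples = 12, n_sites = 4, depth = 40)
  # site A: depth >= 3 in exactly 10 samples -> model
  # site B: in 9 samples -> no model
  pos <- sort(unique(base$pos))
  dep <- base$total_depth
  dep[base$pos == pos[1]][11:12] <- 2L   # only 10 samples at depth >= 3
  dep[base$pos == pos[2]][10:12] <- 2L   # only 9 samples
  base$total_depth <- dep
  base$ref_count <- pmin(base$ref_count, base$total_depth)
  base$alt_count <- base$total_depth - base$ref_count
  models <- build_position_models(base)
  keys <- paste0("X:", pos)
  expect_true(keys[1] %in% names(models))
  expect_false(keys[2] %in% names(models))
  expect_true(all(keys[3:4] %in% names(models)))
  expect_equal(models[[keys[1]]]$n_obs, 10L)
})

test_that("model-key sets equal a brute-force recomputation of the
          eligibility rule", {
  cohort <- make_null_cohort(n_samples = 25, n_sites = 40, seed = 21)
  # introduce uneven coverage
  cohort <- withr::with_seed(22, {
    drop <- runif(nrow(cohort)) < 0.4
    cohort$total_depth[drop] <- sample(0:2, sum(drop), replace = TRUE)
    cohort$ref_count <- pmin(cohort$ref_count, cohort$total_depth)
    cohort$alt_count <- cohort$total_depth - cohort$ref_count
    cohort
  })
  models <- build_position_models(cohort, min_reads = 3, min_samples = 10)
  brute <- vapply(split(cohort, paste0(cohort$chrom, ":", cohort$pos)),
                  function(g) {
                    length(unique(g$sample_id[g$total_depth >= 3])) >= 10
                  }, logical(1))
  expect_setequal(names(models), names(brute)[brute])
})

test_that("a 50:50 cohort yields position models centred on 0.5", {
  cohort <- make_null_cohort(n_samples = 40, n_sites = 20, depth = 50,
                             seed = 31)
  models <- build_position_models(cohort)
  mus <- vapply(models, `[[`, numeric(1), "mu")
  expect_true(all(abs(mus - 0.5) < 0.05))
})

test_that("gene models pool observations and ignore the sentinel symbol", {
  cohort <- make_null_cohort(n_samples = 5, n_sites = 15, seed = 41)
  # each gene: 5 sites x 5 samples = 25 pooled observations -> eligible
  models <- build_gene_models(cohort)
  expect_setequal(names(models), unique(cohort$gene_symbol))
  expect_true(all(vapply(models, `[[`, integer(1), "n_obs") == 25L))
  mus <- vapply(models, `[[`, numeric(1), "mu")
  expect_true(all(abs(mus - 0.5) < 0.05))
  # sentinel-only records produce no gene model
  cohort2 <- cohort
  cohort2$gene_symbol <- "."
  expect_length(build_gene_models(cohort2), 0)
  # a gene with too few pooled observations (5 < 10) is skipped
  small <- cohort[cohort$gene_symbol == "G1" & cohort$sample_id == "N01", ]
  small$gene_symbol <- "TINY"
  expect_length(build_gene_models(rbind(cohort2, small)), 0)
})

test_that("gene-model recovery at a skewed mean", {
  cohort <- withr::with_seed(51, {
    do.call(rbind, lapply(1:20, function(j) {
      r <- rbetabinom(10, 50, 0.6, 0.05)
      data.frame(sample_id = sprintf("S%02d", j), chrom = "X",
                 pos = 1:10 * 1000L, ref_allele = "C", alt_allele = "T",
                 ref_count = r, alt_count = 50L - r, total_depth = 50L,
                 gene_symbol = "GENE_X", stringsAsFactors = FALSE)
    }))
  })
  m <- build_gene_models(cohort)[["GENE_X"]]
  expect_equal(m$mu, 0.6, tolerance = 0.05 / 0.6)
})

test_that("global model: seeded sampling is deterministic and degenerate
          cohorts use all positions", {
  cohort <- make_null_cohort(n_samples = 30, n_sites = 100, seed = 61)
  g1 <- build_global_model(cohort, n_positions = 50, seed = 9)
  g2 <- build_global_model(cohort, n_positions = 50, seed = 9)
  expect_identical(attr(g1, "positions"), attr(g2, "positions"))
  expect_identical(c(g1$mu, g1$sigma), c(g2$mu, g2$sigma))
  g3 <- build_global_model(cohort, n_positions = 50, seed = 10)
  expect_false(identical(attr(g1, "positions"), attr(g3, "positions")))
  expect_warning(gall <- build_global_model(cohort, n_positions = 2000,
                                            seed = 9),
                 "using all")
  expect_length(attr(gall, "positions"), 100)
  expect_equal(gall$mu, 0.5, tolerance = 0.02)
  expect_error(build_global_model(cohort[0, ]), "cohort")
})

test_that("model serialization round-trips bit-for-bit and rejects corrupt
          files", {
  cohort <- make_null_cohort(n_samples = 15, n_sites = 25, seed = 71)
  model <- suppressWarnings(build_reference_model(cohort, seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  reloaded <- load_model(path)
  expect_identical(
    vapply(model$position_models, `[[`, numeric(1), "mu"),
    vapply(reloaded$position_models, `[[`, numeric(1), "mu"))
  expect_identical(model$global_model$sigma, reloaded$global_model$sigma)
  # downstream p-values identical
  one <- cohort[cohort$sample_id == "N01", ]
  expect_identical(test_sample(one, model)$sites$p_value,
                   test_sample(one, reloaded)$sites$p_value)
  # determinism: same inputs + seed -> byte-identical file
  model2 <- suppressWarnings(build_reference_model(cohort, seed = 5))
  path2 <- withr::local_tempfile(fileext = ".json")
  save_model(model2, path2)
  expect_identical(readLines(path), readLines(path2))
  # truncated file is an explicit error
  txt <- readLines(path)
  writeLines(txt[1:(length(txt) %/% 2)], path2)
  expect_error(load_model(path2), "corrupt|missing")
  # empty gene-model map survives the round trip
  model$gene_models <- list()
  save_model(model, path)
  expect_length(load_model(path)$gene_models, 0)
})
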