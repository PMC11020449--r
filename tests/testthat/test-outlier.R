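null_params <- function(mu = 0.5, sigma = 0.1) {
  betabin_params(mu, sigma, 10L, "global", "global")
}

test_that("two-sided p-value: symmetry, cap at 1, frozen enumeration value", {
  p <- null_params()
  # centre of a symmetric null: both tails >= 0.5, capped
  expect_equal(two_sided_pvalue(10, 20, p), 1)
  # symmetry around n/2 when mu = 0.5
  for (x in 0:10) {
    expect_equal(two_sided_pvalue(x, 20, p), two_sided_pvalue(20 - x, 20, p))
  }
  # frozen from direct pmf summation: x = 0, n = 30, mu = 0.5, sigma = 0.1
  expect_equal(two_sided_pvalue(0, 30, p), 0.000437684648211,
               tolerance = 1e-9)
  expect_error(two_sided_pvalue(5, 4, p), "0 <= x <= n")
})

test_that("p-values equal brute-force full-pmf enumeration", {
  for (n in c(5, 20, 50)) {
    for (mu in c(0.3, 0.5, 0.8)) {
      for (sigma in c(0.02, 0.3)) {
        pars <- null_params(mu, sigma)
        got <- vapply(0:n, two_sided_pvalue, numeric(1), n = n,
                      params = pars)
        want <- vapply(0:n, oracle_two_sided_p, numeric(1), n = n,
                       mu = mu, sigma = sigma)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("p-value is non-increasing in distance from n/2 under a symmetric
          null", {
  pars <- null_params(0.5, 0.05)
  for (n in c(21, 40)) {
    pv <- vapply(0:n, two_sided_pvalue, numeric(1), n = n, params = pars)
    d <- abs(0:n - n / 2)
    ord <- order(d)
    expect_true(all(diff(pv[ord]) <= 1e-12))
  }
})

test_that("under the null, P(p < alpha) <= alpha plus Monte-Carlo
          tolerance", {
  withr::with_seed(77, {
    n_sites <- 4000
    depth <- pmax(11, rnbinom(n_sites, mu = 50, size = 5))
    for (sigma in c(0.02, 0.1)) {
      pars <- null_params(0.5, sigma)
      x <- rbetabinom(n_sites, depth, 0.5, sigma)
      pv <- vapply(seq_len(n_sites), function(i)
        two_sided_pvalue(x[i], depth[i], pars), numeric(1))
      for (alpha in c(0.01, 0.05, 0.1)) {
        mc <- 3 * sqrt(alpha * (1 - alpha) / n_sites)
        expect_lte(mean(pv < alpha), alpha + mc)
      }
    }
  })
})

make_test_model <- function() {
  pm <- list("X:1000" = betabin_params(0.5, 0.05, 20L, "position", "X:1000"))
  gm <- list(GENE_A = betabin_params(0.5, 0.08, 30L, "gene", "GENE_A"))
  structure(list(position_models = pm, gene_models = gm,
                 global_model = betabin_params(0.5, 0.1, 100L, "global",
                                               "global"),
                 metadata = list(schema_version = "1.0")),
            class = "xci_reference_model")
}

test_that("model selection follows the position > gene > global hierarchy", {
  m <- make_test_model()
  expect_equal(select_model(m, "X", 1000, "GENE_A")$tier, "position")
  expect_equal(select_model(m, "X", 2000, "GENE_A")$tier, "gene")
  expect_equal(select_model(m, "X", 2000, "GENE_Z")$tier, "global")
  expect_equal(select_model(m, "X", 2000, ".")$tier, "global")
})

make_patient <- function(ref_counts, depths, pos = NULL, gene = ".") {
  k <- length(ref_counts)
  data.frame(sample_id = "P1", chrom = "X",
             pos = if (is.null(pos)) seq_len(k) * 10L + 5000L else pos,
             ref_allele = "C", alt_allele = "T",
             ref_count = as.integer(ref_counts),
             alt_count = as.integer(depths - ref_counts),
             total_depth = as.integer(depths),
             gene_symbol = rep_len(gene, k), stringsAsFactors = FALSE)
}

test_that("test_sample: strict depth rule, tier totality, order invariance", {
  m <- make_test_model()
  cv <- make_patient(c(5, 3, 30, 2), c(10, 11, 30, 9),
                     pos = c(1000L, 2000L, 3000L, 4000L),
                     gene = c("GENE_A", "GENE_A", ".", "."))
  r <- test_sample(cv, m, min_test_depth = 10)
  # depth 10 and 9 excluded (strict), 11 and 30 tested
  expect_equal(r$summary$n_sites_tested, 2L)
  expect_setequal(r$sites$pos, c(2000L, 3000L))
  expect_equal(r$sites$model_used[r$sites$pos == 2000], "gene")
  expect_equal(r$sites$model_used[r$sites$pos == 3000], "global")
  # tier counts sum to n tested
  expect_equal(sum(table(r$sites$model_used)), r$summary$n_sites_tested)
  expect_equal(sum(r$summary$model_usage), 1)
  # significance flag consistent with alpha
  expect_equal(r$sites$significant, r$sites$p_value < r$summary$alpha)
  # input order does not change the summary
  r2 <- test_sample(cv[rev(seq_len(nrow(cv))), ], m, min_test_depth = 10)
  expect_equal(r2$summary$pct_skewed, r$summary$pct_skewed)
})

test_that("samples with no eligible site are unreportable, not 0%", {
  m <- make_test_model()
  cv <- make_patient(c(4, 5), c(10, 8))
  expect_warning(r <- test_sample(cv, m), "unreportable")
  expect_equal(r$summary$status, "unreportable")
  expect_true(is.na(r$summary$pct_skewed))
})

test_that("skewed samples score higher than paired random samples from the
          same simulator", {
  wins <- withr::with_seed(88, {
    vapply(1:10, function(i) {
      spec <- simulation_spec(n_samples = 30, n_sites = 80,
                              rho = c(rep(0.55, 28), 0.9, 0.5),
                              seed = 1000 + i)
      coh <- simulate_reference_cohort(spec)
      model <- suppressWarnings(build_reference_model(
        coh$cvac[!coh$cvac$sample_id %in% c("SIM_029", "SIM_030"), ],
        seed = 3))
      skewed <- test_sample(coh$cvac[coh$cvac$sample_id == "SIM_029", ],
                            model)$summary$pct_skewed
      random <- test_sample(coh$cvac[coh$cvac$sample_id == "SIM_030", ],
                            model)$summary$pct_skewed
      skewed > random
    }, logical(1))
  })
  expect_true(all(wins))
})

test_that("site-list exclusion recomputes both numerator and denominator", {
  m <- make_test_model()
  # 10 tested sites, 2 significant (monoallelic), at known positions
  cv <- make_patient(c(30, 30, rep(15, 8)), rep(30, 10),
                     pos = seq(5000L, 5900L, by = 100L))
  r <- test_sample(cv, m)
  expect_equal(r$summary$n_significant, 2L)
  # remove one significant site (5000) and one non-significant (5200)
  esc <- make_intervals("X", c(4999, 5199), c(5000, 5200),
                        role = "escape_genes")
  ex <- exclude_site_lists(r, escape = esc)
  expect_equal(ex$n_removed, 2L)
  expect_equal(ex$pct_skewed_excluded, 100 * 1 / 8)
  expect_equal(ex$pct_skewed, r$summary$pct_skewed)
  # no overlap: percentages identical
  far <- make_intervals("X", 1, 10, role = "escape_genes")
  ex2 <- exclude_site_lists(r, escape = far)
  expect_equal(ex2$pct_skewed_excluded, r$summary$pct_skewed)
  # editing sites removed by exact coordinate
  ed <- data.frame(chrom = "X", pos = 5100L)
  ex3 <- exclude_site_lists(r, editing_sites = ed)
  expect_equal(ex3$n_removed, 1L)
})

test_that("pairwise tier agreement is symmetric-by-construction and high on
          a null cohort", {
  coh <- make_null_cohort(n_samples = 30, n_sites = 40, depth = 40,
                          seed = 91)
  model <- suppressWarnings(build_reference_model(coh, seed = 3))
  one <- coh[coh$sample_id == "N01", ]
  ag <- model_usage_agreement(one, model)
  expect_true(all(ag >= 80, na.rm = TRUE))
  # sites where every tier is far from significance agree in all pairs
  m <- make_test_model()
  cv <- make_patient(15, 30, pos = 1000L, gene = "GENE_A")
  ag2 <- model_usage_agreement(cv, m)
  expect_equal(unname(ag2), c(100, 100, 100))
})
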