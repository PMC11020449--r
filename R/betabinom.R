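## Beta-binomial null model in the (mu, sigma) mean/dispersion
## parameterization: alpha = mu/sigma, beta = (1 - mu)/sigma, so that
## E[X/n] = mu and the intraclass correlation is sigma/(1 + sigma). This is
## the BB parameterization used by GAMLSS, recorded in every model file.

#' Laplace-smooth an allele-count pair
#'
#' Adds the pseudo-count `k` to both alleles (total becomes `n + 2k`);
#' applied to reference-cohort counts before fitting so that zero-count
#' sites remain informative. Patient counts are tested unsmoothed.
#'
#' @param ref_count,alt_count non-negative counts (vectorized).
#' @param k positive pseudo-count, default 1; fractional values allowed.
#' @return list with `ref` and `alt` smoothed counts.
#' @export
#' @examples
#' laplace_smooth(0, 0)         # (1, 1)
#' laplace_smooth(3, 7, k = 0.5)
laplace_smooth <- function(ref_count, alt_count, k = 1) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    stop("smoothing constant k must be a positive number")
  }
  if (any(ref_count < 0) || any(alt_count < 0)) stop("counts must be >= 0")
  list(ref = ref_count + k, alt = alt_count + k)
}

#' Beta-binomial density in the (mu, sigma) parameterization
#'
#' `P(X = x) = C(n,x) B(x + a, n - x + b) / B(a, b)` with `a = mu/sigma`,
#' `b = (1 - mu)/sigma`. Vectorized over `x` and `n`.
#'
#' @param x observed successes, `0 <= x <= n`.
#' @param n number of trials.
#' @param mu mean parameter in (0, 1).
#' @param sigma dispersion parameter > 0.
#' @param log return the log density?
#' @return (log-)probabilities.
#' @export
dbetabinom <- function(x, n, mu, sigma, log = FALSE) {
  if (any(mu <= 0) || any(mu >= 1)) stop("mu must be in (0, 1)")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (any(x < 0) || any(x > n)) stop("x must satisfy 0 <= x <= n")
  a <- mu / sigma
  b <- (1 - mu) / sigma
  lp <- lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
  if (log) lp else exp(lp)
}

#' Draw beta-binomial counts
#'
#' @param m number of draws.
#' @param n trials per draw (scalar or length `m`).
#' @inheritParams dbetabinom
#' @return integer vector of length `m`.
#' @export
rbetabinom <- function(m, n, mu, sigma) {
  p <- stats::rbeta(m, mu / sigma, (1 - mu) / sigma)
  stats::rbinom(m, n, p)
}

#' Construct a fitted beta-binomial parameter object
#'
#' @param mu,sigma fitted parameters (`0 < mu < 1`, `sigma > 0`).
#' @param n_obs number of (ref, alt) pairs used in the fit.
#' @param tier `"position"`, `"gene"` or `"global"`.
#' @param key position id (`"X:pos"`), gene symbol, or `"global"`.
#' @param loglik optional log-likelihood at the optimum.
#' @return a `betabin_params` list.
#' @export
betabin_params <- function(mu, sigma, n_obs, tier, key, loglik = NA_real_) {
  if (mu <= 0 || mu >= 1) stop("mu must be in (0, 1)")
  if (sigma <= 0) stop("sigma must be > 0")
  tier <- match.arg(tier, c("position", "gene", "global"))
  structure(list(mu = unname(mu), sigma = unname(sigma),
                 n_obs = as.integer(n_obs),
                 tier = tier, key = key, loglik = loglik),
            class = "betabin_params")
}

#' @export
print.betabin_params <- function(x, ...) {
  cat(sprintf("beta-binomial [%s] %s: mu = %.4f, sigma = %.4g (n = %d)\n",
              x$tier, x$key, x$mu, x$sigma, x$n_obs))
  invisible(x)
}

## method-of-moments start: mu from the mean allelic fraction, sigma from
## the intraclass correlation implied by the excess variance of fractions
mom_init <- function(r, n) {
  p <- r / n
  mu0 <- min(max(mean(p), 1e-3), 1 - 1e-3)
  v <- stats::var(p)
  if (!is.finite(v) || v <= 0) {
    rho <- 1e-6
  } else {
    rho <- (v - mu0 * (1 - mu0) * mean(1 / n)) /
      (mu0 * (1 - mu0) * (1 - mean(1 / n)))
    rho <- min(max(rho, 1e-6), 0.9)
  }
  c(mu = mu0, sigma = rho / (1 - rho))
}

#' Fit a beta-binomial null by maximum likelihood
#'
#' Laplace-smooths the supplied (ref, alt) pairs, then maximizes the
#' beta-binomial likelihood over `(logit mu, log sigma)` with bounded
#' quasi-Newton (L-BFGS-B), started from method-of-moments estimates. The
#' optimizer never returns a worse likelihood than the start. `mu` is
#' clamped to `(1e-6, 1 - 1e-6)` and `sigma` to `(1e-8, 1e3)`.
#'
#' @param ref_counts,alt_counts paired non-negative integer vectors.
#' @param k_smooth Laplace pseudo-count applied before fitting (default 1);
#'   `0` disables smoothing.
#' @param min_pairs eligibility threshold; fewer pairs raises an
#'   `xci_eligibility_error` so callers can skip the tier.
#' @param tier,key metadata stored on the result.
#' @return a [betabin_params()] object.
#' @export
fit_betabinom <- function(ref_counts, alt_counts, k_smooth = 1,
                          min_pairs = 10, tier = "global", key = "global") {
  if (length(ref_counts) != length(alt_counts)) {
    stop("ref and alt count vectors differ in length")
  }
  if (length(ref_counts) < min_pairs) {
    stop_classed("xci_eligibility_error",
                 sprintf("only %d pair(s) available, need >= %d",
                         length(ref_counts), min_pairs))
  }
  if (k_smooth > 0) {
    sm <- laplace_smooth(ref_counts, alt_counts, k_smooth)
    r <- sm$ref; a <- sm$alt
  } else {
    r <- ref_counts; a <- alt_counts
  }
  n <- r + a
  if (any(n <= 0)) stop("pairs with zero total count cannot be fitted")
  init <- mom_init(r, n)
  lo <- c(stats::qlogis(1e-6), log(1e-8))
  hi <- c(stats::qlogis(1 - 1e-6), log(1e3))
  th0 <- pmin(pmax(c(stats::qlogis(init["mu"]), log(init["sigma"])), lo), hi)
  nll <- function(th) {
    -sum(dbetabinom(r, n, stats::plogis(th[1]), exp(th[2]), log = TRUE))
  }
  opt <- stats::optim(th0, nll, method = "L-BFGS-B", lower = lo, upper = hi)
  if (opt$convergence != 0 || !is.finite(opt$value)) {
    ## L-BFGS-B can stop in its line search at a bound; retry with a
    ## bound-clamped Nelder-Mead and keep the better optimum
    nll_clamped <- function(th) nll(pmin(pmax(th, lo), hi))
    nm <- stats::optim(th0, nll_clamped, method = "Nelder-Mead",
                       control = list(maxit = 2000))
    nm$par <- pmin(pmax(nm$par, lo), hi)
    if (is.finite(nm$value) &&
        (!is.finite(opt$value) || nm$value < opt$value)) {
      opt <- nm
    }
    if (!is.finite(opt$value)) {
      stop("beta-binomial fit did not converge (code ", opt$convergence,
           ", value ", opt$value, ") for ", tier, " ", key)
    }
  }
  ## guard: never degrade the method-of-moments start
  if (opt$value > nll(th0) + 1e-8) {
    opt$par <- th0
    opt$value <- nll(th0)
  }
  betabin_params(mu = unname(stats::plogis(opt$par[1])),
                 sigma = unname(exp(opt$par[2])),
                 n_obs = length(ref_counts), tier = tier, key = key,
                 loglik = unname(-opt$value))
}
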