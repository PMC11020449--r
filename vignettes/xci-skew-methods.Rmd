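---
title: "Calling skewed X-chromosome inactivation from allelic expression: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling skewed X-chromosome inactivation from allelic expression: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciskew)
```

## The problem

In females, one of the two X chromosomes is epigenetically silenced in each
cell early in development. When the choice is random, a bulk tissue sample
expresses both parental X haplotypes in roughly equal proportion; when the
same parental X is inactivated in a large majority of cells ("skewed" XCI,
observed in roughly a quarter of adult females), one haplotype dominates
expression chromosome-wide. Skew matters clinically: it can unmask or
silence X-linked disease alleles in carriers. The established clinical test
interrogates methylation at a single locus (the androgen receptor CAG
repeat) and is uninformative in 10–20% of patients and not always
representative of the whole chromosome.

`xciskew` instead measures allelic expression at many heterozygous X-linked
sites. Exome sequencing supplies high-confidence heterozygous positions;
RNA-seq read pileups at those positions supply reference/alternate allele
counts (the CVAC table). Because the data are unphased and no parental
genotypes are used, the method does not estimate *which* X is inactive —
only whether each site's allelic balance is an outlier relative to a
reference population, and what fraction of a sample's sites are such
outliers.

## The reference model

For position $i$, let $r_{ji}$ and $a_{ji}$ be the reference and alternate
RNA read counts in reference sample $j$. If every female expressed both
alleles with the same probability, a binomial model would suffice; in
reality each female has her own latent allelic fraction at each position
(cellular mosaicism, local regulation), so the counts are overdispersed. We
integrate the latent fraction over a beta distribution, giving a
beta-binomial null:

$$ r_{ji} \sim \mathrm{BB}(n_{ji},\ \mu_i,\ \sigma_i), \qquad
   \alpha_i = \mu_i/\sigma_i,\quad \beta_i = (1-\mu_i)/\sigma_i , $$

the mean/dispersion parameterization used by GAMLSS-style beta-binomial
regression ($\mathbb{E}[r/n] = \mu$; intraclass correlation
$\sigma/(1+\sigma)$). Counts are Laplace-smoothed ($r+k$, $a+k$, default
$k = 1$) *before fitting only*, so zero-coverage alleles remain
informative; patient counts are never smoothed.

Three tiers are fitted:

* **position models** — one per position covered by ≥ 3 reads in ≥ 10
  reference samples (both bounds inclusive);
* **gene models** — one per gene, pooling all depth-eligible
  (position, sample) pairs within the gene, with the same ≥ 10-observation
  rule applied to the pooled pairs;
* **one global model** — fitted on all depth-eligible pairs from 2000
  positions sampled without replacement under a recorded seed (all
  positions, with a warning, when fewer exist).

When a patient site is scored, the most specific available tier is used:
position, else gene, else global. The hierarchy is strict; a site whose
position was seen in the cohort but below eligibility still falls through
to the gene or global tier.

### Fitting

Maximum likelihood is computed over $(\mathrm{logit}\,\mu, \log\sigma)$
with bounded quasi-Newton (L-BFGS-B), initialized at method-of-moments
estimates (mean allelic fraction; intraclass correlation from the excess
variance of fractions). $\mu$ is clamped to $(10^{-6}, 1-10^{-6})$ and
$\sigma$ to $(10^{-8}, 10^{3})$; degenerate data (all fractions identical)
land on the dispersion floor rather than erroring. If the line search stops
abnormally at a bound, a bound-clamped Nelder-Mead restart is taken when it
improves the likelihood; the returned optimum is never worse than the
moments start. The tests verify the fitted log-likelihood against a dense
grid-search oracle and recovery of $\mu$ within ±0.03 (median over 20
replicates at 200 pairs of depth 50, $\mu \in \{0.5, 0.7, 0.9\}$,
$\sigma \in \{0.02, 0.2\}$).

## The outlier test

For a patient site with $x$ reference reads out of $n > 10$ (strict; sites
at depth ≤ 10 are not tested), the two-sided p-value under the selected
null is the doubled minimum tail, point mass included, capped at one:

$$ p = \min\!\big(1,\ 2\min\{P(X \le x),\ P(X \ge x)\}\big) . $$

Both tails are computed by exact summation of the probability mass
function. $x$ is the reference-allele count by convention; the test being
two-sided makes the choice inconsequential. Raw p-values are compared to
$\alpha = 0.05$ with no multiple-testing correction — the per-sample
statistic is the *percentage of significantly skewed sites among tested
sites*, not any individual site call, and the reference threshold is
calibrated on the same statistic. A sample with zero eligible sites is
explicitly *unreportable*, never a silent 0%.

### Discreteness and calibration

The doubled-tail construction on a discrete support is conservative at
moderate depth: exact enumeration shows the achieved level at
$\alpha = 0.05$, $\mu = 0.5$ is ≈ 0.026–0.036 at $n = 30$, ≈ 0.032–0.038 at
$n = 50$, and approaches the nominal level only as the support grows
(≥ 0.049 for all $\sigma \ge 0.02$ at $n = 1000$). Two checks follow from
this analysis: a validity property test asserts
$P(p < \alpha) \le \alpha + $ Monte-Carlo tolerance at typical depths
($n \approx 50$), and a calibration check at deep coverage ($n = 1000$,
10,000 sites simulated from the fitted null) asserts the fraction
significant is within three Monte-Carlo standard errors of 0.05, where
support discreteness no longer masks miscalibration of the machinery
itself.

## Classification and thresholding

A sample is **skewed** when its percentage of significantly skewed sites
strictly exceeds the threshold. The default fixed threshold is 14%, derived
from a reference-population density plot; 12% is the preset appropriate
when a combined patient cohort is used as its own reference. Because the
appropriate cut depends on the cohort, `derive_threshold()` re-derives it:
a Gaussian KDE (Silverman's rule, 512 grid points on
$[0, \max(\mathrm{pct}) + 5]$) is searched for local minima in 5–25%; a
candidate must be a genuine valley (a mode on each side with at least twice
the valley density — tail wiggles of a unimodal KDE are not separating
minima) and must have at least one sample above it. Among candidates, the
one whose implied skew-call rate falls in the expected population range
(10–20%) is chosen, the deepest valley breaking ties, the closest-rate
candidate when none qualifies; with fewer than 20 samples or no valley the
fixed value is used with a warning. Because the grid endpoints depend on
the data range, translation equivariance of the derived threshold holds up
to the grid resolution.

Concordance with an orthogonal assay uses a 2×3 confusion table (NGS
random/skewed × assay random/skewed/uninformative; "highly" and
"moderately" skewed assay labels collapse to skewed). The concordance rate
is computed over informative pairs with an exact Clopper–Pearson 95%
binomial interval (via `stats::binom.test`; the tests cross-check the
endpoints against direct root-finding on binomial tail probabilities).

## The synthetic cohort generator

No external cohort is shipped or required. The generator collapses cellular
mosaicism to a site-level model: a sample with XCI ratio
$\rho \in [0.5, 1]$ expresses each non-escape site at expected reference
fraction $\rho$ or $1-\rho$ (fair-coin phase per site, since real data are
unphased), with beta-binomial noise $\sigma_{\mathrm{site}} = 0.02$ around
it; escape sites express at 0.5 regardless of $\rho$. Defaults fixed as the
package's study conditions: 135 reference samples, 90% with
$\rho \sim U(0.5, 0.65)$ and 10% with $\rho \sim U(0.85, 0.99)$ (matching
the ~8–10% population skew rate); 150 shared sites observed with
probability 0.7 per sample (not every map site is heterozygous in every
female); depth $\sim \mathrm{NB}(\mathrm{mean}\ 50, \mathrm{size}\ 5)$
capped at 500; 5% of sites in escape genes. Every draw flows from one
master seed, with per-sample derived streams so any sample regenerates
independently and byte-identically.

What the simulator does *not* emulate: reference bias from alignment,
RNA-editing artifacts, positional/GC covariates of dispersion, varying
degrees of escape, or library-preparation differences between cohorts.
Passing recovery tests therefore demonstrates the statistical machinery
under the stated generative assumptions, not performance on any particular
real dataset. The end-to-end check — sensitivity and specificity ≥ 0.9 for
patients at $\rho \ge 0.85$ versus $\rho \le 0.6$, depth ≥ 30, 150
sites/sample, pooled over 20 replicate cohorts — uses these defaults; on
the machine used for development each replicate takes about one second.

## File contracts and numerical choices

* Coordinates: VCF and all internal positions 1-based; BED I/O 0-based
  half-open, converted by `rtracklayer`. Intervals are held as `GRanges`
  (1-based closed). Chromosome aliases ("chrX", "23") normalize to "X".
* PAR defaults are GRCh37 (PAR1 X:60,001–2,699,520; PAR2
  X:154,931,044–155,260,560), overridable by BED.
* Heterozygous = exactly one reference plus one alternate allele after
  multi-allelic decomposition; SNVs and 1-bp indels only. Exome depth
  `> 10` (strict) and GQ `>= 20`; FILTER "." is treated as PASS unless
  strict mode is set.
* The mpileup parser attributes 1-bp indel alleles through `+1X`/`-1X`
  tokens attached to anchor bases; `N`, `*` and `>`/`<` count for neither
  allele. Mapping-quality filtering (≥ 20) is delegated to the pileup
  producer (`samtools mpileup -q 20`); the parser enforces base quality
  (default ≥ 30) only.
* Model files are versioned JSON written with 17 significant digits, so
  reloading reproduces every parameter — and hence every downstream
  p-value — bit-for-bit; truncated or version-mismatched files are explicit
  errors.
* Overlapping gene annotations resolve first-by-coordinate-then-name;
  intergenic sites get a sentinel and are excluded from gene models but not
  from position/global scoring.

## Known limitations

* The percent-skewed statistic does not estimate the XCI ratio itself; a
  sample can be called skewed without an estimate of *how* skewed beyond
  the site-level evidence.
* Sensitivity degrades with sparse heterozygous coverage: with few tested
  sites the percentage is coarse, and the unreportable path triggers when
  nothing passes the depth rule.
* Mild skew (e.g., $\rho \approx 0.7$) overlapping the reference cohort's
  own spread is not reliably separable — by design, since the null is the
  population's variability.
* Whole-blood reference data inform whole-blood patients; transferring the
  threshold across cohorts with different library preparations requires
  re-deriving it (`derive_threshold()`), which is why the threshold is
  configuration, not a constant.
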