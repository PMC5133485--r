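---
title: "Multivariate rare-variant association testing: models, calibration, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate rare-variant association testing: models, calibration, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murat)
```

## The problem

Sequencing cohorts usually measure several related continuous traits on
every individual — here the motivating pair is log-transformed systolic
and diastolic blood pressure, which are strongly correlated (Pearson
correlation about 0.54 on the log scale). A variant, or a region of rare
variants, may influence several of these traits at once (pleiotropy), or
different variants in the same gene may act on different traits. Testing
each trait separately and Bonferroni-correcting throws away the
correlation structure; a joint test can recover that power.

This package implements a region-based multivariate score test for K
correlated continuous phenotypes (exported as `muratPvalue()` and called
"the multivariate test" below), alongside the univariate sequence kernel
association test (SKAT, `skatPvalue()`) as the standard single-phenotype
comparator, and the scan protocol around them: single-variant, gene-based
and fixed-window designs with Bonferroni and minimum-p adjustments.

## The model

For individual $i$ with phenotype vector
$Y_i = (Y_{i1},\dots,Y_{iK})^T$, covariates $X_i$ ($m$ of them) and a
region of $v$ variant dosages $G_i$:

$$
Y_i = \alpha_0 + (I_K \otimes X_i^T)\,\alpha
      + (I_K \otimes G_i^T)\,\beta + \varepsilon_i ,
$$

where $\beta$ stacks the $K \times v$ variant effects phenotype-major
and $\varepsilon_i$ is multivariate normal with an unstructured $K
\times K$ covariance $\Sigma_\varepsilon$ (estimated from the null fit;
the model for a single phenotype reduces to the familiar linear model
behind SKAT). The effects are treated as random,
$\beta \sim N_{Kv}(0, \Sigma_\beta)$, with the structure that carries
the multivariate information: effects of the *same* variant on two
phenotypes share a common correlation $\rho$, effects of *different*
variants are uncorrelated, and each variant carries a MAF-based weight
$w_j$. Testing $H_0:\beta = 0$ against this random-effect alternative
gives a variance-component score statistic at each $\rho$:

$$
Q_\rho = r^T V^{-1} (R_\rho \otimes G W G^T) V^{-1} r,
\qquad
V = \Sigma_\varepsilon \otimes I_n,\quad
R_\rho = (1-\rho) I_K + \rho J_K,\quad
W = \mathrm{diag}(w_j^2),
$$

with $r$ the stacked null residuals (phenotype-major, so that $V$ is the
Kronecker product above — a single stacking convention used everywhere
in the code and asserted by shape checks). Under $H_0$, $Q_\rho$ is a
weighted sum of independent 1-df chi-squares whose weights are the
eigenvalues of
$(\Sigma_\varepsilon^{-1/2} R_\rho \Sigma_\varepsilon^{-1/2}) \otimes
(W^{1/2} G_\perp^T G_\perp W^{1/2})$, where $G_\perp$ is the genotype
matrix residualized against the null design. Because the matrix is a
Kronecker product, the $K\times K$ and $v\times v$ factors are
decomposed separately and their eigenvalues multiplied — the
decomposition never forms the $Kv \times Kv$ matrix.

At $K = 1$ the statistic, eigenvalues and p-value reduce *exactly* to
univariate SKAT; the test suite asserts agreement to 1e-8 relative. At
$\rho = 0$ with a diagonal error covariance the statistic decomposes
into the sum of per-phenotype SKAT statistics.

## The adaptive $\rho$ and the grid combination

The effect correlation is unknown, so $Q_\rho$ is computed on a grid
(default $\{0, 0.1, \dots, 0.9, 0.99\}$; $\rho = 1$ is excluded to keep
$R_\rho$ positive definite, and 0.99 stands in for perfect correlation)
and the minimum p over the grid is taken. That minimum is selected, so
it is not itself a p-value; it is calibrated by seeded Gaussian score
resampling. The key observation is that the score cross-product
$T = W^{1/2} G_\perp^T E \Sigma_\varepsilon^{-1}$ (with $E$ the $n
\times K$ residual matrix) is finite-dimensional and exactly
$N(0,\ \Sigma_\varepsilon^{-1} \otimes W^{1/2}G_\perp^TG_\perp W^{1/2})$
under the null, conditioning on the nuisance estimates — score-test
logic holds $\Sigma_\varepsilon$ fixed at its null estimate. Surrogate
$T$ matrices are drawn from that law, each surrogate's minimum grid p is
compared with the observed minimum, and

$$
p_{\text{final}} = \frac{1 + \#\{\text{surrogate min-p} \le \text{observed min-p}\}}
                        {B + 1}.
$$

Implementation note: rather than evaluating a chi-square-mixture tail
for every surrogate and every grid point, the observed min-p is inverted
once per grid point into a statistic threshold $q_\rho$ (root search on
the analytic tail), and a surrogate counts as an exceedance when any of
its $Q_b(\rho)$ reaches $q_\rho$. This is mathematically identical and
reduces the tail-engine work from $O(B \times |\text{grid}|)$ to
$O(|\text{grid}|)$ inversions per region.

Two boundary rules keep the result coherent: with a one-point grid (or
$K = 1$, where $\rho$ never enters) the resampling is skipped and
$p_{\text{final}}$ equals the per-$\rho$ p exactly; and
$p_{\text{final}}$ is never reported below the observed minimum —
adjusting for the selection of the best $\rho$ cannot make the p-value
smaller, while an unlucky finite resample otherwise could. The
conservative Bonferroni-over-grid bound (grid size times min-p, capped
at 1) is reported alongside in the result object.

An analytic combination of the grid (in the spirit of the optimal-rho
machinery of SKAT-O) would avoid resampling entirely; it is not
implemented here, and the module boundary — `muratPvalue()` owns the
combination — allows such a drop-in later without touching callers.

## The tail engine

`qformPvalue()` computes $P(\sum_l \lambda_l \chi^2_1 > q)$ by numerical
inversion of the characteristic function (Gil-Pelaez / Davies / Imhof
family). The oscillatory integrand is evaluated as a midpoint sum whose
grid spacing bounds the aliasing error through the distribution's own
tail (the spacing is chosen so the aliased mass lies far below the
accuracy target, itself located with the moment-matched tail) and whose
truncation point is set from the decay of the integrand envelope; both
knobs derive from the `accuracy` argument (default 1e-6, absolute).
Weights and quantile are pre-scaled by the largest weight — the tail is
invariant under that rescaling — so the numerics see a normalized
problem. When the inversion fails, or returns a value at or below its
own accuracy floor (deep tails suffer cancellation under an absolute
error bound), the moment-matching approximation of Liu, Tang and Zhang
is used instead and the result is flagged (`liu_fallback` in
`MuratResult` flags). For equal weights the moment match is exact, and
the suite verifies the inversion against exact chi-square tails (within
1e-5) and against a 10-million-draw Monte Carlo oracle (within 3 MC
standard errors).

Eigenvalues below 1e-10 times the largest are truncated as the numerical
null space of the projected kernel; more negative values are clipped
with a warning. Reported p-values are floored at 1e-300 so downstream
$-\log_{10}$ plotting never sees a hard zero.

## Preprocessing rules and their rationale

* **Log transform.** Natural log (not log10). The choice of base is
  irrelevant to any *linear-model* test only up to rescaling of effect
  sizes, so one base is fixed and documented; natural log is the
  modelling default for right-skewed positive traits.
* **Complete cases.** Samples missing *any* requested phenotype or
  covariate are dropped — the shared-design null regression needs every
  column observed. The covariate extension of the complete-case rule is
  a package decision; the alternative (per-phenotype case deletion)
  would break the single-design QR reuse and the residual-covariance
  estimate.
* **Carrier filter.** A carrier is an individual with at least one
  observed minor allele, counted *before* imputation; a homozygote
  counts once. Variants with fewer than 4 carriers are excluded by
  default — individual-level counting is the natural reading of
  "carriers", and the pre-imputation convention makes the filter
  independent of the imputation step.
* **Missing genotypes.** Mean imputation at the expected dosage
  (2·MAF on the minor-allele scale, folded back when the stored alt
  allele is the major one). Mean imputation is the unique choice for
  which the post-imputation allele frequency equals the pre-imputation
  one deterministically; the identity is algebraically exact and holds
  to ~1 ulp in floating point (the suite asserts 1e-15 relative).
* **Missing VCF calls** map to `NA`, never to dosage 0; imputation is a
  separate explicit step.
* **Weights.** The Beta(1, 25) density on MAF — the SKAT-family default
  — since the analysis protocol names no weights; `c(1, 1)` gives an
  unweighted analysis, and all comparisons in the test suite fix one
  weight choice across methods.

## Regions

Gene regions come from a glist-style annotation (chromosome, start, end,
name; 1-based inclusive bounds; overlapping genes both keep their
variants; genes without variants are dropped). Windows tile each
chromosome with non-overlapping 30-kb intervals on a grid anchored at
coordinate 1 — a deterministic, restart-free tiling; anchoring at the
first variant per chromosome is available (`anchor = "first-variant"`)
since the original protocol's anchor is not stated. Every variant falls
in exactly one window, which the suite asserts as a partition property.
Single-variant "regions" are singletons passing the carrier filter.

## The synthetic cohort

`SimConfig()` defaults encode the study conditions the package is
calibrated under: 1851 unrelated individuals, two phenotypes with
residual correlation 0.542 on unit-variance errors, age ~ N(40, 10²) and
sex ~ Bernoulli(0.5) covariates, and per-region variants with MAF
uniform on [0.001, 0.05], genotypes Binomial(2, MAF) with no linkage
disequilibrium. Values the protocol leaves open were fixed once:
intercepts 4.7/4.3 (log-blood-pressure scale), small covariate effects
(0.003 per year of age, 0.02 for sex — negligible against unit error
variance, so the phenotype correlation stays at its target), 10 variants
per region, effect scale 0.25 per causal variant (a fully causal
10-variant region at these MAFs explains roughly 2–3% of phenotypic
variance at n = 500 — mid-range power, so orderings are visible), and
effect correlation 0.9 for the pleiotropic setting. The single-trait
setting uses effect size 0.3 on the affected trait (only one phenotype
carries signal) and weak trait correlation (0.1): the dilution penalty
it demonstrates — a joint test adding noise when only one trait is
associated — is a property of weakly coupled traits. When traits are
strongly correlated, conditioning on the correlated but unaffected
trait reduces the affected trait's effective residual variance by a
factor $1-r^2$, and the joint test can match or beat the univariate
test even for a single-trait effect, so no reversal exists to
demonstrate there.

What the generator does *not* emulate: linkage disequilibrium between
variants, non-normal phenotype tails, population structure or
relatedness, and MAF-dependent effect sizes. Calibration results under
the generator therefore demonstrate correctness of the statistics under
the stated model, not robustness to those real-data features.

## Calibration and power checks the suite runs

* Type-I error of both tests at α = 0.05 under the null configuration
  (n = 500, 2000 replicate regions, fixed seed) must lie in
  [0.04, 0.06], and the multivariate p-values must stay inside a
  Kolmogorov 99% uniformity band — the Q-Q-plot diagonal check.
* Fixed-ρ analytic p-values are compared with a 50,000-permutation
  oracle on five tiny instances (n = 60, v = 3, K = 2) at a 3-permutation-
  standard-error band. At this sample size the band is a demanding one:
  the analytic null is the unconditional Gaussian law with the estimated
  residual covariance plugged in, while the permutation law conditions
  on the observed genotypes and residuals, and the two differ by O(1/n)
  moment terms — a gap of the same order as the band itself for
  mid-range p-values, so a marginal exceedance on an instance reflects
  that finite-sample difference rather than an error in either
  computation (a direct Monte-Carlo draw from the fitted Gaussian null
  reproduces the analytic p).
* Under the pleiotropic alternative the multivariate test's power is at
  least that of Bonferroni-adjusted univariate testing (500 replicates,
  trait correlation 0.542); under the single-trait alternative with
  weakly correlated traits the affected-trait univariate test wins, and
  the harness demonstrates that reversal.

Problem sizes (replicate counts, n per region) are the package's chosen
trade-off between binomial resolution and suite runtime; the acceptance
script uses 1000 null and 300 power replicates for the same quantities.

## Numerical edge cases

* Residual covariance with condition number above 1e12 receives a soft
  ridge (1e-8 times the mean diagonal) before inversion; a still-singular
  matrix is an error ("fail soft, then loudly").
* Rank-deficient null designs error naming the collinear columns.
* Regions whose genotype submatrix is zero after residualization are
  flagged per-region in `runScan()` (NA p-values), not fatal.
* All simulation and resampling seeds derive deterministically from the
  user-facing seed; identical inputs and seed give byte-identical scan
  reports.

## Known limitations

Unrelated samples only (no kinship or mixed models); continuous
phenotypes only; no SKAT-O-style burden/variance-component mixture for
the univariate comparator; no indel-specific handling (all bi-allelic
records are treated uniformly); the grid combination is resampling-based
rather than analytic, so extremely small final p-values are bounded
below by 1/(B+1) — raise `resamples` (or fall back on the reported
per-ρ minimum with its Bonferroni-over-grid bound) when scanning for
genome-wide-significant hits.
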