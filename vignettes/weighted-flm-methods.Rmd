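---
title: "Weighted functional linear models for region-based association: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted functional linear models for region-based association: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wflm)
```

## The model

Single-variant tests are underpowered for rare variants, so region-based
tests aggregate all variants in a gene or window. The classical multi-variant
mixed model for a quantitative trait $y$ on $n$ individuals with $m$ variants
in a region is

$$y = X\alpha + G\beta + h + \epsilon, \qquad
  h \sim N(0,\sigma_g^2 R), \quad \epsilon \sim N(0,\sigma_e^2 I),$$

where $X$ is the covariate design (leading intercept column), $G$ the
$n\times m$ matrix of minor-allele dosages, $R$ the expected additive
relationship matrix ($R = I$ for unrelated samples), and
$\Omega = \sigma_g^2 R + \sigma_e^2 I$ the trait covariance. Testing all $m$
genotype effects costs $m$ degrees of freedom and ignores variant positions.

The functional approach treats the genotypes of each individual, and the
effect sizes, as smooth functions of position. Variant coordinates are sorted
and scaled affinely to $[0,1]$; genotype functions are expanded in $K_G$
basis functions $\phi(t)$ and the effect function in $K_\beta$ basis
functions $\psi(t)$. This collapses the model to

$$y = X\alpha + G W \beta_F + h + \epsilon, \qquad
  W = \Phi(\Phi^T\Phi)^{-1}\int_0^1 \phi(t)\,\psi^T(t)\,dt,$$

with $\Phi_{ij} = \phi_j(t_i)$, so only $K_\beta$ coefficients are tested.
When the same basis is used for genotypes and effects the two-smoothing model
is equivalent to the *beta-smooth only* model that leaves genotypes discrete
($W = \Psi$, the effect-basis evaluation matrix); this equivalence is
verified by the test suite at $10^{-8}$ relative precision.

The weighted model inserts a diagonal matrix $\Theta$ of per-variant weights,

$$y = X\alpha + G\,\Theta\,W \beta_F + h + \epsilon,$$

so that a priori more plausible causal variants contribute more to the
collapsed design. Following the rare-variant weighting used by kernel
methods, the default weight is the beta density evaluated at the sample
minor-allele frequency, $\mathrm{Beta}(\mathrm{MAF}_j; a_1, a_2)$, with
$(1,25)$ the standard rare-variant setting, $(0.5,0.5)$ a milder alternative,
and $(1,1)$ recovering the unweighted model exactly.

$H_0:\beta_F = 0$ is tested with an F-statistic for fixed effects in the
mixed model: variance components are estimated once under the null, data are
whitened by $\Omega^{-1/2}$, and the test is the nested ordinary-least-squares
comparison

$$F = \frac{(RSS_0 - RSS_1)/q}{RSS_1/(n - p_0 - q)},$$

with $q$ the *detected rank* of the whitened, covariate-adjusted functional
design and $p_0$ the number of fixed covariates (intercept included). For
unrelated samples this is exactly the classical multiple-regression F-test.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| basis family | B-spline | `"bspline"` or `"fourier"` |
| $K_\beta$ | 15 (B-spline), 25 (Fourier) | number of effect basis functions; the standard recommendations for these two families |
| spline order | 4 (cubic) | with uniformly spaced simple interior knots and order-fold boundary knots |
| $(a_1, a_2)$ | (1, 25) | beta-density weight shape; $(1,1)$ = unweighted |
| weight convention | density | `"density"` uses $\Theta_{jj} = \mathrm{Beta}(\mathrm{MAF};a_1,a_2)$; `"squared"` its square |
| MAF filter | none | optional hard exclusion of variants with MAF above a cutoff (0.03 conventionally); weighting is the soft alternative |
| REML tolerance | $10^{-8}$ | profiled 1-D search over $h^2 \in [0,1]$ |

The $\sqrt{w}$ convention deserves a note: the weighting literature writes
$\sqrt{w_j} = \mathrm{Beta}(\mathrm{MAF}_j; a_1,a_2)$ while the design
multiplies genotype columns by $\Theta$ once. With a saturated effect basis
the two readings differ only by column scaling and give identical tests; for
smoothed designs they genuinely differ, so both are exposed
(`weight_spec(convention = )`) and the density itself is the default,
matching how kernel-method weights multiply genotypes.

## Null model estimation

`fit_null()` estimates $(\sigma_g^2, \sigma_e^2)$ by REML. With
$R = UDU^T$ computed once per sample, the restricted likelihood profiles to
a bounded scalar search over $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$; the
search is golden-section (`optimize`) with both boundary values checked
explicitly. REML is preferred over ML so that variance components are
unbiased in the presence of covariates. Components are estimated once per
trait under the null (no region term) and held fixed for every region's
F-test — the standard two-step practice for region scans. For unrelated
samples the components are not separately identifiable and the fit reports
$\sigma_g^2 = 0$ by convention, with the total variance in $\sigma_e^2$;
the downstream F-test is then scale-invariant anyway.

## Numerical choices

* **Degenerate positions.** Duplicate coordinates are separated by a
  deterministic jitter of $k\epsilon$ within each run of duplicates,
  $\epsilon = 10^{-6}$ of the raw span, before scaling; a region whose
  positions are all identical is an error. Results are reproducible because
  the jitter is deterministic.
* **Fourier normalisation.** The basis is orthonormal on $[0,1]$ (constant
  $1$, pairs scaled by $\sqrt2$), which makes the Fourier-by-Fourier
  cross-integral the identity analytically. The F-test is invariant to any
  invertible recombination of basis columns, so this choice affects nothing
  observable.
* **Cross-integrals.** Any product involving B-splines is integrated by
  composite Gauss–Legendre quadrature with 7 points per inter-knot interval:
  exact for the piecewise-polynomial products in play and far below
  $10^{-10}$ error for the trigonometric factors.
* **Conditioning of $W$.** $\Phi(\Phi^T\Phi)^{-1}J$ is computed through the
  QR factorisation of $\Phi$, so accuracy degrades with $\kappa(\Phi)$
  rather than $\kappa(\Phi)^2$. If $\mathrm{rcond}(\Phi^T\Phi) < 10^{-10}$
  (random variant positions can leave a spline basis function unsupported),
  the model refuses to invert and advises the beta-smooth-only path.
* **Rank and degrees of freedom.** The numerator degrees of freedom use the
  rank of the whitened, covariate-adjusted design detected by pivoted QR
  (relative tolerance $10^{-9}$), not the nominal $K_\beta$: weighting plus
  smoothing can induce rank deficiency. The reduction, when it happens, is
  recorded in the result's `notes`.
* **Overparametrisation guard.** If $K_\beta > m$ the basis is reduced to
  the largest valid count $\le m$ (odd for Fourier, $\ge$ order for
  B-splines) and the reduction recorded; regions smaller than the spline
  order are errors.
* **Monomorphic and missing genotypes.** Missing dosages are mean-imputed
  per variant (MAF-preserving) before MAF computation; columns are
  re-polarised so dosages count the minor allele in the analysed sample; and
  monomorphic columns are dropped with a warning.

## What the synthetic data emulate — and what they do not

The simulation module stands in for the mini-exome genotype panels on which
the method's operating characteristics were originally established (those
panels, like the cohort data, are access-controlled). It emulates:

* an exome-like site-frequency spectrum: population MAFs from a truncated
  $\mathrm{Beta}(0.2, 2)$, strongly rare-skewed, bounded below by $1/(2n)$;
* region pre-selection: panels of 40 regions with 30–60 polymorphic variants
  and at least 10 rare variants (MAF $\le 0.03$) each;
* family structure: nuclear families (2 founders, 4 offspring) with
  genotypes propagated by Mendelian gene-dropping and $R$ the exact pedigree
  relationship matrix, block-diagonal by family;
* the trait model $y \sim N(G\beta,\; h^2 R + (1-h^2) I)$ with $h^2 = 0.29$,
  and the published effect-size laws
  $|\beta_j| = \log(s)\,|\log_{10}\mathrm{MAF}_j|/2$ and
  $|\beta_j| = s/\sqrt{2\,\mathrm{MAF}_j(1-\mathrm{MAF}_j)}$ (the second is
  the equal-variance-explained reading of the printed formula, consistent
  with $\mathrm{Var}(G_j) = 2\,\mathrm{MAF}_j(1-\mathrm{MAF}_j)$).

It does **not** emulate linkage disequilibrium (sites are independent),
genotyping error, non-normal traits, or real exome gene structure. Passing
calibration and power-ordering tests on these data therefore demonstrates
the statistical correctness of the machinery under the stated model, not
performance on any particular real cohort; cohort-specific gene-level P
values are outside what synthetic data can reproduce.

Two further simulation conventions: when the proportion of same-direction
effects times the causal count is non-integer, the positive count is rounded
to nearest and assigned to a random subset; the causal set itself is a
simple random sample of the pool (rare-only or all variants).

## Experiment design and problem sizes

`run_type1()` and `run_power()` process replicates in bulk: the relationship
matrix is eigendecomposed once, the trait Cholesky factor and the rotated
per-region designs are cached, and family replicates refit the null model by
profiled REML exactly as `flm_test()` would (a test verifies the bulk engine
against the one-call path replicate by replicate). The shipped experiments
use $n \approx 700$ (the historical sample size), panels of 40 regions,
$10^4$–$10^5$ null replicates for type-I error, 200 replicates for
heritability recovery, and 2000 replicates per power scenario — sizes chosen
so the full suite runs comfortably on a laptop while keeping Monte-Carlo
error well below the effects being measured. Power experiments default to a
significance threshold of $10^{-3}$: orderings among weight settings are
threshold-robust, and 2000 replicates cannot resolve the exome-wide
$2.5\times10^{-6}$ tail meaningfully (that threshold remains available via
`threshold =`).

## Known limitations

* Binary traits, score/likelihood-ratio tests, multiple random effects and
  sparse-kinship shortcuts are out of scope.
* Adaptive knot placement is not implemented; knots are uniform, which is
  known to cost some power for the B-spline family relative to optimised
  knots.
* The beta-smooth-only model is the default (no genotype smoothing); full
  smoothing with distinct bases is supported but requires
  $m \ge K_G$ with a well-conditioned $\Phi$.
* Weights are frequency-based only; annotation-based weights can be supplied
  manually via `weight_spec("custom")`.

## A worked example

```{r example}
set.seed(2)
fam <- simulate_families(n_families = 100, m = 40, min_rare = 10)
y <- simulate_trait(fam$region, beta = NULL, h2 = 0.29, R = fam$R)
dat <- phenotype_data(y, ids = fam$pedigree$id)
fit <- fit_null(dat, fam$R)
fit
flm_test(fam$region, dat, fit,
         effect_spec = basis_spec("bspline", 15),
         weights = weight_spec("beta", 1, 25))
```
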