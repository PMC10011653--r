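---
title: "Models and methods in mrflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mrflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrflow)
```

# The two-sample MR model

For variant $j$, let $\beta_{Xj}$ be its additive effect on the exposure and
$\Gamma_j$ its effect on the outcome, estimated in two non-overlapping
samples with standard errors $\sigma_{Xj}$, $\sigma_{Yj}$. Under the
instrumental-variable assumptions (relevance, exchangeability, exclusion
restriction) the structural model is

$$\Gamma_j = \theta\,\beta_{Xj} + \alpha_j,$$

where $\theta$ is the causal effect (a log odds ratio when the outcome is
binary) and $\alpha_j$ is variant $j$'s direct (horizontally pleiotropic)
effect, zero for a valid instrument. Every estimator in the package is a way
of pooling the per-variant Wald ratios $\hat\theta_j =
\hat\beta_{Yj}/\hat\beta_{Xj}$ (first-order SE
$\sigma_{Yj}/|\hat\beta_{Xj}|$) that is robust to different patterns of
$\alpha_j$:

* **IVW** assumes $\alpha_j \equiv 0$ and is the inverse-variance weighted
  mean, equivalently the zero-intercept weighted regression of
  $\hat\beta_Y$ on $\hat\beta_X$ with weights $1/\sigma_{Yj}^2$.
* **MR-Egger** frees the intercept: under the InSIDE assumption
  (pleiotropy independent of instrument strength) the slope remains a causal
  estimate and the intercept estimates the mean directional pleiotropy.
* **Simple / weighted median** are consistent when half the instruments
  (half the weight) are valid.
* **MR-PRESSO** tests the residual sum of squares of the IVW fit against a
  simulated no-pleiotropy distribution, flags per-variant outliers, and
  re-estimates after their removal.
* **Multivariable MR** regresses $\hat\beta_Y$ jointly on $K$ exposures'
  beta columns, giving each exposure's direct effect conditional on the
  others; **MR-Lasso** adds one $L_1$-penalized intercept per variant so
  invalid instruments select themselves out.

Wald-ratio standard errors use the first-order delta method only; the
second-order term (of relative size $\sigma_X^2/\beta_X^2 = 1/F_j$) is
omitted, which is standard and negligible for the strong instruments
($F_j > 10$) the selection stage enforces.

# Tunable parameters

| Parameter | Default | Rationale |
|---|---|---|
| significance threshold | $5\times10^{-8}$ | genome-wide significance convention |
| clumping $r^2$ / window | 0.001 / 1,000 kb | strict independence for summary-level MR |
| palindrome EAF window | 0.08 around 0.5 | A/T and C/G variants with frequency in [0.42, 0.58] carry too little frequency information to resolve strand; outside the band, frequency concordance resolves them |
| IVW model | `auto` | multiplicative random-effects scaling $\max(1,\sqrt{Q/(J-1)})$ applied when the Cochran Q test rejects at 0.05, mirroring the usual "heterogeneity present, use random effects" decision |
| median bootstrap | 1,000 replicates | parametric bootstrap resampling both $\hat\beta_X$ and $\hat\beta_Y$; SE stable to ~3% at this size |
| PRESSO `n_sim` / outlier $\alpha$ | 1,000 / 0.05 (Bonferroni-adjusted) | conventions of the original estimator |
| MR-Lasso grid | 50 log-spaced $\lambda$, from $1.05\max_j w_j\lvert r_j\rvert$ (all intercepts zero) down 4 decades | spans the path from all-valid to saturated |

The random-effects model is *multiplicative* (residual-variance scaling,
floored at 1); an additive between-variant variance component is not
implemented. Exposure order matters in multivariable runs: MVMR-Egger
orients every variant so its *first* exposure beta is non-negative, so the
first listed exposure is the orientation anchor and is part of the analysis
configuration.

## MR-Lasso tuning

Along the descending $\lambda$ path, variants whose penalized intercept is
exactly zero form the valid set. The penalty is chosen by a heterogeneity
stopping rule: scanning from the fully-penalized end (everything valid)
downward, the first $\lambda$ whose valid-set Cochran Q falls below the 0.05
chi-square critical value for its degrees of freedom is selected — i.e. the
largest penalty, hence the largest valid set, that is statistically
homogeneous. If no $\lambda$ qualifies (with at least $K+2$ valid variants),
the $\lambda$ minimizing Q is used. The reported estimate is the plain
multivariable IVW fit restricted to the valid set. The penalized problem is
solved by alternating exact updates (soft-threshold for the intercepts, WLS
for the slopes), warm-started along the path, to a parameter-change
tolerance of $10^{-8}$ with at most 10,000 sweeps.

# The synthetic-data generator

`simulate_univariable()` and `simulate_mvmr()` emulate the summary
statistics of large biobank-scale GWAS: allele frequencies uniform on
(0.05, 0.95), standard errors from the unit-variance-trait approximation
$\sigma \approx 1/\sqrt{2np(1-p)}$, true exposure effects scaled so the
instruments jointly explain a target $R^2$, outcome effects
$\theta^\top\beta_X + \alpha$, and independent Gaussian sampling noise in
the two samples (the non-overlapping two-sample design). Pleiotropy
$\alpha$ can be absent, balanced (zero-mean), directional (nonzero mean),
or planted outliers specified in units of the variant's outcome SE.

The default operating point mirrors a published analysis scale: 128
instruments, $R^2 = 0.139$, $\theta = \ln 1.069$, exposure sample 659,316,
outcome sample 256,896; a two-exposure variant uses 829 instruments with
direct effects $\ln 1.080$ and $\ln 1.189$, exposure-effect correlation
0.4, and a second-exposure $R^2$ of 0.06 — chosen once as the realistic
variance explained by genome-wide-significant variants for an
anthropometric trait in the largest available meta-analyses.

Two deliberate stylizations:

* Univariable per-variant $R^2$ contributions are uniform on
  $[0.25, 1.75]\times$ the mean rather than Gaussian, so *every* generated
  instrument clears genome-wide significance — the generator emulates an
  already-selected instrument set (as published instrument tables are),
  not the selection process itself, and so avoids winner's-curse artifacts.
* Effect alleles are reported aligned to the exposure-increasing direction
  (all true $\beta_X > 0$), the common convention for instrument tables.
  This makes the generating frame coincide with the Egger orientation
  frame; without it, re-orienting variants scrambles a directional
  pleiotropy mean into a balanced one and the Egger intercept has no
  well-defined target.

What the generator does **not** model: LD between instruments (clumping
tests use separately constructed block panels), sample overlap, winner's
curse, binary-trait effective-sample-size corrections (log-odds effects are
treated with the quantitative-trait SE approximation, and the
$2p(1-p)\beta^2$ variance-explained formula is the standardized-trait
approximation applied to log-odds betas), population stratification, and
allele-frequency differences between studies. Passing recovery tests on
these simulations therefore demonstrates correctness of the estimators
under the stated model, not robustness to those real-data complications.

# Numerical choices and degenerate inputs

* All weighted regressions solve explicit normal equations
  ($X^\top W X\,\hat\beta = X^\top W y$); the test suite cross-checks them
  against independent `lm()` fits to $10^{-10}$.
* Clumping ties on p-value break by lexicographic rsID, making the greedy
  selection invariant to input order.
* The weighted median uses centred cumulative weights
  $s_j = \sum_{i\le j} w_i - w_j/2$ with linear interpolation, which
  reduces exactly to the mean-of-central-pair simple median under equal
  weights.
* A single-variant IVW call falls back to the Wald ratio; zero exposure
  betas are excluded from ratio-based estimators with a message; rank
  deficiency in multivariable fits is an error naming the exposures, and
  exposure-beta correlations above 0.98 warn.
* Generated p-values are floored at the smallest positive double so
  extremely strong instruments survive the record validation p ∈ (0, 1].
* Simulation reproducibility: each generation stage draws from a sub-seed
  derived deterministically from the base seed (kept below $2^{31}$), so a
  dataset is reproduced exactly from its `simulation_truth`; bootstrap and
  PRESSO streams restore the caller's RNG state.

# Validation problem sizes

The shipped tests validate oracle equivalence on 50 random fixtures
($J \le 50$); univariable recovery and CI coverage on 200 replicates of the
128-instrument scenario; multivariable recovery on 200 replicates at
$J = 829$; Q and PRESSO calibration on 1,000 null replicates (PRESSO with
200 simulations per replicate); outlier detection on 100 replicates with a
planted 10-SE pleiotropic variant (and 100 clean replicates); and MR-Lasso
exclusion of 3 planted invalid instruments among 30 over 100 replicates.
These sizes give Monte-Carlo standard errors small enough for the stated
acceptance bands while keeping the whole suite to a few minutes.

# Known limitations

**Weak-instrument attenuation.** Because observed exposure betas carry
sampling noise, regression-dilution biases IVW-type estimates toward the
null by a factor $\approx 1/(1 + 1/\bar F)$, where
$\bar F = nR^2/J$ is the mean per-instrument strength — a property of the
estimator, not an implementation artifact. At the univariable operating
point ($\bar F \approx 840$) this is $\sim 0.1\%$ of $\theta$ and
undetectable. For a multivariable adjustment exposure with realistic
strength ($J = 829$, $n = 681{,}275$, $R^2 = 0.06$, $\bar F \approx 49$)
the attenuation is $\sim 2\%$ of its direct effect — measured at $-0.0037$
on $\theta_2 = 0.173$ over 200 replicates, several Monte-Carlo SEs from
zero. The bias depends on $(J, n, R^2)$ only, so no realistic
configuration of the generator removes it; recovering the adjustment
exposure to within 2 Monte-Carlo SEs at these sizes would require a
bias-corrected estimator, which the package intentionally does not
implement (the plain WLS forms are the methods under study). The primary
exposure's recovery is unaffected at its larger $\bar F$.

**Other limitations.** No Steiger direction filtering, mode-based
estimators, additive random-effects IVW, conditional F statistics for
MVMR, or proxy-variant lookup; the LD panel is injected rather than
computed from genotypes; exact reproduction of any published instrument
count depends on the original reference panel, which such publications
rarely name.
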