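---
title: "Calibrating diatom-based transfer functions for total phosphorus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating diatom-based transfer functions for total phosphorus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Pelagic phytoplankton — diatoms above all, because their silica valves
persist in sediments — integrate water-quality conditions and can be
calibrated as quantitative indicators. Given a *training set* of paired
observations (a site-by-taxon abundance matrix and the water-quality
measurements taken with it), one can estimate each taxon's position along a
nutrient gradient and then invert the relationship: infer the nutrient
concentration from an assemblage alone, including fossil assemblages in a
dated sediment core. `phytocal` implements that whole workflow for a total
phosphorus (TP) gradient: environmental screening, per-taxon response
coefficients, the weighted-averaging (WA) transfer function with
cross-validation, spatial-autocorrelation stress tests, constrained
ordination with variance partitioning, and downcore reconstruction
diagnostics — together with a synthetic-data module that generates all of
these inputs with known truth, so every stage is testable without any
external database.

# Models and their assumptions

## Taxon responses

The central ecological assumption is that taxa respond *unimodally* along
the (transformed) gradient: taxon $k$ has expected abundance

$$\mu_k(x) = A_k \exp\!\left(-\frac{(x - u_k)^2}{2 t_k^2}\right),$$

with optimum $u_k$, tolerance (niche breadth) $t_k$ and maximal abundance
$A_k$. Three estimators of a taxon's position are reported side by side:

* **linear** — the sign of the OLS slope, reported only when the Pearson
  correlation is significant at $P < 0.05$ (otherwise `0`);
* **Gaussian** — a quadratic in $x$ on a log link (the Gaussian-logit
  response model); the optimum is $-b_1/(2 b_2)$ when the curvature is
  negative, otherwise the gradient boundary with the larger fitted value,
  always clipped to the observed range. A generic smoother would serve too,
  but the quadratic-logit form is the standard unimodal response model and
  yields a closed-form optimum. The fit is declared better than linear by a
  paired *t*-test on the absolute residuals of the two fits at $P < 0.05$;
* **weighted averaging** — $u_k = \sum_i y_{ik} x_i / \sum_i y_{ik}$, the
  abundance-weighted mean of the gradient where the taxon occurs.

Optima are additionally rescaled onto the observed gradient range as
integer 0–10 *indicator values* (rounded half-up), and per-taxon season and
lake specificity scores are tenths of the taxon's total abundance falling
in each category. Taxa qualify for coefficients when they occur in strictly
more than 5 samples, and for the smoother-based tests below when they occur
in 10 or more.

Whether a taxon responds to TP *at all* — linearly, unimodally or skewed —
is tested non-parametrically: a penalized-spline GAM (basis dimension
$k = 5$, REML smoothness selection, via **mgcv**) of abundance on TP is
compared with 199 Monte-Carlo permutations of TP across samples, scoring
the deviance explained; $p = (1 + \#\{D^\ast \ge D\}) / (n_{\mathrm{perm}} + 1)$.
The *unique* TP effect given a confounded covariate (alkalinity is the
canonical one) uses the added deviance of a TP smooth over a
covariate-only model, permuting TP while the covariate stays fixed.

## The transfer function

WA regression with inverse deshrinking, the work-horse calibration model of
quantitative paleolimnology:

1. optima $u_k$ and tolerances $t_k$ as abundance-weighted moments of the
   gradient (relative-abundance basis; log\(_{10}\)-TP gradient);
2. initial estimates $\hat x^{(0)}_i = \sum_k w_{ik} u_k / \sum_k w_{ik}$
   with $w_{ik} = y_{ik}$, or $y_{ik}/t_k^2$ under tolerance downweighting
   (the default — broad-niche taxa carry less information);
3. averaging twice shrinks the range, so the observed gradient is
   regressed on the initial estimates (*inverse deshrinking*) and
   predictions are $b_0 + b_1 \hat x^{(0)}$.

Skill is reported apparent and leave-one-out: the jackknife refits the full
pipeline without each sample and predicts it, giving $r^2_{\mathrm{jack}}$
and RMSEP in log-TP units. The modern analog technique (MAT; unweighted
mean TP of the $k = 5$ nearest training assemblages under squared chord
distance, the discipline's default dissimilarity) is provided as a
comparator, and every prediction carries a *coverage* value — the share of
the sample's abundance belonging to modelled taxa — so fossil applications
can flag poor taxonomic overlap instead of silently renormalizing it away.

Defaults mirror the standard final configuration: tolerance downweighting
on, inverse deshrinking, no transformation of the taxonomic data
(`species_transform = "none"`; square-root and log1p are exposed as
options, since practice varies), no removal of rare taxa. Classical
deshrinking and WA-PLS are deliberately out of scope.

## Spatial stress tests

Samples a few tens of kilometres apart share both water masses and
assemblages; this lack of independence inflates apparent cross-validated
skill. Two diagnostics address it.

**Neighbourhood deletion (`rne_test`).** During leave-one-out
cross-validation, training sites are deleted (1) within a geographic radius
of the test site, (2) the same *count* of sites nearest in gradient value,
and (3) the same count at random. Pooled predictions give one $r^2$ per
radius per scheme; at radius 0 all three equal the plain jackknife. A
geographic curve falling below the random curve is the signature of
spatial autocorrelation; the count-matching guarantees the three schemes
are always comparable.

**Spatially structured randomization (`random_tf_test`).** An empirical
semivariogram of the gradient is fitted with a theoretical model
(exponential by default; weighted least squares with Cressie weights
$n_h/\gamma_{\mathrm{model}}^2$, parameters bounded nonnegative, a coarse
grid search as fallback), and the gradient is repeatedly replaced by
unconditional Gaussian random fields with that variogram — same spatial
structure, same mean and marginal variance, no relation to the species.
The WA model is refit to each null field and its apparent $r^2$ recorded
(a cross-validated mode exists but is much slower; the apparent statistic
is the conventional choice for this test). The model is significant when
its actual $r^2$ exceeds 95% of the simulations; the percentile among
simulations is reported.

## Ordination and variance partitioning

Redundancy analysis is implemented directly (species matrix
column-centred, *not* standardized, no Hellinger pre-transformation by
default though one is offered; predictors standardized; PCA of the fitted
values gives constrained axes, PCA of the residuals unconstrained ones) so
that the centring statistics can be retained for passive projection.
Variable selection uses *marginal* permutation tests — each variable's
single-variable constrained fraction against permutations of its rows.
Variance partitioning reports a focal variable's **total** fraction (RDA
on it alone) and **unique** fraction (partial RDA after residualizing on
the conditioners), both relative to the *original* total species variance.
Fossil samples are projected passively: intersected with the training
taxa, renormalized over the intersection, centred with the *training*
means, and multiplied by the training species scores. Site scores are
weighted sums of species scores, which is exactly the convention that
makes this projection consistent. `vegan::rda` is used as an independent
cross-check in the test suite, never as the implementation.

## Downcore diagnostics

`reconstruct_core` applies the WA model per interval, back-transforms
log-TP to µg/L, and draws an error band of ± the jackknife RMSEP *on the
log scale*, back-transformed (hence asymmetric in µg/L — the internally
consistent choice given that RMSEP is estimated in log units). Two
reconstruction-relevance diagnostics follow: the Pearson correlation
between the reconstruction and the core's first unconstrained PCA axis
(signed value returned; the axis sign is arbitrary, so the magnitude is
reported alongside), and $\lambda_R/\lambda_P$ — first-axis variance of an
RDA of the core constrained to the reconstruction, over the first-axis
variance of an unconstrained PCA. Because a constrained axis can never
beat the leading eigenvector, $\lambda_R \le \lambda_P$ and the ratio lies
in $(0, 1]$. Note the inherent circularity: the reconstruction is itself
derived from the same species data; the ratio is reported as defined,
without correction.

# The synthetic-data module

The generator reproduces the *statistical* structure the calibration
assumes, with known truth:

* **Environmental fields** are Gaussian random fields simulated by Cholesky
  factorization of the full site covariance (exact and simple at a few
  thousand sites), with exponential, spherical or Gaussian covariance.
  Cross-variable correlation is induced by linearly mixing independent
  standardized fields through the symmetric square root of the target
  correlation matrix: marginal variances are then exact, marginal
  variogram *shapes* only approximate when variables have different
  ranges.
* **Assemblages** are multinomial draws (400 valves per sample — the
  conventional diatom count; the source literature is silent on count
  totals) from the Gaussian-response expected proportions; Poisson and
  negative-binomial noise serve absolute-abundance studies.
* **`simulate_benchmark`** fixes the reference study conditions: 500 sites
  over a 1000 × 500 km planar domain (planar coordinates keep the
  null-model math exact; a lon/lat mode uses great-circle distances), an
  exponential log₁₀-TP field (mean 0.8 ≈ 6 µg/L, sill 0.25, nugget 0.02,
  range 100 km — about two orders of magnitude of TP across sites), 100
  taxa with optima spanning the gradient and tolerances 0.15–0.5.
* **`simulate_basin_training`** emulates a large-lakes monitoring design:
  five site clusters whose mean log₁₀-TP runs from oligotrophic (0.35) to
  eutrophic (1.55) with a short-range within-basin field. Geography then
  genuinely predicts TP, which is the situation the neighbourhood-deletion
  diagnostic must expose; scrambling the TP values across sites
  (`structured = FALSE`) is the negative control.
* **`enrichment_scenario` / `simulate_core`** build a 26-interval
  stratigraphy (1707–2010) with a smooth mid-20th-century enrichment
  excursion over a low baseline, drawn from the same species pool as the
  training set so analogs exist.

What the generator does **not** emulate: seasonality and succession,
taxon interactions, taphonomy and differential valve preservation,
basin-specific assemblages beyond the shared TP response, and secular
changes in taxonomy or counting effort. Passing tests therefore show that
the *algorithms* behave as specified under the model's own assumptions —
not that any particular real training set satisfies those assumptions.

# Numerical choices

* Log transforms are base 10 throughout; variables with zero minima get a
  configurable offset (default: half the smallest positive observed value,
  announced with a message) — monitoring tables routinely contain zero
  chlorophyll or nitrate values, so the policy is explicit rather than
  silent.
* Nutrient ratios are molar, from mass concentrations via the molar
  masses of N, P and Si, with input units configurable (defaults: mg/L
  for NOx and silica, µg/L for TP). A zero denominator yields a missing
  ratio with a warning, never a failure.
* Tolerance floor: taxa with near-zero tolerance (single-occurrence taxa)
  would dominate downweighted averages, so tolerances below
  $\mathrm{sd}(x)/10$ are raised to that floor.
* Indicator values round half *up* (`floor(x + 0.5)`), matching the
  integer presentation convention; `base::round` would round half to even.
* Permutation p-values always use the $+1$ correction, so $p > 0$.
* Bonferroni correction in the correlation screen runs over all unordered
  variable pairs.
* MAT includes every analog tied at the $k$-th distance (within 1e-12)
  and reports how many were used.
* Eigenvalues below $10^{-12}$ of the total inertia are truncated from
  ordination output, so axis counts reflect actual rank.
* All stochastic entry points take a `seed` argument, restore the
  caller's RNG state, and are bit-reproducible under a fixed seed.

# Problem sizes in the test suite

The suite validates oracle equivalence on ≤10 × 5 toys at 1e-10; parameter
recovery and skill on the full 500 × 100 benchmark; null calibration with
500 linear replicates, 100 GAM taxa × 99 permutations, 200 RDA-permutation
replicates, and 50 randomization meta-replicates × 99 simulations
(Kolmogorov–Smirnov uniformity at α = 0.01); the autocorrelation signature
on the 150-site five-basin design; and end-to-end reconstruction at 300
sites × 60 taxa. These sizes keep the whole suite to a few minutes while
leaving every stochastic check comfortable statistical margin.

# Known limitations

* $\mathrm{RMSEP}_{\mathrm{jack}} \ge \mathrm{RMSE}_{\mathrm{apparent}}$
  is an expectation-level regularity, not a theorem: at a few dozen
  samples, individual datasets can invert it by a few thousandths. At
  calibration scale (hundreds of samples) it holds with comfortable
  margin.
* WA optima of taxa whose true optima lie beyond the sampled gradient are
  biased toward the gradient centre — an inherent property of weighted
  averaging, visible in the benchmark as mild edge shrinkage.
* The linear-mixing construction for correlated fields trades marginal
  variogram exactness for simplicity; variogram-sensitive work should use
  uncorrelated fields or equal ranges.
* $\lambda_R/\lambda_P$ and the reconstruction-PCA correlation reuse the
  species data that produced the reconstruction; they measure coherence,
  not independent validation.

# A minimal session

```{r}
library(phytocal)

b <- simulate_benchmark(seed = 1)
cv <- wa_jackknife(b$abundance, b$x)
cv

rt <- random_tf_test(b$abundance, b$x, b$coords, n_sim = 999, seed = 12)
rt

core <- simulate_core(b$pool, enrichment_scenario(), seed = 52)
rec <- reconstruct_core(cv$model, core, cv)
lambda_ratio(core, rec$ditp)
```
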