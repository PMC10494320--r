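---
title: "Models and methods in paleokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in paleokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleokit)
```

paleokit bundles the quantitative methods that a multi-proxy Miocene
paleosite study leans on: cosmogenic-nuclide chronology, stable-isotope
paleoecology, geometric morphometrics with cross-validated classification,
allometric body-mass estimation, and Bayesian posterior-tree
summarization.  This vignette explains each model, its assumptions, the
parameters that matter, and the numerical choices the implementation
makes; it also states what the seeded synthetic-data generators do and do
not emulate.

## Authigenic ¹⁰Be/⁹Be depositional dating

Meteoric ¹⁰Be adsorbs onto sediment together with stable ⁹Be; after
deposition the ratio decays as \(N(t) = N_0 e^{-\lambda t}\) with
\(\lambda = \ln 2 / T_{1/2}\) and \(T_{1/2} = 1.387 \pm 0.012\) Ma.
Dating therefore reduces to estimating the initial ratio \(N_0\) from
modern sediments in analogous depositional environments, and inverting
the decay law:

\[ t = \frac{1}{\lambda}\ln\frac{N_0}{N}, \qquad
   \sigma_t^2 = \frac{1}{\lambda^2}\left[\Big(\frac{\sigma_N}{N}\Big)^2 +
   \Big(\frac{\sigma_{N_0}}{N_0}\Big)^2\right]
   + t^2\Big(\frac{\sigma_\lambda}{\lambda}\Big)^2 . \]

Design choices:

* **The half-life term in \(\sigma_t\) is off by default.**  Published
  age tables of this kind appear measurement-dominated; the term is
  available behind `include_lambda_sigma = TRUE`.
* **A measured ratio above \(N_0\) yields a flagged negative age**
  (`future_age`), not an error, so modern or contaminated samples survive
  batch runs.
* **Ratios are stored unscaled.**  Printed tables mix ×10⁻⁸ and ×10⁻¹³
  display conventions; the CSV schema declares its columns in units of
  10⁻⁸ (`ratio_1e8`) and the reader rescales once, at the boundary.
* **Initial ratios combine by inverse-variance weighting** with
  \(\sigma = (\sum \sigma_i^{-2})^{-1/2}\) and no scatter (MSWD)
  inflation.

Because one fixed \(\lambda\) links every scenario, re-dating a sample
under a different \(N_0\) shifts its age by the constant
\((1/\lambda)\ln(N_{0,b}/N_{0,a})\); for the packaged age table the
estuarine-to-source shift is 2.083 Ma, and the table reproduces it to
within the 0.005 Ma rounding of the printed inputs.  The packaged
fixture corrects two typographic slips in its source (a decade error in
one header ratio and one mis-assigned scenario cell); both are documented
in `?mazamba_authigenic_ages`.

## ²⁶Al/¹⁰Be burial dating

In-situ ¹⁰Be and ²⁶Al accumulate in quartz under a steady denudation rate
\(\varepsilon\); each pathway \(j\) (spallation, slow and fast muons)
contributes at the surface

\[ N_i = \sum_j \frac{P_{ij} S_j}{\lambda_i + \rho\varepsilon/\Lambda_j}. \]

After burial the inherited inventory decays — ²⁶Al (half-life 0.705 Ma)
about twice as fast as ¹⁰Be — while muons keep producing at depth.  The
package solves the two-equation system for (burial duration,
pre-burial denudation) by a 1-D bracketing root-find on the duration via
the two-nuclide ratio (monotone in \(t\)), recovering \(\varepsilon\)
from the ¹⁰Be equation at each trial duration.  This is slower than a
2-D Newton iteration but cannot diverge, and failures produce an
explicit diagnostic with the achievable ratio range.

Key parameter choices, all configurable on `nuclide_system()`:

* SLHL ¹⁰Be spallation rate 4.03 at g⁻¹ a⁻¹; surface spallogenic
  ²⁶Al/¹⁰Be production ratio 6.61; spallation attenuation 160 g cm⁻².
* **Muon pathways are configuration, not constants**: slow/fast muon
  attenuation lengths 1500 and 4320 g cm⁻², rates 0.3% and 1.0% of each
  nuclide's spallation rate (total muogenic share ≈ 1.3%, a mid-range
  literature value).  Exact published burial ages depend on the exact
  muon parameter file used, which varies between laboratories; the
  package is therefore validated by forward/inverse round trips (recovery
  to 10⁻⁴ relative over \(t \in [0.1, 5]\) Ma,
  \(\varepsilon \in [10, 2000]\) m Ma⁻¹) rather than by reproducing any
  single published number.
* **Post-burial production is muogenic only by default**: metres of
  overburden attenuate the neutron flux by many orders of magnitude, and
  with `include_spallation = FALSE` the maximum model converges exactly
  to the minimum model as muon rates go to zero.  The depth history under
  steady post-burial denudation is linear, and the accumulation integral
  is evaluated by adaptive quadrature (relative tolerance 10⁻⁸; the
  closed form for linear depth serves as a test oracle).
* Spallation scaling uses the standard latitude/pressure polynomial
  scheme normalized at sea level/high latitude; muons are unscaled by
  default (`scale_muons` to override).  Rock density defaults to
  2.5 g cm⁻³.

The post-burial denudation rate is found by grid search on the coherence
of the durations of co-buried samples (summed squared normalized
residuals about their weighted mean).  A single sample gives an exactly
identified system at every candidate rate, so its misfit curve is
identically zero and the function warns; at least two samples are needed
to constrain the rate.  Uncertainties come from seeded Monte Carlo
perturbation of the measured concentrations (optionally the production
constants), reporting the SD of re-solved durations and the failure
count.

## Pedogenic-carbonate isotopes and the paleo-shade proxy

Summaries are the conventional ones (sample SD with \(n-1\); printed
"±" values in this literature are sample SDs, which the packaged table
confirms on recomputation).  Correlation is reported as squared Pearson
\(R^2\); stratigraphic trends are OLS slopes of value on height with
two-sided t-tests.

The woody-cover proxy first converts carbonate δ¹³C to organic-matter
δ¹³C by subtracting the carbonate–organic enrichment (documented range
13.5–17.0‰; default 15.25‰, the midpoint), then applies the empirical
sine-squared paleo-shade function
\(f = \sin^2(-1.06688 - 0.08538\,\delta^{13}C_{om})\), clipped to [0, 1].
The functional form is isolated behind `woody_cover()` so alternates can
be swapped in.  The inference is sensitive to the enrichment choice:
at δ¹³C = −7.3‰ the cover estimate is ≥ 50% for enrichment ≥ 15‰ but
drops below 50% at 13.5‰ — the tests document this sensitivity rather
than hiding it.

## 2D outline and 3D landmark morphometrics

The 2D pipeline runs, in order: **(1) GPA, (2) EFT, (3) PCA.**

* `trace_outline()` extracts the boundary of the unique 4-connected
  foreground component by Moore-neighbour tracing, starting at the
  topmost-then-leftmost boundary pixel, counterclockwise.  Start point
  and orientation are part of the contract because elliptical Fourier
  coefficients depend on both.  One 3-point moving-average pass over the
  closed chain (default) removes the raster staircase, which would
  otherwise inflate a smooth perimeter by about 5%.
* `resample_equidistant()` places k = 100 semilandmarks at equal
  arc-length spacing, preserving the first point.
* `gpa()` removes translation, scale (unit centroid size) and rotation
  (orthogonal Procrustes to the evolving consensus, reflections
  disallowed; convergence 10⁻¹⁰ or 100 iterations).
* `eft()` computes Kuhl–Giardina coefficients under the arc-length
  parameterization; harmonics are retained to > 99% cumulative power.
  No additional first-harmonic normalization is applied on top of the
  Procrustes scaling — that would double-normalize.
* `pca()` is covariance-matrix PCA (coefficients are commensurate after
  GPA scaling); components are kept to ≥ 90% cumulative variance, with
  the crossing component included.

Classification is a shared-covariance Gaussian discriminant
(`lda_fit()`), with priors proportional to class frequencies by default
and a uniform option — the original analyses do not state their choice.
A rank-deficient pooled covariance errors unless ridge regularization
(10⁻⁸ × trace/dims) is enabled.  Performance is assessed by
leave-group-out cross-validation: 200 random 80/20 splits (unstratified,
as "randomly assigned observations" implies; a stratified option
exists), pooled confusion matrix, mean accuracy and Cohen's κ.  Unknowns
are classified by posterior probabilities averaged over the repeats'
fitted models.

For 3D configurations, interior semilandmarks slide along their curve's
local tangent (central finite differences along the curve's index order;
endpoints fixed) by the tangential component of their deviation from the
consensus, re-superimposing after each sweep.  The Procrustes sum of
squares is non-increasing by construction — any step that would increase
it reverts and stops — and the loop ends at relative improvement
< 10⁻⁸ or 20 iterations.

## Allometric body mass

Masses regress on lengths on log₁₀–log₁₀ axes by OLS.  Back-transforming
the prediction \(10^{a + b\log_{10}L}\) estimates the median, not the
mean; the quasi-maximum-likelihood correction multiplies by
\(\exp(\tfrac12(\ln 10)^2\hat\sigma^2)\) — one factor per model, so
corrected/detransformed is constant across predictions, a contract the
tests assert.  Duan's smearing estimator is available as a
nonparametric alternative.  Both corrected and uncorrected values are
always reported, since the correction itself rests on lognormality.

The reference regression sample is a pluggable input table.  Printed
specimen masses are used only as consistency checks: the two published
(length, mass) pairs imply a log-log slope of 3.01, and their
corrected/detransformed ratios agree to 2 × 10⁻⁷ — both checked, never
hard-coded as coefficients.  Intervals default to the mean-response OLS
interval in log space, back-transformed; published intervals of this
kind are often of unclear type, so the type is explicit and
configurable (`type = "new"` for prediction intervals).

## Posterior-tree summarization

Burn-in drops the first ⌈fraction · n⌉ trees (25% of 100,000 retains
75,000).  Clades are **rooted** taxon subsets — the trees these tools
consume are rooted, time-calibrated — keyed by canonical sorted
tip-label strings.  The MCC tree is the **sampled** tree maximizing the
product of its clades' posterior frequencies (scored in log space; ties
break to the earliest index); no consensus topology is synthesized.
Node ages are summarized, per clade, across the sample trees containing
that clade, as the median plus the 95% HPD interval — the shortest
contiguous window over the sorted sample containing ⌈level · n⌉ points,
ties resolved to the smallest lower bound.  Non-ultrametric inputs are
summarized as root-to-node distances with a warning.

Effective sample sizes use \(n/(1 + 2\sum_k \rho_k)\) with Geyer's
initial positive-sequence truncation (sum consecutive autocorrelation
pairs while positive), which is deterministic and well-defined; a
constant trace is reported as ESS = n with a warning.

## Synthetic data: what it does and does not emulate

Every generator seeds the RNG explicitly, returns a `ground_truth`
manifest alongside the data, and regenerates identical output for an
identical seed.  The generators invert the package's own forward models:
ratio series from the decay law, quartz concentration pairs from the
burial forward model, carbonate tables from a bivariate normal with
chosen correlation, outline classes from perturbed Fourier coefficient
templates (optionally rasterized for the tracing pipeline), 3D
configurations with tangential noise that sliding can remove, log-log
allometric samples, and tree posteriors with a controlled clade-flip
probability and parent-respecting node-age jitter.

They deliberately do **not** emulate AMS counting statistics, adsorption
geochemistry, taphonomic outline damage, digitization error structure,
or a real fossilized-birth–death process.  Passing tests on synthetic
data therefore demonstrate that the algorithms are correct and invert
their own generating models at realistic noise levels — not that any
particular field dataset satisfies those models.

## Problem sizes and numerical settings

The test and acceptance runs use: 15-sample age tables; burial
round-trips over a 5 × 4 (duration × denudation) grid; 60 outlines per
class with 200 × 80/20 cross-validation repeats; allometric samples of
n = 200; tree samples of 25–900 topologies over 4–8 taxa with
brute-force scoring oracles; ESS traces of n = 10,000.  These sizes give
statistical headroom of at least 3σ on every stochastic assertion while
keeping a full run in the low minutes.  Root-finding tolerances are
10⁻⁶ Ma (burial durations), 10⁻¹⁰ (GPA consensus), 10⁻⁸ relative
(sliding and post-burial quadrature).

## Known limitations

* Burial solutions assume a single exposure–burial cycle (no
  inheritance from earlier cycles) and constant denudation in each
  phase.
* The paleo-shade proxy carries its calibration's scatter, which is not
  propagated; only the enrichment sensitivity is surfaced.
* LDA assumes shared class covariances; strongly heteroscedastic shape
  classes would need a quadratic rule the package does not provide.
* The MCC search is restricted to sampled topologies, as is standard;
  for very diffuse posteriors the best sampled tree can still have low
  credibility.
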