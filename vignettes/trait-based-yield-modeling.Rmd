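---
title: "Trait-based seed-yield modeling from UAV imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based seed-yield modeling from UAV imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grassyield)
```

## The problem

Seed yield in low-canopy perennial turfgrasses (the motivating crop is
buffalograss, *Buchloe dactyloides*) responds non-monotonically to nitrogen
fertilization: too little N limits vegetative development and source
capacity, too much promotes structural overgrowth at the expense of
reproductive allocation. Predicting plot seed yield from UAV imagery with
vegetation indices (VIs) alone works well within a season but transfers
poorly across seasons, because VIs absorb year-specific radiometry and
phenology. `grassyield` implements the alternative: retrieve two
physiologically interpretable traits from the imagery — plant height (PH,
cm), a structural/sink trait, and canopy nitrogen concentration (CNC, %
dry mass), a physiological/source trait — and predict yield through a
constrained quadratic response surface in those traits.

## The yield model

The coupled source–sink form multiplies a nitrogen (source) module and a
height (sink) module:

$$Y = (\delta_1 C + \delta_2 C^2)\,(\gamma_1 P + \gamma_2 P^2) + a$$

with $C$ the CNC, $P$ the plant height and $a$ a baseline yield. The
coefficient pairs are only identified up to the rescaling
$(\delta_i, \gamma_j) \to (k\delta_i, \gamma_j/k)$; fitting therefore fixes
$\gamma_1 = 1$ (`normalize_coupled()`), and recovery is judged on the
invariant products $\delta_i\gamma_j$.

The package's default working form is the *expanded* polynomial

$$Y = b_P P + b_{P^2} P^2 + b_C C + b_{C^2} C^2 + b_{PC}\,P C + a,$$

a quadratic surface with a single height-by-nitrogen interaction. Both
forms are implemented because they are not algebraically equivalent —
expanding the multiplicative form produces four cross terms
($CP, CP^2, C^2P, C^2P^2$), not one — and coefficient tables and
contribution partitions in this literature are reported in the expanded
form. The expanded form is fitted by ordinary least squares; the coupled
form by Levenberg–Marquardt nonlinear least squares (`minpack.lm`),
initialized from the OLS fit of the four separable product regressors and
restarted from five seeded jitters on failure.

Contribution partitioning (`contribution_rates()`) uses grouped
hierarchical partitioning (LMG): the explained sum of squares is
decomposed over the term groups $\{P, P^2\}$, $\{C, C^2\}$ and $\{PC\}$ by
averaging sequential increments over all $3! = 6$ group orderings,
implemented as a Shapley value over the $2^3$ subset regressions. Shares
are non-negative by construction and normalized to 100%. The method tag is
recorded in the report so alternative decompositions could be added; the
direction of the interaction effect is reported from the sign of $b_{PC}$.

## From imagery to traits

* **Plant height.** Per pixel, PH = DSM − DEM, with the DSM bilinearly
  resampled onto the DEM grid when the grids differ, and negative
  differences clipped to zero (the DEM is a bare-ground reference, so
  negative canopy height is noise). Rasters are in metres; plot summaries
  convert to cm, the field-ruler unit.
* **Soil masking.** Background pixels are removed by thresholding NDVI
  with Otsu's method: a 256-bin histogram of the finite NDVI values
  (clipped to $[-1, 1]$), cut at the bin edge maximizing the between-class
  variance. Exact ties — including the plateau that occurs when the
  soil and vegetation modes are separated by an empty gap — break toward
  the lower threshold, deterministically. A degenerate (single-valued)
  histogram is an error that suggests passing a manual threshold.
* **Vegetation indices.** NDVI, NDRE, EVI, GNDVI (the green NDVI, also
  written GDVI) and SAVI, computed per pixel from the five-band
  (B, G, R, RE, NIR) surface-reflectance stack. Pixels whose denominator
  magnitude falls below a guard (1e-6 for EVI, 1e-12 for the normalized
  ratios) are missing, never infinite, and are excluded from plot means.
* **Plot aggregation.** A pixel belongs to a plot if its center lies
  inside the plot polygon (pixel-center convention); plot means are taken
  over vegetation pixels only, consistent with masking the soil background.

CNC is not directly observable from five bands, so it is estimated by
random-forest regression (`ranger`) of field-measured CNC on the five
plot-mean VIs. Two stage-specific models are fitted — vegetative
(tillering + jointing) and reproductive (heading + filling) — because the
physiological shift after heading changes the N–spectrum relationship.
Hyperparameters default to a deliberately compact forest (50 trees, depth
6, minimum leaf 3, $\sqrt p$ feature subsampling, seed 42) and are
overridable; features are matched by name, never position, so band-order
bugs fail loudly. Forest-mean predictions are bounded by the
training-target range, a property the tests assert.

## The calibration convention

Each plot has four stage-wise trait observations but a single final seed
yield. The package's convention, used identically by the synthetic-data
generator and by the default calibration, is to *pool* the stages: the
plot-level predictor is the stage-mean trait pair, one calibration row per
plot. Stacking the four stage rows against the same plot yield
(`calibration_table(pool = "stack")`) is also available, but it cannot be
the generative convention: if yield were a fixed function of a plot-level
trait pair, regressing it on stage-wise traits that vary widely within the
plot would attenuate every coefficient, so no stacked fit could recover
the generating surface even without noise. Pooling keeps the generator and
the estimator coherent (the noiseless round trip is exact, and the tests
assert it) at the cost of fewer calibration rows.

## What the synthetic generator emulates

The generator reproduces the design and the qualitative regimes of a
three-year, seven-N-rate (0–210 kg N/ha), three-block randomized complete
block seed-production trial with four phenological stages:

* **PH trajectory**: saturating (Michaelis–Menten) in N with
  half-saturation 90 kg/ha, scaled by stage asymptotes 8/14/22/26 cm —
  height rises over the season and with N.
* **CNC trajectory**: saturating in N (base 0.6%, max +1.6%,
  half-saturation 80 kg/ha) damped by stage-decline factors
  1/0.9/0.75/0.6 — CNC peaks at tillering and declines, while still
  increasing with N at every stage.
* **Year effects**: multiplicative trait gains per year (PH 1.00/0.92/1.06,
  CNC 1.00/1.05/0.94) and per-year multiplicative band gains on the
  rendered reflectance (1.00/0.95/1.10 by default), emulating
  between-season growth and radiometric differences. The held-out third
  year therefore combines a trait shift with a 10% radiometric shift —
  the cross-year stress the trait-based model is meant to survive.
* **Within-treatment heterogeneity**: log-normal multiplicative gains per
  (year, block) (sd 0.08 on both traits) and per plot (sd 0.15 for PH,
  0.08 for CNC). Blocks are why an RCBD blocks; the plot-level microsite
  component represents soil heterogeneity within blocks. Height varies
  more plot-to-plot than tissue N in the field, hence the asymmetry. This
  heterogeneity is also what makes the six-coefficient surface
  identifiable from a 42-plot calibration set: without independent
  plot-level variation the (P, C) cloud collapses onto the one-dimensional
  curve traced by the N response, and the quadratic terms are unresolvable.
* **Observation noise**: Gaussian, sd 1 cm (PH), 0.05% (CNC), and yield
  noise with sd equal to 5% of the mean model yield, floored at zero.
* **Yield truth**: an expanded surface ($b_P = 193$, $b_{P^2} = -6$,
  $b_C = 1740$, $b_{C^2} = -450$, $b_{PC} = -60$, $a = -1350$ kg/ha) whose
  optimum sits near $P^* \approx 14$ cm, $C^* \approx 1.1\%$ — inside the
  trait ranges the N treatments produce — so expected yield over the N
  rates is hump-shaped with an interior peak and a clear decline at the
  top rates, driven largely by the negative interaction (simultaneous tall
  and N-rich canopies lose yield). The negative intercept is the local
  quadratic approximation's extrapolation artifact, not a physical
  baseline; all simulated yields are positive at the default conditions.

Scenes are rendered as five-band reflectance plus DSM/DEM rasters:
vegetation pixels are drawn inside each plot polygon at exactly the
requested cover fraction (cover grows with stage and N), carry a spectrum
interpolated between low-N and high-N grass endmembers indexed by the
plot's CNC (so NDRE rises strictly with CNC), and sit at DEM + true height
in the DSM; soil pixels carry a bright-soil spectrum and DSM = DEM
exactly. The endmember spectra are plausible grass/soil values, not fitted
to any particular sensor. Band gains multiply all bands; sensor noise is
additive truncated Gaussian.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about real data: no weather or soil-water dynamics (year
effects are reduced to multiplicative gains), no phenology-date model, no
bidirectional-reflectance or illumination geometry, no photogrammetric
reconstruction error structure (DSM noise is i.i.d. Gaussian), no spatial
autocorrelation within plots, and a CNC–spectrum link that is exactly
monotone by construction. In particular, the random forest's CNC skill on
these scenes is an upper bound on what a real chlorophyll-mediated,
stage-confounded link would give, and the cross-year comparison shows the
*direction* of the trait model's advantage, not its field magnitude.

## Evaluation

`agreement_metrics()` reports, with population (1/n) variances throughout:
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$; NRMSE $= \mathrm{RMSE}/\bar y
\times 100\%$; the Nash–Sutcliffe efficiency, which is the same formula as
that $R^2$ and is asserted identical on every report; and Lin's
concordance correlation coefficient in its standard form
$2 r \sigma_y \sigma_{\hat y} / (\sigma_y^2 + \sigma_{\hat y}^2 +
(\bar y - \bar{\hat y})^2)$, which penalizes bias as well as imprecision.
On validation data $1 - \mathrm{SSE}/\mathrm{SST}$ differs from the
squared Pearson correlation; the latter is reported separately
(`r2_pearson`) and clearly labelled. Note that $\mathrm{CCC} \le |r|$
always, a property the tests exercise.

The cross-year protocol fits everything (CNC forests, trait surface,
direct baseline) on the training years only and evaluates on the held-out
year, pooled and per stage. The direct baseline is a random forest on the
five VIs plus PH with the same hyperparameters as the CNC stage — the
conventional approach the trait model is compared against. Treatment
separation uses one-way ANOVA with Fisher's protected LSD: pairwise
comparisons on the pooled error mean square are attempted only when the F
test is significant at 5%, and compact letters are assigned by the
insert-and-absorb algorithm with groups ordered by decreasing mean.

## Numerical choices and degenerate inputs

* Otsu: 256 bins over the observed (clipped) range; ties to the lower
  edge; < 2 distinct finite values is an error, not a guess.
* EVI denominator guard 1e-6; guarded pixels are missing and excluded
  from means rather than propagated as infinities.
* Negative DSM − DEM clipped to 0; plot polygons with zero vegetation
  pixels raise an error rather than returning NaN means.
* Expanded fits require rank-6 designs and trait variation in both P and
  C; constant-trait designs raise an identifiability error.
* Coupled fits normalize $\gamma_1 = 1$; $\gamma_1 = 0$ cannot be
  normalized and is reported as such.
* LMG shares: if the model explains nothing (zero SSR) shares fall back
  to equal thirds rather than 0/0.
* All randomness flows through explicit seeds (`with_seed` restores the
  caller's RNG state); repeated calls with equal seeds are byte-identical.

## Problem sizes

Test and acceptance runs use deliberately compact instances chosen to keep
the full suite in the tens of seconds while leaving every mechanism
exercised: scenes are rendered at 0.25 m pixels (4 m plots, so roughly 250
pixels per plot) rather than the 3 cm native GSD the renderer defaults to;
VI oracle comparisons use $10^5$ random pixels; recovery studies use 20
seeded replicates of the 2-year, 42-plot trial; the cross-year
transferability comparison uses 10 seeded replicates of the full 3-year
trial. Single scenes at native resolution render in seconds and are
exercised through the same code path.

## Known limitations

The expanded and coupled forms are local quadratic approximations; they
extrapolate parabolically outside the trait ranges seen in calibration,
and the reported stationary point is only meaningful when it falls inside
those ranges (its Hessian classification is reported, not assumed to be a
maximum). The CNC estimator inherits the usual random-forest inability to
extrapolate beyond its training-target range — a safety property within
season, a bias under strong domain shift. LSD letters are unadjusted
pairwise comparisons gated by one F test; with many treatments they are
liberal relative to Tukey-style procedures, which is the standard
trade-off accepted in agronomic practice.
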