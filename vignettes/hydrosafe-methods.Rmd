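---
title: "Models and methods in hydrosafe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hydrosafe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrosafe)
```

hydrosafe infers drought-physiology traits of woody plants from three
kinds of observation — optical embolism detection during bench drying,
pressure–volume (PV) bench series, and field water-potential campaigns —
and links them to canopy damage through exhaustive GLM selection. This
vignette documents the underlying models, the estimator and default
choices that were genuinely open, and what the synthetic-data generators
do and do not emulate.

## The sigmoid vulnerability model

Percent embolism as a function of xylem water potential $\Psi$ (MPa) is

$$PE(\Psi) = 100 - \frac{100}{1 + e^{a(\Psi - b)}},$$

with $b$ the water potential at 50 % embolism (P50) and $a$ (MPa$^{-1}$,
negative) the sensitivity to declining water potential. The closed-form
inverse $\Psi_x = b + \log\{x/(100-x)\}/a$ yields P12 and P88. Both signs
are stored negative throughout: water potentials in living tissue are
tensions, and a physical curve must increase as $\Psi$ falls.

`fit_sigmoid()` minimizes squared deviations of cumulative percent
embolism from the model (Levenberg–Marquardt, with data-driven starting
values from the empirical 50 % crossing and the 20–80 % spread, plus up
to five deterministically jittered restarts). All points carry equal
weight. A trace that never spans below 20 % and above 80 % embolism
cannot pin both parameters and is flagged *poorly constrained* rather
than rejected.

### Estimating from an empirical CDF of events

An optical-vulnerability trace is not an arbitrary dose–response data
set: it is the empirical CDF of discrete pixel events, evaluated at the
frames' water potentials. Two refinements follow for traces of class
`embolism_trace` (and only for those — plain `(psi, cum_pct)` model
curves are fitted raw, and recover generating parameters to $10^{-6}$):

* **Plotting position.** The inclusive cumulative sum evaluates the CDF
  *after* each frame's events, which biases the fitted P50 toward less
  negative values by about half a frame's event mass. The fit therefore
  uses the midpoint (Hazen) position, `cum − increment/2`. In seeded
  simulations at 2000 events this removed a +0.0075 MPa bias at
  $a = -10$ MPa$^{-1}$ while leaving the reported trace itself untouched
  (the cumulative trace still ends at exactly 100 %).

* **Standard error of P50.** Successive cumulative points share almost
  all of their events, so the usual least-squares standard error — which
  assumes independent residuals — understates the replicate-to-replicate
  spread of $\hat b$ roughly tenfold. The reported `b_se` is instead the
  delta-method standard error of the 50 % quantile of the underlying
  event distribution, $2 / (|a|\sqrt{N})$ with $N$ the total embolized
  pixels (the logistic density at its median is $|a|/4$). Across 100
  seeded replicates this formula matches the empirical standard deviation
  of $\hat b$ within 10 %. The steepness SE `a_se` remains the
  least-squares value and should be treated as optimistic.

Species-level curves average the *parameters* of individual fits (mean ±
SE), not the pooled points, matching how per-species P50 and slope are
conventionally reported; P12/P50/P88 are evaluated at the mean
parameters.

## Optical embolism quantification

`diff_stack()` counts pixels whose absolute intensity change between
successive frames exceeds a threshold (default 0.5 on a 0–1 scale; there
is no field-standard value, so it is exposed as configuration).
Artifact screening is a deterministic surrogate for the manual screening
practiced at the bench: events below `min_size` pixels (default 2) are
treated as sensor noise, events above the `max_size_quantile` of nonzero
sizes (default 0.995) as whole-leaf movement. Rows are flagged, never
deleted. No connected-component analysis is performed by default — the
method counts pixels, not blobs.

Water potential is interpolated linearly in time from the psychrometer
log (10-min cadence) onto the frame clock (5-min cadence); stem and leaf
water potential equilibrate within 0.1 MPa during slow bench drying, so
the stem log stands in for the leaf. Extrapolation beyond the log is
allowed up to one log interval and flagged.

Pre-computed event tables are a first-class input alongside image
stacks: the pixel-difference step is trivially invertible (the synthetic
stack generator and `diff_stack()` are exact inverses), so desk-scale
analyses need no image I/O.

## Pressure–volume analysis

The linear-elasticity symplastic model underlies both the generator and
the extraction. With symplastic relative water content $R_s$, osmotic
potential magnitude at full turgor $\pi_o$, and bulk elastic modulus
$\varepsilon$:

$$\Psi_s = -\pi_o / R_s, \qquad
  \Psi_p = \max(0,\, \pi_o - \varepsilon(1 - R_s)), \qquad
  \Psi = \Psi_s + \Psi_p.$$

Turgor vanishes at $R_s = 1 - \pi_o/\varepsilon$, giving the closed-form
turgor loss point $TLP = -\pi_o / (1 - \pi_o/\varepsilon)$
(`closed_form_tlp()`, the analytic oracle; it requires
$\varepsilon > \pi_o$, otherwise turgor is never lost and the parameters
are rejected at construction).

Extraction works in the classic transformed space $1/\Psi$ against water
deficit $d = 1 - RWC$, where the post-turgor-loss points are exactly
linear with intercept $-1/\pi_o$. Choices that were genuinely open:

* **Tail rule.** The visual "inflection between linear and nonlinear
  portions" is replaced by a deterministic rule: grow the dry-end suffix
  from the three driest points while the extended fit keeps
  $r^2 \ge$ `r2_min` (default 0.99) *and* the candidate's residual from
  the current line stays below $\max(6 \cdot RMSE_{tail},\ 10^{-8})$.
  The residual gate is what makes the rule exact on noiseless data: near
  the turgor loss point the curve leaves the line so gently that an
  $r^2$ threshold alone can absorb pre-turgor points, whereas a zero-RMSE
  tail rejects any point off the line. On noisy data the gate widens with
  the tail's own scatter and the $r^2$ threshold governs.
* **TLP convention.** The reported TLP is the water potential of the
  wettest tail point (the breakpoint datum); a model-based intersection
  variant is available via `tlp_method = "intersection"`. The two agree
  exactly on the generator's grid, which samples the inflection point
  itself (bench operators measure densely around the inflection).
* **Apoplastic water.** Trait extraction assumes the symplast holds all
  leaf water (apoplastic fraction 0). The generator supports nonzero
  fractions to probe the robustness of that assumption.
* **Elastic modulus.** $\varepsilon = \Delta P / (\Delta V / V)$ is a
  ratio of increments; pooling all pre-turgor points through one OLS
  slope of turgor pressure on RWC uses every increment at once and is
  exact for the linear model.
* **Turgid mass.** If the series contains a point at (numerically) zero
  water potential its fresh mass is taken directly; otherwise fresh mass
  is regressed on $\Psi$ over points wetter than −1 MPa and extrapolated
  to zero, floored at the maximum observed fresh mass.

On noiseless generator data these choices recover $(\pi_o, \varepsilon,
TLP)$ to within $10^{-6}$ relative error across parameter ratios
$\varepsilon/\pi_o \in [1.5, 10]$ (property-tested over 50 random
draws).

Note that published $(\pi_o, \varepsilon, TLP)$ triplets for real
species are *not* exactly consistent with this idealized model — real PV
curves have curvature the linear-elasticity model lacks — so synthetic
data parameterized from a printed trait table reproduce the printed TLP
only as closely as that table is internally consistent (within ~0.01 MPa
for stiff-walled species, ~0.3 MPa for the softest).

## Safety margins and predicted embolism

`hsm(psi_min, px)` and `ssm(tlp, px)` are both differences against an
embolism threshold, `value − px`. The sign convention (field minimum
minus threshold) makes positive margins safe and reproduces reported
negative margins for species whose dry-season water potentials crossed
P50. Predicted percent embolism applies the species-mean curve to *each
individual's* minimum water potential before averaging: because the
sigmoid is convex away from its midpoint, the average of transforms can
differ from the transform of the average by many percentage points for
steep curves, which is why the curve-at-mean-Ψ shortcut is not used. The
SSM standard error is propagated as
$\sqrt{SE_{TLP}^2 + SE_{P50}^2}$ — a convention, since the pairing of
TLP and P50 individuals within species is not observed.

## Statistical layer

Trait differences between species use one-way ANOVA with Tukey HSD and a
compact letter display assigned by greedy insert-and-absorb in order of
group means; only the sharing structure is meaningful, not the letters
themselves. Paired period comparisons use the paired t-test (identical
vectors return $t = 0, p = 1$; a constant nonzero shift with zero
variance of differences is undefined and errors).

Damage metrics are modelled with Gaussian log-link GLMs: the expected
damage is $e^\eta$ while errors stay additive, matching bounded
percentage outcomes with multiplicative trait effects. Open choices:

* Responses are clamped to $[0.5, 99.5]$ before fitting (exact 0 and
  100 are attainable survey values the log link cannot represent); the
  clamp count is recorded on every fit.
* All predictor subsets of size 1–3 are enumerated (92 models for 8
  traits) in deterministic order. AIC ties rank the smaller model first.
* Akaike weights are $e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$; models
  with $\Delta AIC \le 2$ are marked as similarly supported.
* VIF is computed from the *linear* design ($1/(1-R^2_j)$ of each
  predictor on the others), with the convention VIF = 1 for
  single-predictor models, which are therefore never excluded. The
  selection takes the lowest-AIC model whose every VIF is at or below 10.
* McFadden $R^2$ uses full Gaussian log-likelihoods with per-model
  estimated dispersion. With five species and three predictors the
  residual degrees of freedom is 1: such fits are produced but flagged
  `saturated_regime`, and near-unity $R^2$ values in that regime carry
  little information.

## Standardized Precipitation Index

Rolling 12-month sums are transformed through a fitted gamma
distribution with a mixed zero term, $H(x) = q + (1-q) F_\Gamma(x)$, and
mapped to standard-normal units via $\Phi^{-1}(H)$. The gamma MLE is
solved from its profile score equation ($\log\alpha - \psi(\alpha) =
\log\bar x - \overline{\log x}$) by bracketed root search, which is
unconditionally stable where general-purpose optimizers fail sporadically
on short per-month samples; the result matches an independent
maximum-likelihood fit to four decimals where both succeed. All windows
are pooled into one fit by default (one long-term SPI-12 trace);
per-calendar-month fitting is available via `by_month = TRUE`.

A caution on drought blocks in synthetic series: halving the monthly
scale for 12 months guarantees the affected windows rank deep in the
lower tail (bottom 5 % of windows, property-tested at ≥ 95 % of seeds),
but over 40 years of realistic interannual variability a remote window
still occasionally produces the single global minimum — with annual-sum
CV near 20 %, a normal-climate window beats the halved block in roughly
a quarter of seeds. "The drought block is the global minimum" is a
tendency of the construction, not a guarantee, and the tests assert it
only as a majority outcome.

## Synthetic data: what it does and does not emulate

The generators draw embolism thresholds from the exact inverse of the
sigmoid ($\Psi_u = b + \log\{u/(1-u)\}/a$), dry the branch linearly in
time (the lab drying trajectory is not standardized; an exponential
option exists through explicit `psi_start`/`psi_end`), give each event
one pixel by default with the total defining 100 %, and truncate field
water potentials at −0.01 MPa to keep them physical. Damage surveys are
generated as $\mathrm{clip}(e^{\eta}, 0, 100)$ plus observer noise
averaged over two observers — deliberately the same family as the
analysis model, so coefficient recovery is a well-posed check of the
fitting code, not a test of model adequacy.

None of this emulates leaf optics or texture, image registration error,
psychrometer physics, spatially correlated embolism spread, or real PV
curvature beyond the linear-elasticity model. Passing tests therefore
demonstrate that the *estimators* are correct and calibrated under their
own assumptions, not that those assumptions hold for any particular
species.

## Problem sizes and determinism

Default study conditions follow the field design they emulate: 6
species, 3 leaves per species for vulnerability and PV work, ~500–2000
embolism events per leaf, at least 6 (default 10) individuals per
species and period in the field, 40 years of monthly precipitation.
Simulation-based tests use 20–100 seeded replicates per property. Every
generator takes an explicit seed and restores the caller's RNG state;
identical configurations produce byte-identical output, and the pipeline
derives per-stage child seeds deterministically from its master seed.

## Known limitations

* Alternative vulnerability models (Weibull, exponential-sigmoid) are
  out of scope; so are stem- and root-level curves.
* PV capacitance traits, apoplastic-fraction estimation and
  oversaturation correction beyond the turgid-mass extrapolation are not
  implemented.
* The species join in `safety_margins()` is by exact label.
* `a_se` from `fit_sigmoid()` on event traces is a conditional
  least-squares value and understates true uncertainty.
* SPEI (evapotranspiration-adjusted) indices and drought-classification
  taxonomies are out of scope.
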