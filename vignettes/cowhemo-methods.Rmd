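---
title: "Reduced-order hemodynamics of the mouse circle of Willis: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order hemodynamics of the mouse circle of Willis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowhemo)
```

## The problem

Chronic type-1 diabetes damages the vasculature, and the circle of Willis
(CoW) — the anastomotic arterial ring supplying the brain — is both the main
site of collateral flow compensation and accessible to in-vivo angiography.
In a four-arm mouse design (control and streptozotocin-diabetic animals at 1
and 2 months, n = 7/5/10/9), diabetic vasculopathy manifests as a narrowed
internal carotid lumen, altered bifurcation angles, raised hydraulic
resistance and, characteristically, a left/right asymmetry of carotid inflow
that appears only after two months of disease.

`cowhemo` provides a desk-scale computational embodiment of that study
design: a lumped blood-flow model on CoW networks, the three standard
hemodynamic read-outs, a synthetic cohort generator calibrated to the
published group statistics of such an experiment, and the statistical
pipeline (per-feature testing, PLS-DA, two-way ANOVA, asymmetry testing)
that turns per-animal features into group-level conclusions.

## Flow model

Blood is treated as an incompressible Newtonian fluid in rigid, straight
circular tubes; the flow is laminar and fully developed. Under these
assumptions the steady regime of the incompressible Navier–Stokes equations
reduces per segment to Hagen–Poiseuille conduction,

$$ Q = G \, \Delta P, \qquad G = \frac{\pi r^4}{8 \mu L}, $$

with $r$ the equivalent lumen radius $\sqrt{A/\pi}$. Mass conservation
($\nabla \cdot \vec v = 0$) at every junction turns the network into a
conductance-weighted graph Laplacian; `solve_steady()` solves the resulting
nodal-pressure system with one outlet grounded at 0 mmHg (only pressure
*differences* are physically meaningful here, as in the resistance metric).

Boundary conditions mirror angiographic practice: each inlet (left/right
common carotid, left/right vertebral artery) carries a prescribed mean
velocity, contributing $v_k A_k$ of volumetric inflow; the outlets share the
total inflow **in proportion to their cross-section areas**, at every
instant in the pulsatile case. Because two of the template's outlets (the
superior cerebellar pair, outlets 7 and 8) leave the basilar terminus right
at the posterior bifurcation, `lengthen_outlets()` extends them by 1 mm
before solving, so the outlet boundary condition is not imposed directly on
a bifurcation; the steady solution is insensitive to this (flows are fixed
by the area split; only the extended outlets' own pressures move), which is
exactly the property the solver test verifies.

### Pulsatile regime

The inlet waveform is decomposed into harmonics,
$v(t) = \bar v\,[1 + \sum_k \mathrm{Re}(c_k e^{i k \omega t})]$, and each
harmonic is solved on the same network with the rigid-tube Womersley
impedance

$$ Z(\omega) = \frac{i\omega\rho L}{\pi r^2}
   \left[ 1 - \frac{2 J_1(\Lambda)}{\Lambda J_0(\Lambda)} \right]^{-1},
   \qquad \Lambda = i^{3/2} \alpha, \quad \alpha = r\sqrt{\omega/\nu}. $$

$Z \to 8\mu L/(\pi r^4)$ as $\omega \to 0$ (Poiseuille) and
$Z \to i\omega\rho L/(\pi r^2)$ for large $\alpha$ (inertance); both limits
are verified against independent evaluations. The convective term
$(\vec v\cdot\nabla)\vec v$ is dropped — the standard linear Womersley
regime used by lumped and 1-D cerebral network models — which is the main
fidelity gap relative to a full 3-D solve. Since the model is linear,
cycle-averaged flows equal the mean-flow (steady) solution exactly; the
time-resolved signal matters for maximum velocity and instantaneous
resistance only.

At murine radii (0.1–0.3 mm) and the default 0.137 s cardiac cycle the
per-segment Womersley numbers evaluate to roughly 0.5–3 across the first
eight harmonics, i.e. only mildly non-parabolic profiles. Because claims of
much larger $\alpha$ circulate for this preparation, the transient state
stores $\alpha$ per segment and harmonic so users can judge the regime
themselves.

Two numerical details. The complex Bessel ratio is evaluated by power
series up to $|\Lambda| = 15$ (cancellation stays below ~$10^5$ in double
precision) and by the asymptotic $P/Q$ expansion beyond, where the
exponentially growing parts of $J_0$ and $J_1$ cancel in the ratio. And a
0.005 s step does not divide the 0.137 s cycle evenly, so the default grid
snaps to $\lceil T/\Delta t\rceil = 28$ uniform intervals; on a periodic
grid the discrete cycle average of every retained harmonic vanishes
identically, making "cycle average = steady solve" exact rather than
approximate (`strict_grid = TRUE` restores the literal step).

### Default waveform

No measured murine waveform ships with the package. The default is a
parametric, strictly positive von Mises-type pulse whose Fourier
coefficients are modified Bessel ratios, $c_k = 2 I_k(\kappa)/I_0(\kappa)$,
with $\kappa = 0.55$, giving a systolic peak of about 1.6x the cycle mean at
30 % of the cycle — a generic arterial shape, deliberately simple and fully
overridable via `arterial_waveform()`.

## Hemodynamic metrics and the 73-feature registry

From a solved state the package computes, per cross-section plane
$\Omega_i$:

* **mass flow** $Q_i = \iint_{\Omega_i} \rho (\vec v \cdot \vec n)\,dS$
  (mg/s) — in the lumped model, $\rho$ times the segment's volumetric flow,
  signed by the oriented normal;
* **maximum velocity** $v_i^{max}$ (cm/s) — twice the sectional mean for
  the steady parabolic profile; for pulsatile states the Womersley radial
  profile of every harmonic is superposed on a 101-point radial grid, the
  spatial maximum taken per time point and averaged over the cycle;
* **hydraulic resistance** $R_{ij} = \Delta P_{ij}/Q_i$ (mmHg·s/g) between
  plane pairs. $\Delta P$ defaults to *total* pressure (static plus dynamic
  head $\rho \bar v^2/2$) because the quantity of interest is stated in
  terms of average total pressure in the section; a `kind = "static"`
  variant exists, and on same-vessel plane pairs of equal area the two
  coincide. For pulsatile states $R$ is the cycle average of the
  instantaneous ratio $\Delta P(t)/Q(t)$ (falling back to the ratio of
  cycle means if the flow nears zero within the cycle); a ratio-of-means
  definition would equal the steady value identically in a linear model
  and carry no extra information.

The statistics stage consumes exactly 73 features per animal: 7 bifurcation
angles + 22 section areas + 22 sectional maximum velocities + 11 per-vessel
mass flows + 11 same-vessel-pair resistances. The 22-plane registry places
two planes on each of the 11 named vessels (BA, ICA, MCA, ACA, PcoA, PCA,
left/right); the anatomical labels fix plane 1 (basilar base), plane 3
(left ICA, cervical C1) and plane 6 (right ICA, C1), and the remaining
placement is an explicit, overridable convention
(`default_section_registry()`). Under this registry the named pairs (5,6)
and (15,16) are same-vessel pairs (right ICA; right PcoA). Exact plane
positions on the source anatomy cannot be recovered from text alone, so the
registry is documented as a convention, not a measured fact.

## Synthetic cohort generator

No raw imaging data are public for this design, so the generator is the
package's data source, and its defaults *are* the study conditions:
four arms of 7/5/10/9 animals, per-feature Gaussian variation with the
published group means and standard errors (per-animal SD = SE·√n), reduced
ICA lumen and basilar enlargement only in the 2-month diabetic arm, and
left/right carotid-velocity asymmetry only in that arm.

```{r params}
head(read_group_params()[, c("feature", "group", "mean", "se", "mode", "source")], 8)
```

Three calibration decisions deserve emphasis:

* **Positive features are sampled with moment-matched truncation.** Some
  published rows have coefficients of variation up to ~0.7, where a naive
  ">0-truncated Normal(mean, SD)" overshoots the target mean by several
  percent. The generator instead solves, from the closed-form truncated
  normal moments, for the underlying $(\mu, \sigma)$ such that the
  *truncated* distribution has exactly the published mean and SD. Angles
  use plain (0°, 180°) truncation, where the excluded mass is negligible.
* **Placeholders are explicit.** Features without published rows (their
  values live in an unavailable supplement) receive documented placeholder
  distributions flagged `source = "placeholder"`: geometric features take
  the template's nominal value; hemodynamic features take the value
  obtained by solving the control template once per mode, shared across
  arms, so that synthetic group differences arise *only* where the
  published table differs; SE defaults to 8 % of the mean (4 % for angles,
  matching the published angle row). Inlet velocities are placeholders
  calibrated to the narrative: control CCA 12 cm/s, 1-month diabetic arms
  reduced ~20 % on both sides, 2-month diabetic arm reduced on the right
  side only, VA 7 cm/s.
* **Asymmetry is a within-animal coupling.** In the 2-month diabetic arm
  the right CCA velocity is drawn as `left x ratio`, with the ratio's mean
  and SD derived from the group table itself so that the *marginal*
  mean/SD of the right side still match their rows while the paired L−R
  difference becomes strongly positive within animals. In all other arms
  left and right are independent with equal means, so the paired test
  operates at its nominal level there.

One transcribed row is internally inconsistent in its source: the
posterior-communicating mass-flow row pairs an SE of 0.001 with a
non-significant p-value, which no two-sample computation reproduces; the
value is transcribed as printed, with the consequence that this feature is
essentially always flagged in generated 2-month comparisons.

Cohorts can flow through two paths. The *solver path*
(`sample_animal()` → `solve_steady()`/`solve_transient()` →
`compute_metric_set()`) perturbs the template geometry and induces
physically consistent correlations between features. The *direct path*
(`direct_feature_matrix()`) draws each feature independently from its group
distribution and is the calibration reference: real anatomies correlate
lumen with resistance, but no such correlation is identifiable from
marginal summaries, so independence is the defensible default (a covariance
hook would be the natural extension). Passing tests on the direct path
therefore demonstrates fidelity to the published *marginal* statistics, not
to any unpublished correlation structure.

```{r direct}
m <- direct_feature_matrix(cohort_config(seed = 1))
dim(m)   # 31 animals x (animal, group + 73 features)
```

## Statistics pipeline

* **Normality screen**: Kolmogorov–Smirnov distance against a normal with
  plug-in mean/SD. Estimating parameters from the same sample (the
  Lilliefors situation) makes the textbook KS null anti-conservative, so
  p-values are calibrated by Monte-Carlo simulation of same-size normal
  samples instead.
* **Two-group tests**: Student's pooled-variance t by default — matching
  the source analysis — with Welch behind a flag; a summary-statistic
  variant re-tests printed (mean, SE, n) rows directly. No multiplicity
  correction is applied by default (the published per-feature p-values are
  raw across all 73 parameters); a Benjamini–Hochberg switch exists.
* **PLS-DA**: NIPALS extraction against one-hot group coding after
  autoscaling (features mix degrees, mm², mmHg·s/g; unit variance is the
  only defensible common scale). Successive X-scores are orthogonal by
  construction; convergence tolerance 1e-10 on the score vector; signs are
  fixed by making each component's largest-magnitude weight positive.
* **Stepwise variable elimination**: backward elimination of the
  smallest-VIP feature while stratified 5-fold cross-validated
  classification accuracy stays within `tol = 0.05` of the best seen;
  deterministic given the fold seed. The "stable model" flag uses the
  *pre-selection* CV accuracy against a one-sided binomial bound, because
  accuracies computed along the elimination path steer the search and are
  selection-biased.
* **Two-way ANOVA on scores**: pathology (control/diabetes) and duration
  (1/2 months) as crossed factors on each score axis. The default model is
  additive: with 31 animals this yields denominator df 28, the df pattern
  consistent with the published analysis, and partial (Type II) F tests
  from dropping each term are appropriate for the unbalanced 2x2 design.
  The interaction can be reported from a separate full-factorial fit and
  is flagged as such.

```{r stats}
res <- run_stats(direct_feature_matrix(cohort_config(seed = 1),
                                       include_velocities = TRUE),
                 config = list(seed = 1))
res$anova
sort(res$significant[["2c_vs_2d"]])
```

## Degenerate inputs and tie-breaks

Identical two-group samples return t = 0, p = 1 rather than an error; a
constant non-zero paired offset is a degeneracy error (no variance to test
against). Resistance across a dead branch (flow below 1e-9 of the total
inflow) is undefined and propagates as `NA` through `compute_metric_set()`
with a warning, leaving other features untouched. All-equal ANOVA inputs
report F = 0, p = 1. Angle imposition rotates one designated segment of
each pair in the plane of the current two directions, applied in the anchor
order ICA → PcoA → ACA → MCA so that all seven sampled angles are realized
exactly and never overwrite each other.

## Problem sizes

Simulation-backed checks in the test suite use sizes chosen to make
Monte-Carlo noise small relative to the asserted margins: 1e5 draws for
distributional recovery (sampling error ~0.3 % against a 1 % band), 100
random networks for conservation, ~5,000 simulations for the type-I error
of the t-test (binomial SD ~0.003 against a ±0.02 band), and 100 seeded
cohorts for the end-to-end group-difference pattern. The published-n sanity
check (sample mean within 2·SE at n = 7–10) is intrinsically a ~95 % event
per feature; the suite therefore requires 33 of the 36 published rows to
pass rather than all of them.

## Known limitations

* Rigid straight tubes, no convective acceleration, no wall shear stress or
  pulsatility indices: the model preserves conservation laws, boundary
  conditions and the three reported metrics, not 3-D flow structure.
* Blood properties (3.5 mPa·s, 1.05 g/cm³) are standard murine whole-blood
  conventions, configurable but not fitted; the source model statement
  specifies no values and no non-Newtonian law.
* The direct generator path samples features independently; solver-path
  cohorts induce physical correlations, but neither reproduces unknown
  real-animal covariance.
* The section-plane registry beyond the three labelled planes, the outlet
  ordering, and the inlet-velocity placeholder block are documented
  conventions standing in for unavailable source data.
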