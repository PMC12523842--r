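---
title: "Methods: an ensemble habitat model for the saury fishery, tested against a known niche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an ensemble habitat model for the saury fishery, tested against a known niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models and of the design
choices a maintainer would want to interrogate. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` compute at run
time.

## 1. The modelling chain

The package treats a habitat forecast for the Pacific saury fishery as a
chain of five stages, each a small, separately testable contract:

vessel fixes → fishing points → occurrence table → ensemble SDM →
scenario analytics.

The design premise is that fishing locations of a highly standardized fleet
(stick-held dip nets operating at night under lights) are a usable proxy for
species presence, and that the chain from raw kinematics to a projected
centroid shift can be validated end to end only if the truth is known —
hence the synthetic module is first-class, not a test fixture.

## 2. Fishing detection rules

A fix is labelled fishing iff **all** of:

* speed over ground within `[0.1, 4.0]` kn — dip-net vessels drift or
  reposition slowly while operating;
* heading change from the previous fix ≥ 30°, **or** speed < 1 kn — the
  drift clause: a vessel lying to its gear holds an arbitrary, slowly
  wandering heading, and without the clause near-stationary fishing fails
  the turn test;
* local-solar night (UTC + lon/15 h inside 18:00–06:00) — the fishery is a
  light-attraction fishery; an ephemeris is deliberately avoided, as the
  ±30–40 min error of the solar approximation is far below the dwell time of
  a fishing night;
* significant wave height < 2.5 m — operations stop in heavy seas.

The conjunction is the conservative reading of a rule screen; treating the
conditions as a score would admit fixes that fail a hard physical constraint.
All thresholds are parameters of `fishing_rules()`. The rule set is
deliberately the *implementable half* of a dual framework: a trained deep
classifier over trajectory windows is out of scope here, and the package
documents that simplification rather than imitating it.

Tightening any single threshold can only remove fishing labels (a monotone
conservatism property the tests enforce).

## 3. Occurrence preparation

Thinning keeps the **first** record per occupied grid cell — determinism
matters more than which record survives, since cellwise predictors make all
records in a cell interchangeable; a cell-center representative is optional.
Cells follow a half-open, south-west-origin convention so every point
belongs to exactly one cell.

Background cells are sampled uniformly over the whole study extent, *with*
possible coincidence with presence cells by default: these are
pseudo-absences in the strict sense (a random sample of available
environment), not confirmed absences. Exclusion is available for users who
want discrimination-style backgrounds. The full-data fishery analysis uses
50,000 background points; synthetic runs scale this down through
configuration (3,000 at the desk scale) to keep the class ratio, not the
absolute count, the operative quantity.

## 4. Environmental stack

Seven co-registered layers: SST (°C), CHL (mg m⁻³), SSS (‰), MLD (m), the
velocity components Uo/Vo and the derived current speed CV = √(Uo² + Vo²)
(m s⁻¹). Harmonization utilities — bilinear/nearest regridding (bilinear for
continuous fields; exact on constant and planar fields, with missing values
propagating no further than immediate neighbours) and missing-aware monthly
climatology — bring differently gridded sources onto the analysis grid.
Collinearity is screened with VIF = 1/(1 − R²) against the conventional
threshold 5; predictors are extracted at occurrence cells by containing-cell
lookup (no interpolation), matching the thinning grid. CHL enters the model
table untransformed by default (a log10 switch is a one-line change in the
model table construction); the screen and the tests treat the untransformed
variable.

## 5. The synthetic study system

`make_env_stack()` builds each layer as *deterministic trend + spatially
autocorrelated noise* (Gaussian-filtered white noise, correlation length
1°). The trends are chosen so the truly suitable habitat is a compact blob,
not a zonal band:

* SST: a pure monotone meridional gradient, 24 °C at 30° N falling
  0.62 °C per degree latitude (the 9.5 °C isotherm sits near 53° N);
* CHL: log-normal around a zonal productivity ridge at 150° E (background
  0.1, ridge peak 0.5 mg m⁻³, σ = 6°) — a stylized subarctic front;
* SSS, MLD: weak meridional trends; Uo/Vo: weak mean flow plus noise.

Noise standard deviations (SST 0.6 °C, CHL 0.2 log units, SSS 0.2 ‰, MLD
5 m) are set at climatological-mean scale: the layers emulate multi-year
means in which transient mesoscale variability has largely averaged out.

The **niche truth** is a weighted product of scaled Gaussian responses
`∏ᵥ exp(−½((xᵥ−optᵥ)/widthᵥ)²)^wᵥ`, maximal (=1) when every variable sits at
its optimum: SST 9.5 °C (width 1.5, weight 1.0), CHL 0.5 mg m⁻³ (0.2, 0.7),
MLD 44 m (11, 0.3), SSS 34 ‰ (1.2, 0.2), CV 0 m s⁻¹ (0.3, 0.2). The weights
encode the SST-dominant, CHL-second importance ordering the model is
expected to recover; the optima are the recovery targets for the response
curves.

Vessels alternate transit (6.5–10.5 kn, near-constant heading toward target
cells sampled ∝ suitability³) and fishing (night only; 55% of fixes drifting
at 0.1–0.9 kn, the rest repositioning at 1.2–4.0 kn with 40–180° heading
swings). Wave height follows a per-vessel AR(1) sea state around 1.5 m. Fix
cadence defaults to 10 min and is a parameter, since fleet reporting rates
vary. The generator guarantees by construction that fishing speeds fall
inside the rule window, transit speeds outside it, and fishing occurs at
night — the detection tests then measure how much the *boundary* fixes
(state transitions, wave exceedances) erode precision and recall.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: fleet behaviour that is not
habitat-driven (port logistics, quota races, gear conflicts), spatial
sampling bias beyond clustering, position noise, current advection of
drifting vessels, multi-gear fleets, and any mismatch between fishing
suitability and biological suitability.

### Scenario deltas

Climate perturbations are additive fields `add + lat_grad·(lat − 30)`
per variable, with SST warming +0.8…+1.5 °C (2050s) and +1.2…+4.0 °C
(2100s) across SSP1-2.6 → SSP5-8.5, a small poleward-amplification
gradient, slight CHL decline and MLD shoaling — CMIP6-plausible magnitudes,
invented plumbing standing in for downscaled scenario layers. A zero delta
returns the baseline bit-identically.

`shift_delta()` additionally translates the *deterministic trends* of chosen
variables by a known (Δlat, Δlon). CHL, being log-normal, is translated
multiplicatively (`layer · T(x−d)/T(x)`): an additive difference of
log-normal trends would warp the field rather than move it. This rigid
translation is the ground truth for the centroid-recovery experiment.

## 6. Ensemble machinery

* **Cross-validation**: five runs of random 80/20 splits, stratified by
  presence/background so both classes appear in every fold.
* **Evaluation**: the binarization threshold maximizes TSS over the exact
  candidate set (midpoints of sorted distinct scores, plus the two trivial
  extremes), so `TSS = sensitivity + specificity − 1` holds exactly at the
  reported operating point. AUC uses the rank (Mann–Whitney) formulation
  with ties averaged, and is tested cell-for-cell against an O(n²) all-pairs
  oracle. Background records are treated as absences in the confusion
  matrix — that is what "specificity over background points" means here.
* **Member comparison**: classic paired t-tests on per-run scores
  (`stats::t.test`); zero-variance differences are reported as degenerate
  (t = 0 or ±∞) instead of erroring. Raw p-values, no multiplicity
  correction — the comparisons are descriptive, and that choice is stated
  rather than hidden.
* **Selection**: mean-across-runs TSS ≥ 0.8 (the mean, not per-run scores,
  because a selection rule should not reward run-to-run luck). If nothing
  passes, the failure names the rule.
* **Combiners**: EMmean, EMmedian, EMwmean (weights ∝ mean TSS, normalized;
  the exponent is configurable, default 1), and EMca defined as the mean of
  per-member binary maps at each member's own mean max-TSS threshold —
  standard committee averaging, stated explicitly since "committee
  averaging" is often left undefined.
* **Registry**: quadratic-term logistic GLM, rpart classification tree,
  xgboost gradient boosting, ranger random forest, nnet single-hidden-layer
  network (inputs standardized), and an in-package surface-range envelope
  (rectilinear 2.5–97.5% presence envelope, binary scores — its skill
  ceiling is accordingly ~0.95 TSS). The ensemble framework, not the
  learners, is the contribution; the registry is pluggable and the exact
  roster of a reference implementation is not asserted.

### Importance and response curves

Permutation importance: `1 − cor(predictions, predictions with column v
permuted)`, averaged over permutations, rescaled to sum to 100%. Response
curves use the evaluation-strip method; the strip holds the other variables
at their **presence-row medians** by default. With a ~50:1
background-to-presence table, all-row medians would pin every companion
variable deep in unsuitable conditions, where tree and net members are flat
and a peak position is meaningless; `at = "all"` restores the plain
behaviour.

## 7. Projection analytics

* Spherical cell areas `R²·Δλ·(sin φ₂ − sin φ₁)`, R = 6371 km.
* Zones: [0, 0.4), [0.4, 0.6), [0.6, 0.8), [0.8, 1.0] — left-closed, top
  closed, so touching printed ranges partition [0, 1]; zone areas sum to the
  non-missing study area (a conservation test).
* Transitions binarize both maps at 0.4 — the Non-Suitable boundary is the
  only threshold the zonation itself distinguishes, and it is configurable.
  Both stable classes (suitable and unsuitable) are computed and reported
  separately, since figure conventions elsewhere are ambiguous about
  "stable"; percentages are over total classified area.
* Centroids: suitability-weighted mean of cell centers (weights
  HSI·cell area) by default, with a binary-suitable mode; displacement is
  haversine distance with initial bearing.

## 8. The recovery experiment (design rationale)

`niche_recovery_run()` is the package's decisive check: fit everything on
one synthetic realisation, then ask whether the *known* truth comes back.
Three choices deserve justification:

1. **Desk-scale conditions** (full extent at 1/4°, 12 vessels × 1440 fixes,
   3000 background, ten seeds) — the niche parameters, rules and noise model
   are identical to the generator defaults; only grid resolution and fleet
   size are reduced, which changes sample sizes, not the science.
2. **Displacement is measured on noise-free evaluation stacks.** The
   scenario delta translates the *trends*; the noise field does not
   translate (a warm patch does not pack up and move northeast). Measured on
   noisy fields, the "true" centroid displacement itself varies by tens of
   percent across realisations, so the comparison would test the weather,
   not the model. Fitting on noisy data and evaluating on the expected
   fields isolates niche-recovery error, which is what the experiment is
   about.
3. **Core-weighted centroids (HSI³) for this experiment.** The generator's
   suitability has a soft off-ridge background (≈0.25 response); a fitted
   presence/background model is sharper. Plain weighted centroids therefore
   shift by systematically different amounts on truth and model even when
   the model is right about *where* the habitat is. Cubing concentrates
   both fields on their core smoothly (no threshold cliffs) and identically,
   making the comparison like-for-like. The public `hsi_centroid()` keeps
   the plain weighted and binary modes.

The applied translation is (Δlat, Δlon) = (2.0°, 3.0°) ≈ 295 km toward the
northeast at the habitat's latitude — the magnitude of an
end-of-century-scale range shift.

## 9. Numerical choices and degenerate inputs

* Thresholds candidates include guards beyond the score range so
  all-positive/all-negative classifications are reachable; ties in scores
  are handled by the rank AUC exactly as by pair counting.
* Perfect collinearity in VIF reports `Inf`, not an error; constant columns
  are an error (no regression is defined).
* `evaluate_scores()` refuses single-class inputs; `cv_split()` refuses
  fewer than 10 records per class.
* A failing base learner is excluded with a warning, not fatal — an
  ensemble should survive one member's convergence failure.
* Constant predictions during permutation importance yield importance 0
  with a warning (the correlation is undefined).
* All generators and fits are pure functions of (parameters, seed);
  `withr::with_seed` keeps the global RNG state untouched.

## 10. Problem sizes

The package defaults describe the full study conditions (1/12° grid —
226,800 cells — and a 20 × 2000-fix fleet). The shipped analysis scripts,
test suite and acceptance script run the same code at 1/4° with a
12 × 1440-fix fleet and 3000 background points: large enough that
cross-validated skill estimates stabilise (≈50–90 presences after thinning),
small enough that the ten-seed experiment and the full suite run in minutes
on one CPU. The vignette states these sizes as the package's reporting
choice; nothing in the methods depends on them.

## 11. Known limitations

* Fishing presence is an imperfect proxy for biological presence; the
  package quantifies recovery of the *generator's* niche, not of a real
  species' niche.
* Niche conservatism is assumed under projection — responses are static.
* The solar-time night window is approximate at high latitudes in summer
  (white nights compress the true dark window; the rule window is
  configurable).
* The SRE member's binary scores make it a blunt instrument; it is included
  for registry breadth, and the TSS ≥ 0.8 gate usually excludes it.
* No spatial block cross-validation: random splits over thinned cells still
  share large-scale spatial structure between folds, so CV skill estimates
  are optimistic in the way standard random-split SDM evaluations are.
* Regular lat/lon grids only; no projected coordinate systems.
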