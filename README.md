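# sauryhab

Habitat modelling for the Pacific saury (*Cololabis saira*) fishery in the
North Pacific high seas, built as a fully testable pipeline: fishing-point
extraction from vessel trajectories, occurrence preparation, an ensemble
species distribution model (ESDM) with TSS-weighted model averaging, and
climate-scenario projection with habitat zonation, transition mapping and
centroid-shift quantification.

## The scientific problem

Pacific saury is a stenothermal, migratory pelagic fish whose distribution is
tracked operationally by where the stick-held dip-net fleet fishes. Vessel
position (AIS-style) records therefore carry presence information at a
resolution fishery logbooks cannot match — but turning them into a habitat
forecast requires a chain of steps, each easy to get subtly wrong:

1. **Fishing detection** — a fix is a fishing operation only if it looks like
   one: speed over ground within 0.1–4.0 kn, a heading change of at least
   30° (or drifting below 1 kn), local-solar night, significant wave height
   below 2.5 m. All conditions must hold (a conservative conjunction).
2. **Occurrence preparation** — clustered fishing points are thinned to one
   presence per 1/12° grid cell and contrasted with background
   (pseudo-absence) cells sampled uniformly over the study area
   (135–180° E, 30–65° N).
3. **Ensemble SDM** — base learners (quadratic logistic GLM, classification
   tree, gradient boosting, random forest, neural net, surface-range
   envelope) are evaluated by five runs of 80/20 cross-validation on
   TSS = sensitivity + specificity − 1 and AUC; members with mean TSS ≥ 0.8
   form the ensemble, combined as the TSS-weighted mean
   `HSI(x) = Σᵢ wᵢ · pᵢ(x)`, `wᵢ ∝ mean TSSᵢ` (EMmean, EMmedian and
   committee averaging are also provided).
4. **Projection and analytics** — the ensemble is projected onto baseline
   and scenario stacks (SSP1-2.6 … SSP5-8.5 at mid-century and
   end-of-century); per-cell suitability is classified into
   Non-Suitable [0,0.4), Low [0.4,0.6), Moderate [0.6,0.8), High [0.8,1.0]
   zones with spherical-Earth areas, transition maps, and
   suitability-weighted habitat centroids with great-circle displacements.

Because the real fleet data are proprietary, the package ships a first-class
synthetic module: environmental stacks with realistic gradients, a **known
niche truth** (product of scaled Gaussian responses; SST optimum 9.5 °C, CHL
optimum 0.5 mg m⁻³, MLD 44 m, weak-current and high-salinity preference), and
vessel trajectories with labelled fishing/transit states. Every downstream
stage is tested against this ground truth.

## Worked example

```r
library(sauryhab)

g      <- grid_spec(res = 1/4)                      # 180 x 140 cells
truth  <- niche_truth()
stack  <- make_env_stack(g, seed = 1)
fleet  <- simulate_trajectories(stack, truth, n_vessels = 12,
                                n_fixes = 1440, seed = 2)

fishing   <- classify_fixes(fleet, fishing_rules())
presences <- spatial_thin(fishing[fishing$label == "fishing", ], g)
occ       <- occurrence_set(presences, sample_background(g, 3000, seed = 3), g)
tab       <- build_model_table(occ, stack)

splits <- cv_split(tab, runs = 5, seed = 4)
fits   <- fit_members(tab, model_registry(seed = 5), splits)
ens    <- sdm_ensemble(fits, select_members(fits$evals))
ens
#> <sdm_ensemble EMwmean> 4 member(s): ANN (TSS 0.900, w 0.253), GBM (TSS 0.883, w 0.248),
#>   GLM (TSS 0.916, w 0.257), RF (TSS 0.863, w 0.242)
```

The printed ensemble shows which members passed the TSS ≥ 0.8 selection rule
and their normalised weights. Projecting and warming:

```r
current <- project_ensemble(ens, stack)
future  <- project_ensemble(ens, apply_scenario(stack,
             default_scenario_deltas()[["2100s SSP5-8.5"]]))
d <- centroid_displacement(hsi_centroid(current), hsi_centroid(future))
round(c(km = d$km, bearing = d$bearing_deg))
#>      km bearing
#>     680     359
```

Under the strongest warming the synthetic habitat centroid moves ~680 km
poleward — the same qualitative signal (a several-hundred-km shift of the
habitat centre under high emissions) the method is designed to quantify.

The `analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate.R` … `06_recovery_experiment.R`), each writing its
tables under `results/`.

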