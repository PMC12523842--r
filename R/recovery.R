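#' Single-seed niche-and-shift recovery experiment
#'
#' Runs the full chain on one synthetic realisation and quantifies how well
#' the fitted ensemble recovers the generator's ground truth: the response
#' curve peaks for SST and CHL, the top-ranked variable in permutation
#' importance, the cross-validated skill of the weighted-mean ensemble versus
#' its single members, and the habitat-centroid displacement under a
#' scenario delta that translates the niche-defining trends northeast by a
#' known offset (the true displacement is measured on the generator's own
#' suitability field, so realisation noise is part of the truth, not of the
#' error).
#'
#' The default sizes are the package's desk-scale recovery conditions: the
#' full study extent at 1/4 degree, a 12-vessel fleet with 1440 fixes each,
#' 3000 background points, and a trend translation of +2.6 degrees latitude /
#' +3.9 degrees longitude (roughly 300 km toward the northeast at the
#' habitat's latitude).
#'
#' @param seed Integer seed for the realisation.
#' @param res Analysis-grid resolution in degrees.
#' @param n_vessels,n_fixes Fleet size.
#' @param background_n Background sample size.
#' @param shift List with \code{dlat}, \code{dlon}: the niche translation.
#' @param tss_min Member-selection threshold.
#' @return One-row data.frame: \code{seed}, \code{n_presences},
#'   \code{sst_peak}, \code{chl_peak}, \code{top_variable},
#'   \code{ensemble_tss}, \code{median_member_tss}, \code{true_shift_km},
#'   \code{true_bearing_deg}, \code{recovered_shift_km},
#'   \code{recovered_bearing_deg}.
#' @export
niche_recovery_run <- function(seed, res = 1 / 4, n_vessels = 12,
                               n_fixes = 1440, background_n = 3000,
                               shift = list(dlat = 2.0, dlon = 3.0),
                               tss_min = 0.8) {
  g <- grid_spec(res = res)
  truth <- niche_truth()
  stack <- make_env_stack(g, seed = seed)
  fixes <- simulate_trajectories(stack, truth, n_vessels = n_vessels,
                                 n_fixes = n_fixes, seed = seed + 1)
  classed <- classify_fixes(fixes)
  presences <- spatial_thin(classed[classed$label == "fishing", ], g)
  background <- sample_background(g, background_n, seed = seed + 2)
  occ <- occurrence_set(presences, background, g)
  variables <- c("SST", "CHL", "SSS", "MLD", "CV")
  table <- build_model_table(occ, stack, variables)
  splits <- cv_split(table, seed = seed + 3)
  specs <- model_registry(seed = seed + 4)
  fits <- fit_members(table, specs, splits, variables)
  selection <- select_members(fits$evals, tss_min = tss_min)
  ens <- sdm_ensemble(fits, selection)
  skill <- ensemble_cv_skill(table, specs, splits, fits$evals,
                             tss_min = tss_min)
  imp <- variable_importance(ens, table, seed = seed + 5)
  sst_peak <- with(response_curve(ens, table, "SST"),
                   value[which.max(suitability)])
  chl_peak <- with(response_curve(ens, table, "CHL"),
                   value[which.max(suitability)])

  # Displacement is measured on noise-free evaluation stacks (the trend
  # fields), where the suitable band translates rigidly by the known offset:
  # the model is fitted on the noisy realisation, but evaluating it on the
  # expected fields isolates niche-recovery error from realisation noise,
  # which does not translate and would otherwise contaminate the truth
  # itself. Core-weighted centroids (suitability cubed) concentrate the
  # weight on the habitat core smoothly and identically for the generator's
  # suitability and the model's, keeping the comparison like-for-like.
  core_centroid <- function(map) {
    hsi_centroid(hsi_map(map$grid, map$hsi^3, tag = map$tag))
  }
  zero_noise <- list(SST = 0, CHL = 0, SSS = 0, MLD = 0, Uo = 0, Vo = 0)
  eval_base <- make_env_stack(g, seed = seed, noise_sd = zero_noise)
  delta <- shift_delta(shift$dlat, shift$dlon,
                       variables = c("SST", "CHL", "SSS", "MLD"))
  eval_shift <- apply_scenario(eval_base, delta)
  truth_disp <- centroid_displacement(
    core_centroid(true_suitability(eval_base, truth)),
    core_centroid(true_suitability(eval_shift, truth)))
  model_disp <- centroid_displacement(
    core_centroid(project_ensemble(ens, eval_base)),
    core_centroid(project_ensemble(ens, eval_shift)))

  data.frame(
    seed = seed,
    n_presences = nrow(presences),
    sst_peak = sst_peak,
    chl_peak = chl_peak,
    top_variable = imp$variable[which.max(imp$contribution_pct)],
    ensemble_tss = mean(skill$tss),
    ensemble_auc = mean(skill$auc),
    ensemble_sensitivity = mean(skill$sensitivity),
    ensemble_specificity = mean(skill$specificity),
    median_member_tss = stats::median(
      tapply(fits$evals$tss, fits$evals$model, mean)),
    true_shift_km = truth_disp$km,
    true_bearing_deg = truth_disp$bearing_deg,
    recovered_shift_km = model_disp$km,
    recovered_bearing_deg = model_disp$bearing_deg,
    stringsAsFactors = FALSE
  )
}

#' Multi-seed recovery experiment
#'
#' @param seeds Integer vector of seeds.
#' @param ... Passed to \code{\link{niche_recovery_run}}.
#' @return data.frame with one row per seed.
#' @export
recovery_experiment <- function(seeds = 1:10, ...) {
  do.call(rbind, lapply(seeds, function(s)
    suppressMessages(suppressWarnings(niche_recovery_run(s, ...)))))
}
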