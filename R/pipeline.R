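#' Default pipeline configuration
#'
#' Study conditions for a fully synthetic end-to-end run: the full 1/12-degree
#' study grid, a 20-vessel fleet with 2000 fixes each at a 10-minute cadence,
#' the default niche truth and threshold rule set, 5-run 80/20
#' cross-validation, TSS >= 0.8 member selection, and the TSS-weighted-mean
#' combiner. \code{background_n} is scaled to the synthetic problem (the
#' full-data fishery analysis uses 50000).
#'
#' @param ... Named overrides of any top-level entry.
#' @return Nested list; serialisable to YAML with \code{yaml::write_yaml}.
#' @export
default_config <- function(...) {
  cfg <- list(
    grid = list(lon_min = 135, lon_max = 180, lat_min = 30, lat_max = 65,
                res = 1 / 12),
    generator = list(n_vessels = 20, n_fixes = 2000, dt_min = 10,
                     p_fish = 0.95),
    rules = list(speed_min = 0.1, speed_max = 4.0, dheading_min = 30,
                 drift_speed = 1.0, night_start = 18, night_end = 6,
                 wave_max = 2.5),
    background_n = 5000,
    cv = list(runs = 5, train_fraction = 0.8),
    variables = c("SST", "CHL", "SSS", "MLD", "CV"),
    algorithms = c("GLM", "CTA", "GBM", "RF", "ANN", "SRE"),
    tss_min = 0.8,
    combiner = "EMwmean",
    scenarios = names(default_scenario_deltas()),
    transition_threshold = 0.4
  )
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Entries present in the file override the defaults of
#' \code{\link{default_config}}; everything else keeps its default, so a
#' config file only needs the entries it changes.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (sub in names(user[[nm]])) cfg[[nm]][[sub]] <- user[[nm]][[sub]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

#' Run the full habitat pipeline
#'
#' Orchestrates the chain simulate -> detect -> thin -> background -> VIF ->
#' cross-validated member fits -> selection/ensemble -> projection onto
#' baseline and scenario stacks -> zonal areas, transitions and centroid
#' shifts. Every stage is a pure function of (config, seed); rerunning with
#' the same arguments reproduces the manifest. Stage failures abort with the
#' stage name.
#'
#' @param config Configuration list (see \code{\link{default_config}}).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param out_dir Optional directory; when given, summary CSVs and the JSON
#'   manifest are written there.
#' @return Manifest list: per-stage record counts, the evaluation and
#'   selection tables, variable contributions, response-curve peaks, zonal
#'   areas, transition summaries and centroid displacements per scenario, and
#'   paths of written artifacts.
#' @export
run_pipeline <- function(config = default_config(), seed = 1,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  g <- stage("grid", do.call(grid_spec, config$grid))
  truth <- niche_truth()
  stack <- stage("simulate_env", make_env_stack(g, seed = seed))
  fixes <- stage("simulate_fleet", simulate_trajectories(
    stack, truth,
    n_vessels = config$generator$n_vessels,
    n_fixes = config$generator$n_fixes,
    seed = seed + 1, dt_min = config$generator$dt_min,
    p_fish = config$generator$p_fish))
  rules <- do.call(fishing_rules, config$rules)
  classed <- stage("detect", classify_fixes(fixes, rules))
  fishing_pts <- classed[classed$label == "fishing", ]
  presences <- stage("thin", spatial_thin(fishing_pts, g))
  background <- stage("background", sample_background(
    g, config$background_n, seed = seed + 2))
  occ <- occurrence_set(presences, background, g)
  table <- stage("extract", build_model_table(occ, stack, config$variables))
  vif_tab <- stage("vif", vif_screen(table, config$variables))
  splits <- stage("cv_split", cv_split(table, runs = config$cv$runs,
                                       train_fraction = config$cv$train_fraction,
                                       seed = seed + 3))
  specs <- model_registry(seed = seed + 4, algorithms = config$algorithms)
  fits <- stage("fit_members", fit_members(table, specs, splits,
                                           config$variables))
  selection <- stage("select", select_members(fits$evals,
                                              tss_min = config$tss_min))
  ens <- sdm_ensemble(fits, selection, combiner = config$combiner)
  ens_skill <- stage("ensemble_cv", ensemble_cv_skill(
    table, specs, splits, fits$evals, rule = config$combiner,
    tss_min = config$tss_min))
  imp <- stage("importance", variable_importance(ens, table,
                                                 seed = seed + 5))
  curves <- stage("response_curves", {
    out <- lapply(config$variables, function(v)
      cbind(variable = v, response_curve(ens, table, v)))
    do.call(rbind, out)
  })
  peaks <- do.call(rbind, lapply(split(curves, curves$variable), function(d)
    data.frame(variable = d$variable[1],
               peak_value = d$value[which.max(d$suitability)])))

  current_map <- stage("project_current", project_ensemble(ens, stack))
  cur_zones <- zone_areas(current_map)
  cur_centroid <- hsi_centroid(current_map)

  deltas <- default_scenario_deltas()[config$scenarios]
  scen_rows <- list(); trans_rows <- list(); cent_rows <- list()
  for (nm in names(deltas)) {
    fut_stack <- stage(paste0("scenario ", nm),
                       apply_scenario(stack, deltas[[nm]]))
    fut_map <- project_ensemble(ens, fut_stack)
    za <- zone_areas(fut_map)
    scen_rows[[nm]] <- cbind(scenario = nm,
                             as.data.frame(t(stats::setNames(za$area_km2,
                                                             za$zone))))
    tr <- transitions(current_map, fut_map,
                      threshold = config$transition_threshold)
    trans_rows[[nm]] <- cbind(scenario = nm,
                              as.data.frame(t(stats::setNames(tr$areas$pct,
                                                              tr$areas$category))))
    ct <- hsi_centroid(fut_map)
    dsp <- centroid_displacement(cur_centroid, ct)
    cent_rows[[nm]] <- data.frame(scenario = nm, lon = ct$lon, lat = ct$lat,
                                  displacement_km = dsp$km,
                                  bearing_deg = dsp$bearing_deg)
  }
  zone_tab <- rbind(cbind(scenario = "current",
                          as.data.frame(t(stats::setNames(cur_zones$area_km2,
                                                          cur_zones$zone)))),
                    do.call(rbind, scen_rows))
  rownames(zone_tab) <- NULL
  trans_tab <- do.call(rbind, trans_rows); rownames(trans_tab) <- NULL
  cent_tab <- do.call(rbind, cent_rows); rownames(cent_tab) <- NULL

  manifest <- list(
    seed = seed,
    counts = list(raw_fixes = nrow(fixes),
                  fishing_points = nrow(fishing_pts),
                  presences = nrow(presences),
                  background = nrow(background),
                  model_rows = nrow(table)),
    detection = detection_metrics(classed$label, classed$true_state),
    vif = vif_tab,
    member_evals = fits$evals,
    selection = list(selected = selection$selected,
                     weights = as.list(selection$weights),
                     mean_tss = as.list(selection$mean_tss)),
    ensemble_skill = ens_skill,
    importance = imp,
    response_peaks = peaks,
    zone_areas_km2 = zone_tab,
    transition_pct = trans_tab,
    centroids = list(current = cur_centroid, future = cent_tab),
    artifacts = character(0)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      member_evals = file.path(out_dir, "member_evals.csv"),
      importance = file.path(out_dir, "importance.csv"),
      response_curves = file.path(out_dir, "response_curves.csv"),
      zone_areas = file.path(out_dir, "zone_areas_km2.csv"),
      transitions = file.path(out_dir, "transition_pct.csv"),
      centroids = file.path(out_dir, "centroids.csv"),
      vif = file.path(out_dir, "vif.csv"),
      manifest = file.path(out_dir, "manifest.json"))
    utils::write.csv(fits$evals, paths["member_evals"], row.names = FALSE)
    utils::write.csv(imp, paths["importance"], row.names = FALSE)
    utils::write.csv(curves, paths["response_curves"], row.names = FALSE)
    utils::write.csv(zone_tab, paths["zone_areas"], row.names = FALSE)
    utils::write.csv(trans_tab, paths["transitions"], row.names = FALSE)
    utils::write.csv(cent_tab, paths["centroids"], row.names = FALSE)
    utils::write.csv(vif_tab, paths["vif"], row.names = FALSE)
    manifest$artifacts <- as.list(paths)
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  manifest
}
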