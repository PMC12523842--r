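test_that("suitability maps validate their range", {
  g <- grid_spec(135, 140, 30, 35, res = 1)
  expect_error(hsi_map(g, matrix(1.5, g$ny, g$nx)), "0, 1")
  m <- hsi_map(g, matrix(0.5, g$ny, g$nx))
  expect_s3_class(m, "hsi_map")
})

test_that("zone areas follow the left-closed bins and conserve total area", {
  g <- grid_spec(135, 145, 30, 40, res = 1 / 2)
  high <- zone_areas(hsi_map(g, matrix(0.9, g$ny, g$nx)))
  total <- sum(grid_row_areas(g)) * g$nx
  expect_equal(high$area_km2[high$zone == "High"], total, tolerance = 1e-9)
  expect_equal(sum(high$area_km2), total, tolerance = 1e-9)

  # 0.4 exactly belongs to the Low class (left-closed bins)
  low <- zone_areas(hsi_map(g, matrix(0.4, g$ny, g$nx)))
  expect_equal(low$area_km2[low$zone == "Low"], total, tolerance = 1e-9)
  # 1.0 exactly belongs to the top bin (closed above)
  top <- zone_areas(hsi_map(g, matrix(1, g$ny, g$nx)))
  expect_equal(top$area_km2[top$zone == "High"], total, tolerance = 1e-9)

  # random map equals a brute-force per-cell loop oracle
  h <- withr::with_seed(8, matrix(runif(g$ny * g$nx), g$ny, g$nx))
  h[3, 5] <- NA
  za <- zone_areas(hsi_map(g, h))
  areas <- grid_row_areas(g)
  oracle <- c(0, 0, 0, 0)
  edges <- c(0, 0.4, 0.6, 0.8, 1)
  for (i in seq_len(g$ny)) for (j in seq_len(g$nx)) {
    v <- h[i, j]
    if (is.na(v)) next
    k <- max(which(v >= edges[1:4]))
    oracle[k] <- oracle[k] + areas[i]
  }
  expect_equal(za$area_km2, oracle, tolerance = 1e-9)
  expect_equal(sum(za$area_km2),
               sum(areas) * g$nx - areas[3], tolerance = 1e-6)
  expect_error(zone_areas(hsi_map(g, matrix(NA_real_, g$ny, g$nx))),
               "missing")
})

test_that("transition maps partition the grid and sum to total area", {
  g <- grid_spec(135, 145, 30, 40, res = 1 / 2)
  cur <- hsi_map(g, withr::with_seed(1, matrix(runif(g$ny * g$nx),
                                               g$ny, g$nx)))
  # future identical to current: nothing improves or degrades
  same <- transitions(cur, cur)
  expect_equal(same$areas$area_km2[same$areas$category == "improvement"], 0)
  expect_equal(same$areas$area_km2[same$areas$category == "degradation"], 0)

  # all suitable -> all unsuitable: 100% degradation
  all1 <- hsi_map(g, matrix(0.9, g$ny, g$nx))
  all0 <- hsi_map(g, matrix(0.1, g$ny, g$nx))
  degr <- transitions(all1, all0)
  expect_equal(degr$areas$pct[degr$areas$category == "degradation"], 100)

  # random pair equals a cellwise enumeration oracle and partitions the area
  fut <- hsi_map(g, withr::with_seed(2, matrix(runif(g$ny * g$nx),
                                               g$ny, g$nx)))
  tr <- transitions(cur, fut)
  areas <- grid_row_areas(g)
  oracle <- c(improvement = 0, degradation = 0, `stable suitable` = 0,
              `stable unsuitable` = 0)
  for (i in seq_len(g$ny)) for (j in seq_len(g$nx)) {
    a <- cur$hsi[i, j] >= 0.4; b <- fut$hsi[i, j] >= 0.4
    k <- if (!a && b) "improvement" else if (a && !b) "degradation"
         else if (a && b) "stable suitable" else "stable unsuitable"
    oracle[k] <- oracle[k] + areas[i]
  }
  expect_equal(tr$areas$area_km2, unname(oracle[tr$areas$category]),
               tolerance = 1e-9)
  expect_equal(sum(tr$areas$area_km2), sum(areas) * g$nx, tolerance = 1e-6)
  expect_equal(sum(tr$areas$pct), 100, tolerance = 1e-9)
  expect_error(transitions(cur, hsi_map(grid_spec(135, 145, 30, 40, 1),
                                        matrix(0.5, 10, 10))), "match")
})

test_that("centroids sit at weighted cell centers", {
  g <- grid_spec(135, 140, 30, 35, res = 1)
  h <- matrix(0, g$ny, g$nx)
  h[2, 3] <- 0.8                 # single positive cell
  ct <- hsi_centroid(hsi_map(g, h))
  expect_equal(ct$lon, 137.5)
  expect_equal(ct$lat, 31.5)

  # two equal-weight cells at the same latitude: midpoint longitude
  h2 <- matrix(0, g$ny, g$nx)
  h2[3, c(1, 5)] <- 0.6
  ct2 <- hsi_centroid(hsi_map(g, h2))
  expect_equal(ct2$lon, (135.5 + 139.5) / 2)
  expect_equal(ct2$lat, 32.5)

  # binary mode ignores sub-threshold cells
  h3 <- h2; h3[1, 1] <- 0.2
  expect_equal(hsi_centroid(hsi_map(g, h3), mode = "binary")$lat, 32.5)

  expect_error(hsi_centroid(hsi_map(g, matrix(0, g$ny, g$nx))),
               "positive weight")
})

test_that("centroid displacement is a symmetric great-circle distance", {
  a <- list(lon = 155.8, lat = 41.5)
  b <- list(lon = 159.1, lat = 44.5)
  d <- centroid_displacement(a, b)
  expect_equal(d$km, haversine_km(155.8, 41.5, 159.1, 44.5))
  expect_gt(d$km, 400)                      # end-of-century-scale shift
  expect_true(d$bearing_deg > 0 && d$bearing_deg < 90)  # northeastward
  expect_equal(centroid_displacement(a, a)$km, 0)
  expect_equal(centroid_displacement(b, a)$km, d$km)
})

test_that("projection reproduces fitted scores and respects missing cells", {
  g <- grid_spec(140, 150, 48, 58, res = 1 / 2)
  st <- make_env_stack(g, seed = 21)
  tab <- separable_table()
  splits <- cv_split(tab, runs = 2, seed = 1)
  specs <- model_registry(seed = 1, algorithms = c("GLM", "RF"))
  fits <- fit_members(tab, specs, splits, variables = c("SST", "CHL"))
  sel <- select_members(fits$evals, tss_min = 0.5)
  ens <- sdm_ensemble(fits, sel)

  m <- project_ensemble(ens, st)
  full_tab <- data.frame(SST = as.vector(st$layers$SST),
                         CHL = as.vector(st$layers$CHL))
  expect_equal(as.vector(m$hsi), predict_ensemble(ens, full_tab),
               tolerance = 1e-12)

  st$layers$SST[4, 4] <- NA
  m2 <- project_ensemble(ens, st)
  expect_true(is.na(m2$hsi[4, 4]))
  expect_equal(sum(is.na(m2$hsi)), 1L)

  st$layers$SST <- NULL
  expect_error(project_ensemble(ens, st), "lacks predictor")
})

test_that("warming an already-warm SST-only niche never grows the High zone", {
  g <- grid_spec(135, 145, 30, 36, res = 1 / 2)
  zero <- list(SST = 0, CHL = 0, SSS = 0, MLD = 0, Uo = 0, Vo = 0)
  st <- make_env_stack(g, seed = 1, noise_sd = zero)
  truth <- niche_truth(data.frame(variable = "SST", optimum = 20,
                                  width = 2, weight = 1))
  # baseline SST >= 20.28 everywhere on this sub-extent: all cells sit at or
  # beyond the optimum, so warming can only push suitability down
  expect_true(all(st$layers$SST >= 20))
  high_area <- function(stack) {
    za <- zone_areas(true_suitability(stack, truth))
    za$area_km2[za$zone == "High"]
  }
  prev <- high_area(st)
  expect_gt(prev, 0)
  for (dT in c(0.5, 1, 2, 4)) {
    warmed <- apply_scenario(st, scenario_delta(
      terms = list(SST = list(add = dT))))
    cur <- high_area(warmed)
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})
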