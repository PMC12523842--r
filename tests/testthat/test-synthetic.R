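test_that("environmental stack generation is deterministic and physical", {
  g <- test_grid()
  a <- make_env_stack(g, seed = 3)
  b <- make_env_stack(g, seed = 3)
  expect_identical(a$layers, b$layers)
  d <- make_env_stack(g, seed = 4)
  expect_false(identical(a$layers$SST, d$layers$SST))

  expect_setequal(names(a$layers),
                  c("SST", "CHL", "SSS", "MLD", "Uo", "Vo", "CV"))
  expect_true(all(a$layers$CHL > 0))
  expect_true(all(a$layers$MLD >= 1))
  expect_true(all(a$layers$CV >= 0))
  # SST decreases with latitude on average despite noise
  expect_lt(mean(a$layers$SST[g$ny, ]), mean(a$layers$SST[1, ]))
})

test_that("a zero-noise stack has SST as a pure monotone function of latitude", {
  g <- test_grid()
  zero <- list(SST = 0, CHL = 0, SSS = 0, MLD = 0, Uo = 0, Vo = 0)
  st <- make_env_stack(g, seed = 1, noise_sd = zero)
  # constant along each row, strictly decreasing along each column
  expect_true(all(apply(st$layers$SST, 1, function(r) diff(range(r)) == 0)))
  expect_true(all(diff(st$layers$SST[, 1]) < 0))
})

test_that("true suitability is a bounded product of scaled Gaussians", {
  g <- grid_spec(135, 140, 30, 35, res = 1)
  at_opt <- constant_stack(g, optimum_values())
  expect_equal(max(true_suitability(at_opt, niche_truth())$hsi), 1)

  # SST far beyond optimum + width collapses suitability regardless of rest
  hot <- optimum_values(); hot$SST <- 30
  expect_lt(max(true_suitability(constant_stack(g, hot),
                                 niche_truth())$hsi), 0.01)

  # a single-variable truth is exactly that response applied cellwise
  solo <- niche_truth(data.frame(variable = "SST", optimum = 9.5,
                                 width = 1.5, weight = 1))
  st <- make_env_stack(test_grid(), seed = 8)
  expect_equal(true_suitability(st, solo)$hsi,
               gaussian_response(st$layers$SST, 9.5, 1.5))

  # missing layer errors
  st2 <- env_stack(g, list(SST = matrix(9.5, g$ny, g$nx)))
  expect_error(true_suitability(st2, niche_truth()), "lacks layer")
})

test_that("suitability stays in [0, 1] across many seeds", {
  g <- grid_spec(140, 160, 45, 60, res = 1)
  truth <- niche_truth()
  for (seed in 1:20) {
    s <- true_suitability(make_env_stack(g, seed = seed), truth)$hsi
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("scenario deltas perturb a copy and zero delta is the identity", {
  st <- make_env_stack(test_grid(), seed = 5)
  expect_identical(apply_scenario(st, scenario_delta()), st)

  plus2 <- scenario_delta(terms = list(SST = list(add = 2)))
  warmed <- apply_scenario(st, plus2)
  expect_equal(warmed$layers$SST, st$layers$SST + 2)
  expect_equal(warmed$layers$CHL, st$layers$CHL)  # untouched layer
  # the baseline object is unmodified
  expect_equal(st$tag, "current")

  expect_error(apply_scenario(st, scenario_delta(
    terms = list(NO2 = list(add = 1)))), "absent")
})

test_that("warming moves an SST isotherm poleward", {
  g <- test_grid()
  zero <- list(SST = 0, CHL = 0, SSS = 0, MLD = 0, Uo = 0, Vo = 0)
  st <- make_env_stack(g, seed = 1, noise_sd = zero)
  iso_lat <- function(stack) {
    col <- stack$layers$SST[, 1]
    g$lat[which.min(abs(col - 9.5))]
  }
  warmed <- apply_scenario(st, default_scenario_deltas()[["2100s SSP5-8.5"]])
  expect_gt(iso_lat(warmed), iso_lat(st))
})

test_that("shift deltas translate the suitable habitat by the requested offset", {
  g <- test_grid()
  zero <- list(SST = 0, CHL = 0, SSS = 0, MLD = 0, Uo = 0, Vo = 0)
  st <- make_env_stack(g, seed = 1, noise_sd = zero)
  truth <- niche_truth()
  shifted <- apply_scenario(st, shift_delta(2, 3, c("SST", "CHL")))
  c0 <- hsi_centroid(true_suitability(st, truth))
  c1 <- hsi_centroid(true_suitability(shifted, truth))
  expect_equal(c1$lat - c0$lat, 2, tolerance = 0.15)
  # the zonal background attenuates the longitudinal centroid shift, but the
  # direction and a substantial fraction of the offset must be there
  expect_gt(c1$lon - c0$lon, 1)
})

test_that("simulated fleets carry labelled states with the designed kinematics", {
  fleet <- test_fleet()
  expect_identical(fleet, simulate_trajectories(test_fleet_stack(),
                                                niche_truth(),
                                                n_vessels = 6, n_fixes = 800,
                                                seed = 12))
  expect_setequal(unique(fleet$true_state), c("fishing", "transit"))
  fish <- fleet[fleet$true_state == "fishing", ]
  trans <- fleet[fleet$true_state == "transit", ]
  expect_true(all(fish$sog_kn >= 0.1 & fish$sog_kn <= 4.0))
  expect_true(all(trans$sog_kn > 6))
  # fishing happens at night (local solar window)
  hr <- local_solar_hour(fish$timestamp, fish$lon)
  expect_true(all(hr >= 18 | hr < 6))
})

test_that("fishing concentrates in the top-decile suitability cells", {
  fleet <- test_fleet()
  st <- test_fleet_stack()
  S <- true_suitability(st, niche_truth())$hsi
  top <- S >= stats::quantile(S, 0.9)
  fish <- fleet[fleet$true_state == "fishing", ]
  idx <- cell_index(fish$lon, fish$lat, st$grid)
  in_top <- top[cbind(idx$cell_i + 1L, idx$cell_j + 1L)]
  # areal fraction of top-decile cells is 0.1; fishing should be far denser
  expect_gt(mean(in_top, na.rm = TRUE), 0.5)
})

test_that("an all-transit configuration emits no fishing fixes", {
  st <- test_fleet_stack()
  fleet <- simulate_trajectories(st, niche_truth(), n_vessels = 1,
                                 n_fixes = 300, seed = 2, p_fish = 0)
  expect_false(any(fleet$true_state == "fishing"))
})

test_that("a suitability-free grid is rejected as degenerate", {
  g <- grid_spec(135, 140, 30, 35, res = 1)
  frozen <- optimum_values(); frozen$SST <- 1e6   # response underflows to 0
  st <- constant_stack(g, frozen)
  expect_error(simulate_trajectories(st, niche_truth(), 1, 10, seed = 1),
               "degenerate")
})

test_that("trajectory CSV round-trips fixes with ISO-8601 timestamps", {
  fleet <- utils::head(test_fleet(), 50)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories_csv(fleet, path)
  line1 <- readLines(path, n = 2)[2]
  expect_match(line1, "\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z")
  back <- read_trajectories_csv(path)
  expect_equal(back$timestamp, fleet$timestamp)
  expect_equal(back$lon, fleet$lon)
  expect_equal(back$true_state, fleet$true_state)
})
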