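# Shared small fixtures, built in code.

# coarse study grid for unit tests (45 x 35 cells)
test_grid <- function() grid_spec(res = 1)

# tiny stack with constant layers at chosen values
constant_stack <- function(grid, values, tag = "current") {
  layers <- lapply(values, function(v) matrix(v, grid$ny, grid$nx))
  env_stack(grid, layers, tag = tag)
}

# values putting every niche variable exactly at its default optimum
optimum_values <- function() {
  rs <- niche_truth()$responses
  stats::setNames(as.list(rs$optimum), rs$variable)
}

# small labelled fleet on a coarse grid (memoised: several tests reuse it)
.fleet_cache <- new.env(parent = emptyenv())
test_fleet <- function() {
  if (is.null(.fleet_cache$fleet)) {
    st <- make_env_stack(grid_spec(res = 1 / 2), seed = 11)
    .fleet_cache$stack <- st
    .fleet_cache$fleet <- simulate_trajectories(st, niche_truth(),
                                                n_vessels = 6, n_fixes = 800,
                                                seed = 12)
  }
  .fleet_cache$fleet
}
test_fleet_stack <- function() {
  invisible(test_fleet())
  .fleet_cache$stack
}

# separable one-predictor model table: presence iff SST above a cut
separable_table <- function(n = 400, seed = 5) {
  withr::with_seed(seed, {
    sst <- runif(n, 0, 20)
    chl <- runif(n, 0, 1)
    data.frame(SST = sst, CHL = chl, pa = as.integer(sst > 10))
  })
}
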