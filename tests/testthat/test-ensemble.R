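test_that("cross-validation splits are stratified, disjoint and seeded", {
  occ <- data.frame(role = rep(c("presence", "background"), c(100, 400)))
  sp <- cv_split(occ, runs = 5, seed = 9)
  expect_length(sp, 5)
  for (s in sp) {
    expect_setequal(c(s$train, s$test), 1:500)
    expect_length(intersect(s$train, s$test), 0)
    # 20% of 100 presences in every test fold
    expect_equal(sum(s$test <= 100), 20)
    expect_equal(sum(s$train <= 100), 80)
  }
  expect_identical(sp, cv_split(occ, runs = 5, seed = 9))
  few <- data.frame(role = rep(c("presence", "background"), c(5, 400)))
  expect_error(cv_split(few), "at least 10")
})

test_that("threshold optimisation reproduces reference sensitivity/specificity", {
  # confusion constructed so the optimum sits at sens 96.3%, spec 93.0%
  scores <- c(rep(0.9, 963), rep(0.1, 37),    # presences
              rep(0.1, 930), rep(0.9, 70))    # background
  labels <- rep(c(1, 0), c(1000, 1000))
  ev <- evaluate_scores(scores, labels)
  expect_equal(ev$sensitivity, 0.963)
  expect_equal(ev$specificity, 0.930)
  expect_equal(ev$tss, 0.893)
  expect_equal(ev$tss, ev$sensitivity + ev$specificity - 1)
})

test_that("perfect separation yields TSS 1 and AUC 1; identity always holds", {
  ev <- evaluate_scores(c(0.8, 0.9, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(ev$tss, 1)
  expect_equal(ev$auc, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  for (seed in 1:10) {
    d <- withr::with_seed(seed, list(s = runif(80),
                                     y = rbinom(80, 1, 0.3)))
    if (sum(d$y) %in% c(0, 80)) next
    e <- evaluate_scores(d$s, d$y)
    expect_equal(e$tss, e$sensitivity + e$specificity - 1, tolerance = 1e-12)
  }
  expect_error(evaluate_scores(runif(5), rep(1, 5)), "both classes")
})

test_that("rank AUC equals the all-pairs oracle, ties counted half", {
  pair_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
  }
  for (seed in 1:10) {
    d <- withr::with_seed(seed, {
      n <- sample(50:300, 1)
      list(s = round(runif(n), 2),             # heavy ties
           y = rbinom(n, 1, 0.4))
    })
    if (sum(d$y) %in% c(0, length(d$y))) next
    expect_equal(auc_rank(d$s, d$y), pair_auc(d$s, d$y), tolerance = 1e-12)
  }
  # large random instance sits near 0.5
  d <- withr::with_seed(99, list(s = runif(2000), y = rbinom(2000, 1, 0.5)))
  expect_lt(abs(auc_rank(d$s, d$y) - 0.5), 0.05)
})

test_that("paired metric test matches the textbook formula and degenerates cleanly", {
  a <- c(0.81, 0.85, 0.88, 0.83, 0.86)
  b <- c(0.80, 0.82, 0.90, 0.80, 0.84)
  out <- paired_metric_test(a, b)
  d <- a - b
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  expect_equal(out$t, t_oracle, tolerance = 1e-12)
  expect_equal(out$df, 4)
  expect_equal(out$p_value,
               2 * stats::pt(-abs(t_oracle), df = 4), tolerance = 1e-12)
  expect_false(out$degenerate)

  same <- paired_metric_test(a, a)
  expect_equal(same$t, 0)
  expect_true(same$degenerate)
  const <- paired_metric_test(a + 0.1, a)
  expect_equal(const$t, Inf)
  expect_equal(const$mean_diff, 0.1)
})

test_that("members separate a separable problem and not a shuffled one", {
  tab <- separable_table()
  splits <- cv_split(tab, runs = 2, seed = 1)
  specs <- model_registry(seed = 1)
  fits <- suppressWarnings(fit_members(tab, specs, splits,
                                       variables = c("SST", "CHL")))
  expect_length(fits$failed, 0)
  mean_tss <- tapply(fits$evals$tss, fits$evals$model, mean)
  # the envelope model trims 5% of presences by construction, so its ceiling
  # sits near 0.95; every other learner should be essentially perfect
  expect_true(all(mean_tss > 0.85))
  expect_true(all(mean_tss[setdiff(names(mean_tss), "SRE")] > 0.95))

  shuffled <- tab
  shuffled$pa <- withr::with_seed(2, sample(shuffled$pa))
  fits0 <- suppressWarnings(fit_members(shuffled, specs,
                                        cv_split(shuffled, runs = 2,
                                                 seed = 1),
                                        variables = c("SST", "CHL")))
  expect_lt(mean(fits0$evals$tss), 0.25)

  # deterministic given the same seeds
  fits_b <- suppressWarnings(fit_members(tab, specs, splits,
                                         variables = c("SST", "CHL")))
  expect_equal(fits$evals, fits_b$evals)
})

test_that("combiners follow their definitions and bounds", {
  sm <- rbind(c(0.2, 0.4, 0.9),
              c(0.1, 0.5, 0.3))
  # weighted mean with TSS 0.8 / 0.9 / 1.0 at values 0.2 / 0.4 / 0.9
  w <- c(0.8, 0.9, 1.0) / sum(c(0.8, 0.9, 1.0))
  expect_equal(combine_scores(sm, "EMwmean", weights = w)[1],
               (0.8 * 0.2 + 0.9 * 0.4 + 1.0 * 0.9) / 2.7,
               tolerance = 1e-12)
  expect_equal(combine_scores(sm, "EMmean"), rowMeans(sm))
  expect_equal(combine_scores(sm, "EMmedian"), c(0.4, 0.3))
  expect_equal(combine_scores(sm, "EMca", thresholds = c(0.15, 0.45, 0.5)),
               c(mean(c(1, 0, 1)), mean(c(0, 1, 0))))

  # a single member is returned unchanged by every rule
  one <- matrix(c(0.3, 0.8), ncol = 1)
  expect_equal(combine_scores(one, "EMmean"), c(0.3, 0.8))
  expect_equal(combine_scores(one, "EMmedian"), c(0.3, 0.8))
  expect_equal(combine_scores(one, "EMwmean", weights = 1), c(0.3, 0.8))

  # equal weights make EMwmean collapse onto EMmean
  expect_equal(combine_scores(sm, "EMwmean", weights = rep(1 / 3, 3)),
               combine_scores(sm, "EMmean"))

  # bounds: member envelope for the averaging rules, [0, 1] for EMca
  big <- withr::with_seed(5, matrix(runif(300), 100, 3))
  for (rule in c("EMmean", "EMmedian")) {
    out <- combine_scores(big, rule)
    expect_true(all(out >= apply(big, 1, min) - 1e-12))
    expect_true(all(out <= apply(big, 1, max) + 1e-12))
  }
  ca <- combine_scores(big, "EMca", thresholds = c(0.3, 0.5, 0.7))
  expect_true(all(ca >= 0 & ca <= 1))
})

test_that("selection applies the mean-TSS rule and normalises weights", {
  evals <- data.frame(model = rep(c("A", "B", "C"), each = 2),
                      run = rep(1:2, 3),
                      tss = c(0.85, 0.95, 0.70, 0.75, 0.92, 0.88),
                      threshold = 0.5)
  sel <- select_members(evals)
  expect_setequal(sel$selected, c("A", "C"))
  expect_equal(sum(sel$weights), 1)
  expect_equal(unname(sel$weights["A"] / sel$weights["C"]), 0.9 / 0.9)
  expect_error(select_members(evals, tss_min = 0.99), "selection rule")
})

test_that("permutation importance isolates used and ignored variables", {
  # an envelope member with an unbounded window on one variable provably
  # ignores it; the bounded variable carries all the contribution
  member <- structure(list(
    algorithm = "SRE",
    fit = list(envelope = list(SST = c(8, 11), CHL = c(-Inf, Inf))),
    variables = c("SST", "CHL"), seed = 1), class = "sdm_member")
  tab <- withr::with_seed(3, data.frame(SST = runif(300, 0, 20),
                                        CHL = runif(300, 0, 1)))
  imp <- variable_importance(member, tab, seed = 4, permutations = 3)
  expect_equal(imp$contribution_pct[imp$variable == "SST"], 100)
  expect_equal(imp$contribution_pct[imp$variable == "CHL"], 0)
})

test_that("response curves sweep one variable at fixed strip conditions", {
  member <- structure(list(
    algorithm = "SRE",
    fit = list(envelope = list(SST = c(10, 25), CHL = c(-Inf, Inf))),
    variables = c("SST", "CHL"), seed = 1), class = "sdm_member")
  tab <- data.frame(SST = seq(0, 20, length.out = 50),
                    CHL = runif(50))
  rc <- response_curve(member, tab, "SST", n_points = 40)
  expect_equal(nrow(rc), 40)
  # a step envelope yields a monotone (non-decreasing) curve over this range
  expect_true(all(diff(rc$suitability) >= 0))
  expect_true(all(rc$suitability >= 0 & rc$suitability <= 1))

  one <- response_curve(member, tab, "SST", n_points = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$value, mean(range(tab$SST)))
})
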