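#!/usr/bin/env Rscript
# Stage 4 — ensemble fitting and evaluation.
#
# Five runs of 80/20 random cross-validation for every registry member,
# paired t-tests between members on the per-run TSS, selection at mean TSS
# >= 0.8, TSS-weighted ensemble assembly, permutation variable importance,
# and response curves. Writes the evaluation tables a reader would check
# first: member skill, pairwise comparisons, contributions, curves.

library(sauryhab)

seed <- 1
table <- utils::read.csv("results/model_table.csv")
variables <- c("SST", "CHL", "SSS", "MLD", "CV")

splits <- cv_split(table, runs = 5, seed = seed + 3)
specs <- model_registry(seed = seed + 4)
fits <- fit_members(table, specs, splits, variables)

mean_tss <- sort(tapply(fits$evals$tss, fits$evals$model, mean),
                 decreasing = TRUE)
message("mean CV TSS by member:")
print(round(mean_tss, 3))

# pairwise paired t-tests on per-run TSS (raw p-values, as reported)
members <- names(mean_tss)
pairs <- t(utils::combn(members, 2))
ttests <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
  a <- fits$evals$tss[fits$evals$model == pairs[k, 1]]
  b <- fits$evals$tss[fits$evals$model == pairs[k, 2]]
  tt <- paired_metric_test(a, b)
  data.frame(model_a = pairs[k, 1], model_b = pairs[k, 2],
             mean_diff = tt$mean_diff, t = tt$t, p_value = tt$p_value)
}))

selection <- select_members(fits$evals, tss_min = 0.8)
message(sprintf("selected (TSS >= 0.8): %s",
                paste(selection$selected, collapse = ", ")))
ens <- sdm_ensemble(fits, selection, combiner = "EMwmean")

skill <- ensemble_cv_skill(table, specs, splits, fits$evals)
message(sprintf("EMwmean held-out: TSS %.3f, AUC %.3f (members' median TSS %.3f)",
                mean(skill$tss), mean(skill$auc), stats::median(mean_tss)))

imp <- variable_importance(ens, table, seed = seed + 5)
print(imp[order(-imp$contribution_pct), ])

curves <- do.call(rbind, lapply(variables, function(v)
  cbind(variable = v, response_curve(ens, table, v))))
peaks <- vapply(split(curves, curves$variable),
                function(d) d$value[which.max(d$suitability)], numeric(1))
message("response-curve peaks:")
print(round(peaks, 3))

utils::write.csv(fits$evals, "results/member_evals.csv", row.names = FALSE)
utils::write.csv(ttests, "results/member_ttests.csv", row.names = FALSE)
utils::write.csv(imp, "results/importance.csv", row.names = FALSE)
utils::write.csv(curves, "results/response_curves.csv", row.names = FALSE)
utils::write.csv(skill, "results/ensemble_cv_skill.csv", row.names = FALSE)
dir.create("scratch", showWarnings = FALSE)
saveRDS(ens, "scratch/ensemble.rds")   # scratch: binary, session-local
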