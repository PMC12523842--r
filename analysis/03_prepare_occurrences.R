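#!/usr/bin/env Rscript
# Stage 3 — occurrence preparation and predictor screening.
#
# Thins the clustered fishing points to one presence per grid cell, samples
# background (pseudo-absence) cells over the full study extent, extracts the
# predictor values at every occurrence cell, and runs the VIF collinearity
# screen that justifies keeping all five predictors.

library(sauryhab)

seed <- 1
g <- grid_spec(res = 1 / 4)
stack <- read_stack_csv("results/env_stack_current.csv")
fishing <- utils::read.csv("results/fishing_points.csv")

presences <- spatial_thin(fishing, g)
message(sprintf("thinned %d fishing points to %d presences (%.1f : 1)",
                nrow(fishing), nrow(presences),
                nrow(fishing) / nrow(presences)))

background <- sample_background(g, 3000, seed = seed + 2)
occ <- occurrence_set(presences, background, g)
table <- build_model_table(occ, stack)

vif_tab <- vif_screen(table, c("SST", "CHL", "SSS", "MLD", "CV"))
print(vif_tab)
stopifnot(all(vif_tab$pass_lt_threshold))

utils::write.csv(occ, "results/occurrences.csv", row.names = FALSE)
utils::write.csv(table, "results/model_table.csv", row.names = FALSE)
utils::write.csv(vif_tab, "results/vif.csv", row.names = FALSE)
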