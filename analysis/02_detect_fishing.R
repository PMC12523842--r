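#!/usr/bin/env Rscript
# Stage 2 — fishing-activity identification.
#
# Applies the conservative threshold rule set (speed 0.1-4.0 kn, heading
# change >= 30 deg or drifting below 1 kn, local-solar night, wave height
# < 2.5 m) to the raw fixes and scores the labels against the generator's
# ground truth. On real AIS data the same call produces the fishing points
# without any scoring, since no truth column exists.

library(sauryhab)

fixes <- read_trajectories_csv("results/trajectories.csv")
out <- classify_fixes(fixes, fishing_rules())

m <- detection_metrics(out$label, out$true_state)
message(sprintf("detected %d fishing fixes of %d (precision %.3f, recall %.3f)",
                sum(out$label == "fishing"), nrow(out),
                m$precision, m$recall))

utils::write.csv(out[out$label == "fishing", ],
                 "results/fishing_points.csv", row.names = FALSE)
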