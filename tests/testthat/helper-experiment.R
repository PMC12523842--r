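# The multi-seed recovery experiment is the backbone of the stochastic
# acceptance checks (niche recovery, centroid recovery, ensemble
# superiority). It is expensive, so it runs once per session and the blocks
# share the result.
.experiment_cache <- new.env(parent = emptyenv())
acceptance_experiment <- function() {
  if (is.null(.experiment_cache$result))
    .experiment_cache$result <- recovery_experiment(seeds = 1:10)
  .experiment_cache$result
}
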