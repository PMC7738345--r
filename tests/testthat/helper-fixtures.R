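# shared fixtures: a small simulated dataset with split, built once per run
small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 1)
      samples <- generate_samples(cfg)
      ref <- build_reference(samples, select_standard(generate_yields(cfg)))
      diffs <- split_train_validation(compute_differences(samples, ref), seed = 2)
      cache <<- list(cfg = cfg, samples = samples, ref = ref, diffs = diffs)
    }
    cache
  }
})

# printed per-treatment yield table used throughout the campaign
observed_yields <- function() {
  data.frame(treatment = c(0, 50, 100, 150),
             yield = c(261.99, 342.66, 387.15, 333.60))
}
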