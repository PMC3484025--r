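# replicate machinery for calibration/power studies over simulated
# datasets, shared by the statistical test blocks

replicate_empirical_p <- function(theta, n_rep, seed0,
                                  n_universe = 50000, n_hits = 500,
                                  n_sets = 500, q = 0.05) {
  vapply(seq_len(n_rep), function(i) {
    scfg <- sim_config(n_universe = n_universe, n_hits = n_hits,
                       eqtl_base_rate = q, tissues = "parietal",
                       analyses = "a1", enrichment_multiplier = theta,
                       seed = seed0 + i)
    b <- simulate_study(scfg)
    run_enrichment(b$hit_lists[[1]], b$eqtl_map$parietal, "parietal",
                   b$universe,
                   enrichment_config(n_null_sets = n_sets,
                                     seed = seed0 + 100000 + i)
    )$empirical_p
  }, 0)
}

# the theta = 1 batch at full study scale is used by two test blocks;
# compute it once per session
.calibration_cache <- new.env(parent = emptyenv())
calibration_ps <- function() {
  if (is.null(.calibration_cache$ps)) {
    .calibration_cache$ps <- replicate_empirical_p(1, 200, seed0 = 31000)
  }
  .calibration_cache$ps
}
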