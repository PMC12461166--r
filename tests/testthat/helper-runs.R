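# Desk-scale signal-recovery experiments shared by the acceptance tests.
# Study conditions: 300 patients, effect size 2 SD, hidden size 32, up to 55
# epochs; training uses a single 80/20 patient-level holdout. Results are
# cached so both acceptance blocks that need a run reuse it.
signal_recovery_run <- local({
  cache <- new.env(parent = emptyenv())
  function(arm, null = FALSE) {
    key <- paste0(arm, if (null) "_null" else "_strong")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- simulation_config(n_patients = 300L, effect_size = 2, seed = 11L)
    ch <- if (null) null_cohort(cfg) else simulate_cohort(cfg)
    rep <- holdout_experiment(
      ch,
      model_config(arm, hidden_size = 32L),
      train_config(learning_rate = 3e-3, seed = 5L),
      seed = 1L
    )
    cache[[key]] <- rep
    rep
  }
})
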