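# 20 full-size replicate simulations at the calibrated defaults, shared by
# the parameter-recovery and outlier-rate acceptance checks. Computed once
# per test session.
replicate_sims <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    res <- lapply(1:20, function(s) {
      trials <- simulate_experiment(sim_params(), n_participants = 28,
                                    seed = 100 + s)
      filt <- filter_outliers(trials, k = 3)
      swf <- summary_wf(weber_fractions(cell_statistics(filt$kept)),
                        c(5, 8))
      cond <- dplyr::summarise(dplyr::group_by(swf, task, arrangement),
                               wf = mean(wf), .groups = "drop")
      dac <- delta_ac_table(attentional_cost_table(swf))
      dmean <- tapply(dac$delta_ac, dac$dual_task, mean)
      list(cond = cond, dac = dmean,
           removal_fraction = filt$removal_fraction)
    })
    cache <<- res
    res
  }
})
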