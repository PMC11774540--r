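# groupitize

Simulation and analysis of **groupitizing**: the gain in numerosity-estimation
precision when the items of an array are spatially clustered into small,
subitizable subgroups rather than scattered at random.

The package is built for dual-task studies of this effect. Participants
estimate the numerosity of grouped and ungrouped arrays either with full
attention (single task, with or without to-be-ignored distractors) or while
performing a concurrent auditory, visuo-spatial, or arithmetic task. The
analysis chain it implements, end to end:

* **Weber fraction** — precision via scalar variability,
  `Wf = SD_i / N`, the response SD normalised by the physical numerosity;
* **Attentional cost** — the normalised percent precision loss from single
  (ST) to dual (DT) task,
  `AC = (Wf_DT − Wf_ST) / (Wf_ST + Wf_DT) × 100`;
* **Delta attentional cost** — the headline statistic,
  `ΔAC = AC_grouped − AC_ungrouped`, positive when the concurrent task
  hurts grouped arrays more (evidence that grouping recruits extra
  attention-dependent machinery).

Around this core it provides:

* a stimulus generator for the calibrated geometry (106-position grid for
  ungrouped arrays; four quadrants × 12 slots and a 36-entry subgroup
  configuration table for grouped arrays);
* a synthetic observer emitting the full 1296-trial design per participant
  with condition-specific Weber fractions, estimation bias, rare wild
  "lapse" trials and concurrent-task accuracy — so the whole pipeline is
  testable without any data download;
* the precision pipeline (3-SD outlier filter, per-cell statistics, Weber
  fractions, summary precision, AC, ΔAC);
* the inferential suite: repeated-measures ANOVA with Mauchly's test and
  Greenhouse–Geisser correction, Bonferroni post-hoc paired t tests with
  Cohen's d, JZS log₁₀ Bayes factors, BIC inclusion Bayes factors, PCA with
  oblimin rotation, and noncentral-t power tools for paired designs.

## Worked example

One call simulates a 28-participant experiment and runs the complete
analysis:

```r
library(groupitize)
res <- run_end_to_end(run_config(seed = 7, n_participants = 28))
res
#> <groupitize_run>
#>   36288 trials, 28 participants, seed 7; 0.65% removed as outliers
#>   mean summary Wf by condition:
#>     arithm_dt          grouped    0.200
#>     arithm_dt          ungrouped  0.147
#>     aud_dt             grouped    0.158
#>     aud_dt             ungrouped  0.141
#>     single             grouped    0.098
#>     single             ungrouped  0.119
#>     single_distractor  grouped    0.101
#>     vsp_dt             grouped    0.216
#>     vsp_dt             ungrouped  0.146
#>   delta AC tests (alpha = 0.0167):
#>     delta_ac aud_dt vs 0     mean  12.43%  t(27) =  2.47, p = 0.02027
#>     delta_ac vsp_dt vs 0     mean  23.73%  t(27) =  4.24, p = 0.000233 *
#>     delta_ac arithm_dt vs 0  mean  20.26%  t(27) =  4.25, p = 0.0002293 *
#>   PCA (grouped vsp/arithm Wfs): 2 components, 74% variance
```

Reading the output: single-task precision is better (lower Wf) for grouped
(0.098) than ungrouped (0.119) arrays — the groupitizing advantage. Under
dual tasks Weber fractions rise for both arrangements but far more for
grouped arrays, so ΔAC is positive everywhere; at the Bonferroni-adjusted
α = 0.05/3 ≈ 0.017, ΔAC differs from zero for the visuo-spatial and
arithmetic concurrent tasks but not the auditory one, and the PCA of the
grouped visuo-spatial/arithmetic Weber fractions separates into two
components — the two interference sources are not one shared visual
bottleneck. All intermediate tables (`res$wfs`, `res$attentional_cost`,
`res$delta_ac`, `res$ac_anova`, ...) are tidy data frames; passing
`out_dir` to `run_config()` writes them as CSV together with a provenance
log sufficient to rerun the analysis exactly.

Individual pieces compose just as well:

```r
trials <- simulate_experiment(n_participants = 28, seed = 1)
kept   <- filter_outliers(trials, k = 3)$kept
wfs    <- weber_fractions(cell_statistics(kept))
swf    <- summary_wf(wfs, range = c(5, 8))
dac    <- delta_ac_table(attentional_cost_table(swf))
one_sample_t(dac$delta_ac[dac$dual_task == "vsp_dt"], alpha = 0.05 / 3)
```

A thin command-line wrapper for shell use lives at
`inst/cli/groupitize.R` (subcommands `gen-stimuli`, `simulate`, `analyze`,
`run`).

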