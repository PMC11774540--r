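#' Configuration of an end-to-end run
#'
#' @param seed Root seed for the simulation.
#' @param n_participants Number of simulated participants.
#' @param params Simulator parameters ([sim_params()]).
#' @param summary_range Numerosity range for the summary precision index and
#'   all attentional-cost computations (default 5-8, the range showing the
#'   groupitizing advantage).
#' @param single_task_range Numerosity range for the single-task grouping
#'   comparison (default 5-16, the full tested range).
#' @param outlier_k SD multiplier of the outlier filter.
#' @param m_single_posthoc Bonferroni family size for the single-task
#'   post-hoc comparisons (3: ungrouped vs grouped vs grouped-with-
#'   distractors).
#' @param m_delta_ac Bonferroni family size for the delta-attentional-cost
#'   tests against zero (3 dual tasks; alpha = 0.05 / 3 = 0.017).
#' @param alpha Base significance level.
#' @param out_dir Optional directory; when given, all result tables and a
#'   provenance log are written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, n_participants = 28, params = sim_params(),
                       summary_range = c(5, 8),
                       single_task_range = c(5, 16), outlier_k = 3,
                       m_single_posthoc = 3, m_delta_ac = 3, alpha = 0.05,
                       out_dir = NULL) {
  stopifnot(inherits(params, "sim_params"), n_participants >= 1,
            length(summary_range) == 2, length(single_task_range) == 2,
            alpha > 0, alpha < 1)
  structure(
    list(seed = as.integer(seed), n_participants = as.integer(n_participants),
         params = params, summary_range = summary_range,
         single_task_range = single_task_range, outlier_k = outlier_k,
         m_single_posthoc = m_single_posthoc, m_delta_ac = m_delta_ac,
         alpha = alpha, out_dir = out_dir),
    class = "run_config"
  )
}

.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline: simulate, filter, Weber fractions, attentional
#' cost, statistics
#'
#' Orchestrates one reproducible analysis: simulation (or a supplied trial
#' table), 3-SD outlier filtering, per-cell statistics, Weber fractions,
#' summary precision, attentional costs, delta attentional costs, the
#' single-task grouping comparison, the arrangement x dual-task ANOVA on
#' attentional cost (with BIC inclusion Bayes factors), one-sample delta-AC
#' tests at the Bonferroni-adjusted alpha, the PCA of grouped visuo-spatial
#' and arithmetic dual-task Weber fractions, and the perceived-numerosity
#' table. Deterministic given the configuration.
#'
#' @param config A [run_config()].
#' @param trials Optional trial table to analyse instead of simulating.
#' @return A list of class `groupitize_run` with elements `trials`,
#'   `filter`, `cells`, `wfs`, `summary_wf`, `summary_wf_full`,
#'   `attentional_cost`, `delta_ac`, `single_task_posthoc`, `ac_anova`,
#'   `ac_inclusion_bf`, `delta_ac_tests`, `pca`, `perceived`, `provenance`.
#' @export
run_end_to_end <- function(config = run_config(), trials = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(trials)) {
    trials <- .with_stage("simulate",
      simulate_experiment(config$params, config$n_participants, config$seed))
  } else {
    .with_stage("validate", validate_trials(trials))
  }
  filt <- .with_stage("filter_outliers",
                      filter_outliers(trials, config$outlier_k))
  cells <- .with_stage("cell_statistics", cell_statistics(filt$kept))
  wfs <- .with_stage("weber_fractions", weber_fractions(cells))
  swf <- .with_stage("summary_wf", summary_wf(wfs, config$summary_range))
  swf_full <- .with_stage("summary_wf",
                          summary_wf(wfs, config$single_task_range))
  ac <- .with_stage("attentional_cost", attentional_cost_table(swf))
  dac <- .with_stage("delta_ac", delta_ac_table(ac))

  # single-task grouping comparison over the full numerosity range
  single_wide <- .with_stage("single_task_posthoc", {
    st <- swf_full[swf_full$task %in% c("single", "single_distractor"), ]
    st$condition <- ifelse(st$task == "single_distractor",
                           "grouped_distractor", st$arrangement)
    tidyr::pivot_wider(st[, c("participant", "condition", "wf")],
                       names_from = "condition", values_from = "wf")
  })
  posthoc <- .with_stage("single_task_posthoc", posthoc_paired_t(
    single_wide[, c("ungrouped", "grouped", "grouped_distractor")],
    m = config$m_single_posthoc))

  ac_anova <- .with_stage("ac_anova",
    rm_anova(ac, "ac", c("arrangement", "dual_task"), "participant"))
  ac_bf <- .with_stage("ac_anova",
    bic_inclusion_bf(ac, "ac", c("arrangement", "dual_task"), "participant"))

  alpha_dac <- config$alpha / config$m_delta_ac
  dac_tests <- .with_stage("delta_ac_tests", dplyr::bind_rows(lapply(
    c("aud_dt", "vsp_dt", "arithm_dt"), function(task) {
      one_sample_t(dac$delta_ac[dac$dual_task == task], mu = 0,
                   alpha = alpha_dac, m = config$m_delta_ac,
                   label = paste0("delta_ac ", task, " vs 0"))
    })))

  pca <- .with_stage("pca", {
    sub <- wfs[wfs$arrangement == "grouped" &
                 wfs$task %in% c("vsp_dt", "arithm_dt") &
                 wfs$numerosity >= config$summary_range[1] &
                 wfs$numerosity <= config$summary_range[2], ]
    sub$var <- paste0(sub$task, "_N", sub$numerosity)
    wide <- tidyr::pivot_wider(sub[, c("participant", "var", "wf")],
                               names_from = "var", values_from = "wf")
    pca_oblimin(wide[, -1])
  })

  perceived <- .with_stage("perceived_numerosity",
                           perceived_numerosity(cells, config$summary_range))

  provenance <- list(
    package = "groupitize",
    version = as.character(utils::packageVersion("groupitize")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_participants = config$n_participants,
    params = unclass(config$params),
    summary_range = config$summary_range,
    single_task_range = config$single_task_range,
    outlier_k = config$outlier_k,
    alpha_delta_ac = alpha_dac,
    n_trials = nrow(trials),
    n_removed = nrow(filt$removed),
    removal_fraction = filt$removal_fraction
  )

  res <- structure(
    list(trials = trials, filter = filt, cells = cells, wfs = wfs,
         summary_wf = swf, summary_wf_full = swf_full,
         attentional_cost = ac, delta_ac = dac,
         single_task_posthoc = posthoc, ac_anova = ac_anova,
         ac_inclusion_bf = ac_bf, delta_ac_tests = dac_tests, pca = pca,
         perceived = perceived, provenance = provenance),
    class = "groupitize_run"
  )
  if (!is.null(config$out_dir)) .write_run(res, config$out_dir)
  res
}

.write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    readr::write_csv(df, file.path(out_dir, name), na = "NA", eol = "\n")
  write_trials(res$trials, file.path(out_dir, "trials.csv"))
  w(res$cells, "cell_statistics.csv")
  w(res$wfs, "weber_fractions.csv")
  w(res$summary_wf, "summary_wf.csv")
  w(res$attentional_cost, "attentional_cost.csv")
  w(res$delta_ac, "delta_ac.csv")
  w(res$single_task_posthoc, "single_task_posthoc.csv")
  w(res$ac_anova, "ac_anova.csv")
  w(res$ac_inclusion_bf, "ac_inclusion_bf.csv")
  w(res$delta_ac_tests, "delta_ac_tests.csv")
  w(res$perceived, "perceived_numerosity.csv")
  loadings <- tibble::as_tibble(res$pca$loadings, rownames = "variable")
  w(loadings, "pca_loadings.csv")
  jsonlite::write_json(res$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.groupitize_run <- function(x, ...) {
  cat("<groupitize_run>\n")
  cat(sprintf("  %d trials, %d participants, seed %d; %.2f%% removed as outliers\n",
              x$provenance$n_trials, x$provenance$n_participants,
              x$provenance$seed, 100 * x$provenance$removal_fraction))
  msum <- x$summary_wf %>%
    dplyr::group_by(.data$task, .data$arrangement) %>%
    dplyr::summarise(wf = mean(.data$wf), .groups = "drop")
  cat("  mean summary Wf by condition:\n")
  for (i in seq_len(nrow(msum)))
    cat(sprintf("    %-18s %-10s %.3f\n", msum$task[i], msum$arrangement[i],
                msum$wf[i]))
  cat(sprintf("  delta AC tests (alpha = %.4f):\n",
              x$provenance$alpha_delta_ac))
  dt <- x$delta_ac_tests
  for (i in seq_len(nrow(dt)))
    cat(sprintf("    %-24s mean %6.2f%%  t(%d) = %5.2f, p = %.4g%s\n",
                dt$comparison[i], dt$mean[i], dt$df[i], dt$t[i], dt$p[i],
                ifelse(dt$significant[i], " *", "")))
  cat(sprintf("  PCA (grouped vsp/arithm Wfs): %d components, %.0f%% variance\n",
              x$pca$n_components, x$pca$pct_variance))
  invisible(x)
}
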