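#' Remove outlier trials by the 3-SD rule
#'
#' A trial is an outlier when its response deviates from the cell mean
#' (cell = participant x task x arrangement x numerosity) by more than
#' `k` standard deviations of that cell, or when its response time deviates
#' from the participant x task mean by more than `k` standard deviations
#' (response times are pooled over numerosity since they do not scale with
#' it the way responses do). Two-sided, single pass; cells with zero spread
#' never flag anything.
#'
#' @param trials A trial table as produced by [simulate_experiment()] or
#'   [read_trials()].
#' @param k SD multiplier (default 3).
#' @return A list of class `filtered_trials`: `kept`, `removed` (same
#'   columns as the input) and `removal_fraction`.
#' @export
filter_outliers <- function(trials, k = 3) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0)
    stop("k must be a positive number", call. = FALSE)
  if (nrow(trials) == 0) stop("trials table is empty", call. = FALSE)
  flagged <- trials %>%
    dplyr::group_by(.data$participant, .data$task, .data$arrangement,
                    .data$numerosity) %>%
    dplyr::mutate(
      .resp_out = {
        s <- sd(.data$response)
        !is.na(s) & s > 0 &
          abs(.data$response - mean(.data$response)) > k * s
      }
    ) %>%
    dplyr::group_by(.data$participant, .data$task) %>%
    dplyr::mutate(
      .rt_out = {
        s <- sd(.data$rt_ms)
        !is.na(s) & s > 0 & abs(.data$rt_ms - mean(.data$rt_ms)) > k * s
      }
    ) %>%
    dplyr::ungroup()
  out <- flagged$.resp_out | flagged$.rt_out
  flagged$.resp_out <- NULL
  flagged$.rt_out <- NULL
  structure(
    list(kept = flagged[!out, ], removed = flagged[out, ],
         removal_fraction = mean(out)),
    class = "filtered_trials"
  )
}

#' @export
print.filtered_trials <- function(x, ...) {
  cat(sprintf("<filtered_trials> kept %d, removed %d (%.2f%%)\n",
              nrow(x$kept), nrow(x$removed), 100 * x$removal_fraction))
  invisible(x)
}

#' Per-cell response statistics
#'
#' One record per participant x task x arrangement x numerosity: mean
#' response (perceived numerosity), sample standard deviation (n - 1
#' denominator) and trial count. Cells with fewer than 2 trials have no
#' defined SD and are dropped with a warning.
#'
#' @param trials A (filtered) trial table.
#' @return A tibble with columns `participant`, `task`, `arrangement`,
#'   `numerosity`, `mean_response`, `sd_response`, `n_trials`.
#' @export
cell_statistics <- function(trials) {
  cells <- trials %>%
    dplyr::group_by(.data$participant, .data$task, .data$arrangement,
                    .data$numerosity) %>%
    dplyr::summarise(mean_response = mean(.data$response),
                     sd_response = sd(.data$response),
                     n_trials = dplyr::n(), .groups = "drop")
  thin <- cells$n_trials < 2
  if (any(thin)) {
    warning(sprintf("excluding %d cell(s) with fewer than 2 trials",
                    sum(thin)), call. = FALSE)
    cells <- cells[!thin, ]
  }
  cells
}

#' Weber fraction
#'
#' The dimensionless precision index `Wf = SD_i / N`: the standard deviation
#' of the responses to numerosity `N`, normalised by `N`. Lower is more
#' precise; under scalar variability it is constant across numerosities.
#'
#' @param sd_response Response standard deviation(s).
#' @param numerosity Physical numerosity(ies), >= 1.
#' @return Numeric vector of Weber fractions.
#' @export
weber_fraction <- function(sd_response, numerosity) {
  if (any(numerosity < 1)) stop("numerosity must be >= 1", call. = FALSE)
  if (any(sd_response < 0)) stop("sd_response must be >= 0", call. = FALSE)
  sd_response / numerosity
}

#' Add Weber fractions to a cell-statistics table
#'
#' @param cells Output of [cell_statistics()].
#' @return `cells` with a `wf` column.
#' @export
weber_fractions <- function(cells) {
  cells$wf <- weber_fraction(cells$sd_response, cells$numerosity)
  cells
}

#' Summary precision index per condition
#'
#' Averages Weber fractions (unweighted) across the numerosities in
#' `range`, per participant x task x arrangement. The default range 5-8
#' restricts to the numerosities showing the groupitizing advantage.
#'
#' @param wfs Output of [weber_fractions()].
#' @param range Length-2 numeric `c(lo, hi)`, inclusive.
#' @return A tibble with `participant`, `task`, `arrangement`, `wf`,
#'   `n_numerosities`.
#' @export
summary_wf <- function(wfs, range = c(5, 8)) {
  if (length(range) != 2 || range[1] > range[2])
    stop("range must be c(lo, hi) with lo <= hi", call. = FALSE)
  sub <- wfs[wfs$numerosity >= range[1] & wfs$numerosity <= range[2], ]
  if (nrow(sub) == 0)
    stop("no Weber fractions fall in the requested numerosity range",
         call. = FALSE)
  sub %>%
    dplyr::group_by(.data$participant, .data$task, .data$arrangement) %>%
    dplyr::summarise(wf = mean(.data$wf),
                     n_numerosities = dplyr::n(), .groups = "drop")
}

#' Attentional cost
#'
#' Normalised percent increase in Weber fraction from single to dual task:
#' `AC = (Wf_DT - Wf_ST) / (Wf_ST + Wf_DT) * 100`. Antisymmetric under
#' swapping the two arguments, zero when they are equal, and strictly
#' increasing in `wf_dt` for fixed `wf_st`.
#'
#' @param wf_st,wf_dt Single-task and dual-task summary Weber fractions.
#' @return Attentional cost in percent.
#' @export
attentional_cost <- function(wf_st, wf_dt) {
  if (any(wf_st < 0) || any(wf_dt < 0))
    stop("Weber fractions must be non-negative", call. = FALSE)
  if (any(wf_st + wf_dt == 0))
    stop("attentional cost is undefined when both Weber fractions are zero",
         call. = FALSE)
  (wf_dt - wf_st) / (wf_st + wf_dt) * 100
}

#' Per-participant attentional costs
#'
#' Builds the attentional-cost records from a summary-precision table. The
#' single-task reference is the grouped-with-ignored-distractors condition
#' for grouped arrays (matching the visual stimulation of the dual tasks)
#' and the plain single task for ungrouped arrays (no ungrouped-distractor
#' session exists).
#'
#' @param swf Output of [summary_wf()].
#' @return A tibble with `participant`, `arrangement`, `dual_task`,
#'   `wf_st`, `wf_dt`, `ac`.
#' @export
attentional_cost_table <- function(swf) {
  st <- swf[(swf$task == "single_distractor" & swf$arrangement == "grouped") |
              (swf$task == "single" & swf$arrangement == "ungrouped"), ]
  st <- st[, c("participant", "arrangement", "wf")]
  names(st)[names(st) == "wf"] <- "wf_st"
  dt <- swf[swf$task %in% c("aud_dt", "vsp_dt", "arithm_dt"), ]
  dt <- dt[, c("participant", "arrangement", "task", "wf")]
  names(dt)[names(dt) == "task"] <- "dual_task"
  names(dt)[names(dt) == "wf"] <- "wf_dt"
  out <- dplyr::inner_join(dt, st, by = c("participant", "arrangement"))
  out$ac <- attentional_cost(out$wf_st, out$wf_dt)
  out[, c("participant", "arrangement", "dual_task", "wf_st", "wf_dt", "ac")]
}

#' Delta attentional cost
#'
#' The headline statistic: `delta AC = AC_grouped - AC_ungrouped`. Positive
#' values mean the concurrent task cost more precision for grouped than for
#' ungrouped arrays.
#'
#' @param ac_g,ac_u Attentional costs (percent) for grouped and ungrouped
#'   arrangements.
#' @return Difference in percent.
#' @export
delta_ac <- function(ac_g, ac_u) ac_g - ac_u

#' Per-participant delta attentional costs
#'
#' @param ac_table Output of [attentional_cost_table()].
#' @return A tibble with `participant`, `dual_task`, `ac_grouped`,
#'   `ac_ungrouped`, `delta_ac`.
#' @export
delta_ac_table <- function(ac_table) {
  wide <- ac_table[, c("participant", "dual_task", "arrangement", "ac")] %>%
    tidyr::pivot_wider(names_from = "arrangement", values_from = "ac",
                       names_prefix = "ac_")
  wide$delta_ac <- delta_ac(wide$ac_grouped, wide$ac_ungrouped)
  wide
}

#' Mean perceived numerosity per condition
#'
#' Averages the per-cell mean response over the numerosities in `range`
#' within participant, then across participants, per task x arrangement.
#'
#' @param cells Output of [cell_statistics()].
#' @param range Length-2 numerosity range, inclusive.
#' @return A tibble with `task`, `arrangement`, `mean_perceived`,
#'   `sd_perceived` (across participants), `n_participants`.
#' @export
perceived_numerosity <- function(cells, range = c(5, 8)) {
  if (length(range) != 2 || range[1] > range[2])
    stop("range must be c(lo, hi) with lo <= hi", call. = FALSE)
  sub <- cells[cells$numerosity >= range[1] & cells$numerosity <= range[2], ]
  if (nrow(sub) == 0) stop("no cells in the requested range", call. = FALSE)
  sub %>%
    dplyr::group_by(.data$participant, .data$task, .data$arrangement) %>%
    dplyr::summarise(perceived = mean(.data$mean_response),
                     .groups = "drop") %>%
    dplyr::group_by(.data$task, .data$arrangement) %>%
    dplyr::summarise(mean_perceived = mean(.data$perceived),
                     sd_perceived = sd(.data$perceived),
                     n_participants = dplyr::n(), .groups = "drop")
}
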