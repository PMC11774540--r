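#' Parameters of the synthetic observer
#'
#' Defaults are calibrated to the group-level results of the dual-task
#' groupitizing study the package models: single-task Weber fractions of
#' 0.09 (grouped) and 0.11 (ungrouped); dual-task fold increases of 1.6
#' (auditory), 2.3 (visuo-spatial) and 2.0 (arithmetic) for grouped arrays
#' and 1.3 / 1.5 / 1.3 for ungrouped arrays; concurrent-task accuracies of
#' 0.82 / 0.94 / 0.96; a +7% estimation bias (so mean perceived numerosity
#' over N 5-8 is close to the reported ~6.97); and a 0.6% rate of wild
#' "lapse" trials that exercise the 3-SD outlier filter.
#'
#' @param wf_single_grouped,wf_single_ungrouped Generating single-task Weber
#'   fractions (dimensionless). The grouped value is also used for the
#'   grouped-with-ignored-distractors session.
#' @param fold_increase Named numeric vector of dual-task multipliers on the
#'   single-task Weber fraction; names are `<arrangement>.<task>` with task
#'   in `aud_dt`, `vsp_dt`, `arithm_dt`.
#' @param bias Proportional over/under-estimation `b`: the mean response to
#'   numerosity N is N(1+b) before rounding.
#' @param lapse_rate Probability of a wild trial (uniform response in
#'   1..3N, long response time). Must be in [0, 0.05).
#' @param between_participant_sd Log-scale SD of participant-level Weber
#'   fractions around each condition mean.
#' @param concurrent_accuracy Named probabilities of a correct concurrent
#'   response per dual task.
#' @param rt_meanlog,rt_sdlog Log-scale location and scale of clean response
#'   times in milliseconds (lognormal).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(wf_single_grouped = 0.09,
                       wf_single_ungrouped = 0.11,
                       fold_increase = c(grouped.aud_dt = 1.6,
                                         grouped.vsp_dt = 2.3,
                                         grouped.arithm_dt = 2.0,
                                         ungrouped.aud_dt = 1.3,
                                         ungrouped.vsp_dt = 1.5,
                                         ungrouped.arithm_dt = 1.3),
                       bias = 0.07,
                       lapse_rate = 0.006,
                       between_participant_sd = 0.3,
                       concurrent_accuracy = c(aud_dt = 0.82,
                                               vsp_dt = 0.94,
                                               arithm_dt = 0.96),
                       rt_meanlog = log(750),
                       rt_sdlog = 0.15) {
  if (wf_single_grouped <= 0 || wf_single_ungrouped <= 0)
    stop("Weber fractions must be positive", call. = FALSE)
  needed <- c("grouped.aud_dt", "grouped.vsp_dt", "grouped.arithm_dt",
              "ungrouped.aud_dt", "ungrouped.vsp_dt", "ungrouped.arithm_dt")
  if (!all(needed %in% names(fold_increase)))
    stop("fold_increase must name all six arrangement x dual-task cells",
         call. = FALSE)
  if (any(fold_increase <= 0))
    stop("fold increases must be positive", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate >= 0.05)
    stop("lapse_rate must be in [0, 0.05)", call. = FALSE)
  if (between_participant_sd < 0)
    stop("between_participant_sd must be non-negative", call. = FALSE)
  if (!all(c("aud_dt", "vsp_dt", "arithm_dt") %in%
             names(concurrent_accuracy)) ||
      any(concurrent_accuracy < 0 | concurrent_accuracy > 1))
    stop("concurrent_accuracy must give probabilities for the three dual tasks",
         call. = FALSE)
  if (rt_sdlog < 0) stop("rt_sdlog must be non-negative", call. = FALSE)
  structure(
    list(wf_single_grouped = wf_single_grouped,
         wf_single_ungrouped = wf_single_ungrouped,
         fold_increase = fold_increase[needed],
         bias = bias, lapse_rate = lapse_rate,
         between_participant_sd = between_participant_sd,
         concurrent_accuracy = concurrent_accuracy,
         rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog),
    class = "sim_params"
  )
}

#' Generating Weber fraction per experimental condition
#'
#' @param params A [sim_params()] object.
#' @return A tibble with `task`, `arrangement` and the condition-mean
#'   generating Weber fraction `wf`. The grouped-with-ignored-distractors
#'   session shares the grouped single-task value.
#' @export
condition_wf <- function(params = sim_params()) {
  fi <- params$fold_increase
  tibble::tibble(
    task = c("single", "single", "single_distractor",
             "aud_dt", "vsp_dt", "arithm_dt",
             "aud_dt", "vsp_dt", "arithm_dt"),
    arrangement = c("grouped", "ungrouped", "grouped",
                    rep("grouped", 3), rep("ungrouped", 3)),
    wf = unname(c(params$wf_single_grouped, params$wf_single_ungrouped,
                  params$wf_single_grouped,
                  params$wf_single_grouped * fi[c("grouped.aud_dt",
                                                  "grouped.vsp_dt",
                                                  "grouped.arithm_dt")],
                  params$wf_single_ungrouped * fi[c("ungrouped.aud_dt",
                                                    "ungrouped.vsp_dt",
                                                    "ungrouped.arithm_dt")]))
  )
}

#' Simulate numerosity-estimation responses
#'
#' Scalar-variability response model: with probability `1 - lapse_rate` the
#' response is `max(1, round(N (1 + bias) + eps))` with
#' `eps ~ Normal(0, wf * N)`; with probability `lapse_rate` the response is a
#' wild draw, uniform on `1..3N`. Vectorised over `numerosity` (and `wf`).
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param numerosity Integer vector of physical numerosities (>= 1).
#' @param wf Generating Weber fraction(s), >= 0.
#' @param bias Proportional estimation bias.
#' @param lapse_rate Wild-response probability.
#' @return Integer vector of responses (all >= 1).
#' @export
simulate_response <- function(numerosity, wf, bias = 0, lapse_rate = 0) {
  if (any(numerosity < 1)) stop("numerosity must be >= 1", call. = FALSE)
  if (any(wf < 0)) stop("wf must be non-negative", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate > 1)
    stop("lapse_rate must be a probability", call. = FALSE)
  m <- length(numerosity)
  eps <- rnorm(m, 0, wf * numerosity)
  resp <- pmax(1L, as.integer(round(numerosity * (1 + bias) + eps)))
  if (lapse_rate > 0) {
    lapse <- runif(m) < lapse_rate
    if (any(lapse)) {
      resp[lapse] <- vapply(numerosity[lapse],
                            function(n) sample.int(3L * n, 1L), integer(1))
    }
  }
  resp
}

# One participant's trial design: which task/arrangement/numerosity/
# configuration each trial has, honouring the block structure
# (4 grouped + 4 ungrouped blocks of 36 per session; grouped-only for the
# single-with-distractors session).
.design_one <- function(blocks_per_arrangement = 4) {
  cfg <- configuration_table()
  grouped_block <- tibble::tibble(numerosity = cfg$numerosity,
                                  configuration = cfg$configuration)
  ungrouped_block <- tibble::tibble(
    numerosity = rep(5:16, each = 3L),
    configuration = ""
  )
  session_design <- function(task, arrangements) {
    blocks <- lapply(arrangements, function(a) {
      block <- if (a == "grouped") grouped_block else ungrouped_block
      dplyr::bind_rows(lapply(seq_len(blocks_per_arrangement),
                              function(b) block))
    })
    out <- dplyr::bind_rows(blocks)
    out$arrangement <- rep(arrangements,
                           each = blocks_per_arrangement * nrow(grouped_block))
    out$task <- task
    out
  }
  dplyr::bind_rows(
    session_design("single", c("grouped", "ungrouped")),
    session_design("single_distractor", "grouped"),
    session_design("aud_dt", c("grouped", "ungrouped")),
    session_design("vsp_dt", c("grouped", "ungrouped")),
    session_design("arithm_dt", c("grouped", "ungrouped"))
  )
}

#' Simulate a full dual-task groupitizing experiment
#'
#' Emits the complete design for each participant: a single-task session
#' (4 grouped + 4 ungrouped blocks of 36 trials), a grouped-only
#' single-task-with-ignored-distractors session (4 blocks), and three
#' dual-task sessions (auditory, visuo-spatial, arithmetic; 8 blocks each) -
#' 1296 trials per participant. Participant-level Weber fractions are drawn
#' log-normally around the condition means of [condition_wf()] (independent
#' draws per condition, with `meanlog` offset so the population mean equals
#' the condition mean). Concurrent-task correctness is Bernoulli with the
#' task-specific accuracy; response times are lognormal with rare long
#' "lapse" trials coupled to wild responses.
#'
#' @param params A [sim_params()] object.
#' @param n_participants Number of participants (default 28).
#' @param seed Integer seed; the full table is reproducible given the seed.
#' @return A tibble with columns `participant`, `session`, `task`,
#'   `arrangement`, `numerosity`, `configuration`, `response`, `rt_ms`,
#'   `concurrent_correct`.
#' @examples
#' trials <- simulate_experiment(n_participants = 1, seed = 1)
#' nrow(trials) # 1296
#' @export
simulate_experiment <- function(params = sim_params(), n_participants = 28,
                                seed = 1) {
  stopifnot(inherits(params, "sim_params"), n_participants >= 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  design <- .design_one()
  cond <- condition_wf(params)
  sdlog <- params$between_participant_sd
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    cond_p <- cond
    cond_p$wf_p <- exp(rnorm(nrow(cond), log(cond$wf) - sdlog^2 / 2, sdlog))
    tr <- dplyr::left_join(design, cond_p[, c("task", "arrangement", "wf_p")],
                           by = c("task", "arrangement"))
    n <- nrow(tr)
    resp <- simulate_response(tr$numerosity, tr$wf_p, params$bias,
                              lapse_rate = 0)
    rt <- rlnorm(n, params$rt_meanlog, params$rt_sdlog)
    lapse <- runif(n) < params$lapse_rate
    if (any(lapse)) {
      resp[lapse] <- vapply(tr$numerosity[lapse],
                            function(k) sample.int(3L * k, 1L), integer(1))
      rt[lapse] <- rlnorm(sum(lapse), params$rt_meanlog + 1.2, 0.5)
    }
    acc <- params$concurrent_accuracy[tr$task]
    cc <- ifelse(is.na(acc), NA, runif(n) < acc)
    out[[p]] <- tibble::tibble(
      participant = sprintf("P%02d", p),
      session = tr$task,
      task = tr$task,
      arrangement = tr$arrangement,
      numerosity = as.integer(tr$numerosity),
      configuration = tr$configuration,
      response = as.integer(resp),
      rt_ms = round(rt, 1),
      concurrent_correct = as.logical(cc)
    )
  }
  dplyr::bind_rows(out)
}
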