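.trial_columns <- c("participant", "session", "task", "arrangement",
                    "numerosity", "configuration", "response", "rt_ms",
                    "concurrent_correct")
.tasks <- c("single", "single_distractor", "aud_dt", "vsp_dt", "arithm_dt")
.arrangements <- c("grouped", "ungrouped")

#' Validate a trial table against the schema
#'
#' Checks column presence, closed vocabularies for `task` and
#' `arrangement`, numerosity in 5-16, positive integer responses, positive
#' response times, that the single-with-distractors session only appears
#' with grouped arrays, and that ungrouped trials carry an empty
#' configuration. All violations are collected and reported together.
#'
#' @param trials A trial table.
#' @return `trials`, invisibly, if valid; otherwise an error listing the
#'   offending rows.
#' @export
validate_trials <- function(trials) {
  missing <- setdiff(.trial_columns, names(trials))
  if (length(missing) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  problems <- character(0)
  note <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      problems <<- c(problems, sprintf(
        "%s (row%s %s%s)", what, if (length(rows) > 1) "s" else "",
        paste(head(rows, 5), collapse = ", "),
        if (length(rows) > 5) ", ..." else ""))
    }
  }
  note(!trials$task %in% .tasks, "unknown task label")
  note(!trials$arrangement %in% .arrangements, "unknown arrangement label")
  note(is.na(trials$numerosity) | trials$numerosity < 5 |
         trials$numerosity > 16, "numerosity outside 5-16")
  note(is.na(trials$response) | trials$response < 1 |
         trials$response != round(trials$response),
       "response not a positive integer")
  note(is.na(trials$rt_ms) | trials$rt_ms <= 0, "non-positive rt_ms")
  note(trials$task == "single_distractor" &
         trials$arrangement == "ungrouped",
       "single_distractor trials must be grouped")
  note(trials$arrangement == "ungrouped" &
         !(is.na(trials$configuration) | trials$configuration == ""),
       "ungrouped trials must have an empty configuration")
  if (length(problems) > 0)
    stop("invalid trial table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(trials)
}

#' Write a trial table as CSV
#'
#' Comma-separated, UTF-8, Unix newlines, fixed header. The inverse of
#' [read_trials()].
#'
#' @param trials A trial table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials[, .trial_columns], path, na = "NA", eol = "\n")
  invisible(path)
}

#' Read and validate a trial table CSV
#'
#' @param path File written by [write_trials()] (or any CSV with the same
#'   schema).
#' @return A validated trial tibble.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant = readr::col_character(),
      session = readr::col_character(),
      task = readr::col_character(),
      arrangement = readr::col_character(),
      numerosity = readr::col_integer(),
      configuration = readr::col_character(),
      response = readr::col_double(),
      rt_ms = readr::col_double(),
      concurrent_correct = readr::col_logical()
    ),
    na = "NA", progress = FALSE
  )
  extra <- setdiff(names(trials), .trial_columns)
  if (length(extra) > 0)
    stop("unexpected column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  trials$configuration[is.na(trials$configuration)] <- ""
  validate_trials(trials)
  trials$response <- as.integer(trials$response)
  trials
}
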