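#' Classify a trial's outcome
#'
#' Responses at or before 150 ms after the sensory change are premature
#' (they cannot have been driven by the evidence); trials with no response
#' within the deadline are misses; everything else is correct or an error
#' by choice vs target.
#'
#' @param trial one trial row: `choice` ("left"/"right"/"none" or NA),
#'   `rt` (ms relative to the sensory change, may be negative), `target`.
#' @param config a [task_config()].
#' @return one of `"correct"`, `"error"`, `"premature"`, `"miss"`.
#' @export
classify_outcome <- function(trial, config) {
  no_choice <- is.na(trial$choice) || trial$choice == "none"
  if (no_choice) return("miss")
  if (is.na(trial$rt)) stop("trial with a choice but no RT")
  if (trial$rt > config$deadline) {
    stop("invalid record: response at ", trial$rt,
         " ms is beyond the ", config$deadline, " ms deadline")
  }
  if (trial$rt <= config$premature_cutoff) return("premature")
  if (trial$choice == trial$target) "correct" else "error"
}

#' Points awarded for a trial
#'
#' Correct responses earn 40 points plus a speed bonus that diminishes
#' linearly from 40 to 0 across the range of possible response times
#' (150-2000 ms); premature, erroneous and missed trials earn nothing.
#'
#' @param outcome outcome class from [classify_outcome()].
#' @param rt response time, ms relative to the sensory change.
#' @param config a [task_config()].
#' @return points (numeric).
#' @export
score_points <- function(outcome, rt, config) {
  if (outcome != "correct") return(0)
  span <- config$deadline - config$premature_cutoff
  bonus <- 40 * (config$deadline - rt) / span
  40 + max(0, min(40, bonus))
}

#' Behavioural summaries
#'
#' Per-foreperiod summary statistics, conditional accuracy functions, and
#' the sequential (previous-by-current foreperiod) grids. Accuracy is the
#' percentage of trials on which the direction was correctly reported,
#' over all trials (premature responses and misses count against it;
#' conditioning accuracy on having escaped the premature cutoff creates a
#' selection artifact in high-noise cells, where excluding the
#' noise-driven fast guesses flatters the remainder). Mean RT pools
#' corrects and errors and excludes premature and missed trials; points
#' per trial average over all trials including zero-point ones. The conditional accuracy functions use
#' equal-count RT bins over all trials with a recorded choice (premature
#' responses included, since they carry a choice), with accuracy there
#' simply the fraction of choices matching the target.
#'
#' @param trials a trial tibble with `foreperiod`, `prev_foreperiod`,
#'   `target`, `choice`, `rt`, `outcome`, `points`.
#' @param config a [task_config()].
#' @param caf_bins RT bins for the conditional accuracy function; default 8
#'   for the gratings task and 6 for the dot-motion task.
#' @return list of class `behavioural_summary`: `by_foreperiod`, `caf`,
#'   `grid` (FPn x FPn-1 mean RT and accuracy), `miss_by_prev` (short-FPn
#'   trials), `premature_by_prev` (long-FPn trials).
#' @export
summarize_behaviour <- function(trials, config,
                                caf_bins = if (config$task == "gratings") 8 else 6) {
  acc <- function(d) {
    if (nrow(d) == 0) NA_real_ else 100 * mean(d$outcome == "correct")
  }
  by_foreperiod <- trials |>
    dplyr::group_by(.data$foreperiod) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_rt = mean(.data$rt[.data$outcome %in% c("correct", "error")]),
      accuracy = acc(dplyr::pick(dplyr::everything())),
      miss_rate = 100 * mean(.data$outcome == "miss"),
      premature_rate = 100 * mean(.data$outcome == "premature"),
      points_per_trial = mean(.data$points),
      .groups = "drop")

  caf <- trials |>
    dplyr::filter(!is.na(.data$choice), .data$choice != "none") |>
    dplyr::group_by(.data$foreperiod) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < caf_bins) return(tibble::tibble())
      b <- bin_trials(d, by = "rt", n_bins = caf_bins)
      d$bin <- b
      d |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(
          rt = mean(.data$rt),
          accuracy = 100 * mean(.data$choice == .data$target),
          n = dplyr::n(), .groups = "drop")
    }) |>
    dplyr::ungroup()

  seqd <- trials |> dplyr::filter(!is.na(.data$prev_foreperiod))
  grid <- seqd |>
    dplyr::group_by(.data$foreperiod, .data$prev_foreperiod) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_rt = mean(.data$rt[.data$outcome %in% c("correct", "error")]),
      accuracy = acc(dplyr::pick(dplyr::everything())),
      .groups = "drop")

  fp_short <- min(config$foreperiods); fp_long <- max(config$foreperiods)
  miss_by_prev <- seqd |>
    dplyr::filter(.data$foreperiod == fp_short) |>
    dplyr::group_by(.data$prev_foreperiod) |>
    dplyr::summarise(miss_rate = 100 * mean(.data$outcome == "miss"),
                     n = dplyr::n(), .groups = "drop")
  premature_by_prev <- seqd |>
    dplyr::filter(.data$foreperiod == fp_long) |>
    dplyr::group_by(.data$prev_foreperiod) |>
    dplyr::summarise(premature_rate = 100 * mean(.data$outcome == "premature"),
                     n = dplyr::n(), .groups = "drop")

  structure(list(by_foreperiod = by_foreperiod, caf = caf, grid = grid,
                 miss_by_prev = miss_by_prev,
                 premature_by_prev = premature_by_prev),
            class = "behavioural_summary")
}

#' Two-down one-up staircase
#'
#' Adaptive difficulty titration: the stimulus level (e.g. contrast step or
#' coherence) is lowered after two consecutive correct responses and raised
#' after every error, converging on the ~70.7% point of the observer's
#' psychometric function when the up and down steps are equal.
#'
#' @param observer function mapping level to p(correct), monotone
#'   increasing in level.
#' @param n_trials staircase length (an 80-trial block in the task).
#' @param seed integer seed.
#' @param start_level initial level.
#' @param step step size (same units as level) for both directions.
#' @param level_range permissible level range, clamped.
#' @return list: `levels` (trajectory, length `n_trials`), `correct`
#'   (logical), `final_level`, `accuracy`.
#' @export
run_staircase <- function(observer, n_trials = 80, seed = 1,
                          start_level = 0.2, step = 0.01,
                          level_range = c(0.005, 1)) {
  local_rng(seed)
  levels <- numeric(n_trials)
  correct <- logical(n_trials)
  level <- start_level
  streak <- 0L
  for (i in seq_len(n_trials)) {
    levels[i] <- level
    correct[i] <- stats::runif(1) < observer(level)
    if (correct[i]) {
      streak <- streak + 1L
      if (streak == 2L) {
        level <- max(level - step, level_range[1])
        streak <- 0L
      }
    } else {
      level <- min(level + step, level_range[2])
      streak <- 0L
    }
  }
  list(levels = levels, correct = correct, final_level = level,
       accuracy = mean(correct))
}
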