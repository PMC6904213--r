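#' Generate a full synthetic dataset
#'
#' Draws a balanced trial schedule, simulates every trial's behaviour with
#' the variable-onset accumulator, forward-models the 128-channel EEG, and
#' classifies and scores the outcomes. For the gratings task the evidence
#' trace is the signed contrast difference; for the dot-motion task it is
#' the opponent motion energy of the trial's own kinematogram (scaled so
#' that the titrated coherence yields a comparable drift), which couples
#' choices to pre-evidence stimulus fluctuations.
#'
#' @param config a [task_config()].
#' @param params a [generative_params()].
#' @param n_trials number of trials (divisible by the number of
#'   foreperiods).
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @param eeg generate the EEG forward model (set FALSE for
#'   behaviour-only simulations, which is much faster).
#' @param keep_frames keep each trial's kinematogram frames (rdk task;
#'   memory-heavy).
#' @param me_params an [me_filter_params()] for the rdk evidence trace; the
#'   default drops the rasterisation to 0.1 deg/px for speed.
#' @param rdk_drift_scale rescaling of the raw opponent-energy trace into
#'   accumulator evidence units, chosen so the mean post-onset drift at the
#'   titrated coherence matches the gratings task's contrast evidence.
#' @return list of class `synthetic_dataset`: `trials` (tibble with design,
#'   behaviour, points and hidden-truth columns `t_on`, `lapse`,
#'   `crossing_ms`, `degenerate`, `n_blinks`), `eeg` (per-trial list from
#'   [synthesize_eeg_trial()], or NULL), `energy` (per-trial motion-energy
#'   traces, rdk only), `frames` (optional), `config`, `params`, `layout`.
#' @export
generate_dataset <- function(config, params = generative_params(),
                             n_trials = 300, seed = 1,
                             eeg = TRUE, keep_frames = FALSE,
                             me_params = me_filter_params(resolution = 0.1),
                             rdk_drift_scale = NULL) {
  schedule <- make_trial_schedule(n_trials, config, seed = seed)
  layout <- biosemi128_layout()
  seeds <- sub_seeds(seed, n_trials, salt = 101L)
  eeg_seeds <- sub_seeds(seed, n_trials, salt = 202L)

  if (config$task == "rdk" && is.null(rdk_drift_scale)) {
    # calibrate once: mean opponent energy of a few reference trials at the
    # configured coherence maps onto the gratings-task evidence level
    ref <- calibrate_rdk_energy(config, me_params, seed)
    rdk_drift_scale <- (2 * config$contrast_delta) / ref
  }

  trials <- schedule
  trials$t_on <- NA_real_; trials$crossing_ms <- NA_real_
  trials$choice <- NA_character_; trials$rt <- NA_real_
  trials$degenerate <- FALSE; trials$lapse <- FALSE
  eeg_list <- if (eeg) vector("list", n_trials) else NULL
  energy_list <- if (config$task == "rdk") vector("list", n_trials) else NULL
  frames_list <- if (keep_frames) vector("list", n_trials) else NULL
  trials$n_blinks <- 0L

  for (i in seq_len(n_trials)) {
    tr <- schedule[i, ]
    if (config$task == "gratings") {
      stim <- render_grating_timecourse(tr, config,
                                        phase_reversed = seeds[i] %% 2L == 0L)
      evidence <- list(time_ms = stim$time_ms,
                       value = stim$contrast_right - stim$contrast_left)
    } else {
      frames <- generate_rdk_frames(tr, config, seed = seeds[i] + 1L)
      trace <- compute_motion_energy(frames, me_params)
      energy_list[[i]] <- trace
      if (keep_frames) frames_list[[i]] <- frames
      stim <- NULL
      evidence <- list(time_ms = trace$time_ms,
                       value = trace$energy * rdk_drift_scale)
    }
    sim <- simulate_trial_accumulator(tr, evidence, params, config,
                                      seed = seeds[i])
    trials$choice[i] <- sim$choice
    trials$rt[i] <- sim$rt
    trials$t_on[i] <- sim$t_on
    trials$crossing_ms[i] <- sim$crossing_ms
    trials$degenerate[i] <- sim$degenerate
    trials$lapse[i] <- sim$lapse
    if (eeg) {
      eeg_list[[i]] <- synthesize_eeg_trial(sim, tr, stim, params, config,
                                            seed = eeg_seeds[i],
                                            layout = layout)
      trials$n_blinks[i] <- eeg_list[[i]]$n_blinks
    }
  }
  trials$outcome <- vapply(seq_len(n_trials), function(i)
    classify_outcome(trials[i, ], config), character(1))
  trials$points <- vapply(seq_len(n_trials), function(i)
    score_points(trials$outcome[i], trials$rt[i], config), numeric(1))

  structure(
    list(trials = trials, eeg = eeg_list, energy = energy_list,
         frames = frames_list, config = config, params = params,
         layout = layout, rdk_drift_scale = rdk_drift_scale),
    class = "synthetic_dataset")
}

# mean absolute opponent energy during coherent motion, short reference run
calibrate_rdk_energy <- function(config, me_params, seed) {
  tr <- tibble::tibble(index = 1L, foreperiod = min(config$foreperiods),
                       prev_foreperiod = NA_real_, target = "right")
  vals <- vapply(1:3, function(k) {
    fr <- generate_rdk_frames(tr, config, seed = seed + 7000L + k)
    trace <- compute_motion_energy(fr, me_params)
    post <- trace$time_ms >= tr$foreperiod + 200
    mean(trace$energy[post])
  }, numeric(1))
  mean(vals)
}

# independent integer sub-seeds below 2^31, reproducible from (seed, salt)
sub_seeds <- function(seed, n, salt = 0L) {
  local_rng(seed + salt)
  sample.int(.Machine$integer.max - 1L, n)
}
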