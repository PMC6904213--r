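#' Task configuration
#'
#' Bundle of all stimulus and task constants for the two discrimination
#' tasks: overlaid flickering gratings (contrast discrimination) and random
#' dot kinematograms (motion discrimination). Defaults reproduce the study
#' conditions: a 100 Hz display, foreperiods of 800/1200/1600 ms drawn
#' pseudorandomly, a 2000 ms evidence period and response deadline, and a
#' 150 ms premature-response cutoff.
#'
#' @param task `"gratings"` or `"rdk"`.
#' @param refresh_rate display frame rate, frames/s.
#' @param foreperiods foreperiod durations, ms; each must be a multiple of
#'   the frame period.
#' @param evidence_duration duration of the informative sensory change, ms.
#' @param flicker_freqs named numeric, tag frequencies in Hz for the left-
#'   and right-tilted gratings.
#' @param baseline_contrast starting contrast of both gratings (fraction).
#' @param contrast_delta per-subject contrast step (fraction); the group
#'   mean titrated level is 0.055 (range 0.02-0.07).
#' @param n_dots number of dots in the kinematogram.
#' @param dot_diameter dot diameter, px.
#' @param aperture_radius aperture radius, deg of visual angle.
#' @param coherence fraction of dots displaced coherently per frame; the
#'   group mean titrated level is 0.0742 (range 0.03-0.12).
#' @param dot_speed coherent dot speed, deg/s. Not a reported constant;
#'   default 5 deg/s, the usual kinematogram convention.
#' @param deadline response deadline, ms after the sensory change.
#' @param premature_cutoff responses at or before this latency (ms, relative
#'   to the sensory change) count as premature.
#' @return A `task_config` list.
#' @export
task_config <- function(task = c("gratings", "rdk"),
                        refresh_rate = 100,
                        foreperiods = c(800, 1200, 1600),
                        evidence_duration = 2000,
                        flicker_freqs = c(left = 20, right = 25),
                        baseline_contrast = 0.50,
                        contrast_delta = 0.055,
                        n_dots = 100,
                        dot_diameter = 4,
                        aperture_radius = if (match.arg(task) == "rdk") 4 else 6,
                        coherence = 0.0742,
                        dot_speed = 5,
                        deadline = 2000,
                        premature_cutoff = 150) {
  task <- match.arg(task)
  frame_ms <- 1000 / refresh_rate
  if (any(foreperiods <= 0) || any(abs(foreperiods / frame_ms -
                                       round(foreperiods / frame_ms)) > 1e-9)) {
    stop("foreperiods must be positive multiples of the frame period (",
         frame_ms, " ms)")
  }
  if (coherence <= 0 && task == "rdk") {
    if (coherence < 0) stop("coherence must be in (0, 1]")
  }
  if (coherence > 1 || coherence < 0) stop("coherence must be in [0, 1]")
  if (baseline_contrast + contrast_delta >= 1 ||
      baseline_contrast - contrast_delta <= 0) {
    stop("baseline_contrast +/- contrast_delta must stay within (0, 1)")
  }
  structure(
    list(task = task, refresh_rate = refresh_rate, frame_ms = frame_ms,
         foreperiods = sort(foreperiods),
         evidence_duration = evidence_duration,
         flicker_freqs = flicker_freqs,
         baseline_contrast = baseline_contrast,
         contrast_delta = contrast_delta,
         n_dots = n_dots, dot_diameter = dot_diameter,
         aperture_radius = aperture_radius, coherence = coherence,
         dot_speed = dot_speed, deadline = deadline,
         premature_cutoff = premature_cutoff),
    class = "task_config")
}

#' Number of stimulus frames for a trial
#'
#' @param foreperiod foreperiod, ms.
#' @param config a [task_config()].
#' @return integer frame count, `(foreperiod + evidence_duration) *
#'   refresh_rate / 1000`.
#' @export
n_trial_frames <- function(foreperiod, config) {
  as.integer(round((foreperiod + config$evidence_duration) *
                     config$refresh_rate / 1000))
}

#' Pseudorandom balanced trial schedule
#'
#' Draws a trial schedule in which each foreperiod level occurs equally
#' often and each target side is assigned at random, balanced within blocks
#' of `3 * block_k` trials so that no level can cluster at one end of the
#' session. The previous trial's foreperiod is recorded for sequential
#' analyses.
#'
#' @param n_trials number of trials; must be divisible by the number of
#'   foreperiod levels (and by `levels * block_k` when `block_k > 1`).
#' @param config a [task_config()].
#' @param seed integer seed; the schedule is reproducible from it.
#' @param block_k foreperiods are balanced within blocks of
#'   `length(foreperiods) * block_k` trials.
#' @return tibble with columns `index`, `foreperiod`, `prev_foreperiod`
#'   (NA on trial 1) and `target`.
#' @export
make_trial_schedule <- function(n_trials, config, seed, block_k = 1L) {
  fps <- config$foreperiods
  k <- length(fps)
  if (n_trials %% k != 0) {
    stop("n_trials (", n_trials, ") must be divisible by the number of ",
         "foreperiod levels (", k, ") for a balanced schedule")
  }
  block <- k * block_k
  if (n_trials %% block != 0) {
    stop("n_trials must be divisible by the block size ", block)
  }
  rng <- local_rng(seed)
  shuffle <- function(x) x[sample.int(length(x))]
  fp <- unlist(lapply(seq_len(n_trials / block), function(b) {
    shuffle(rep(fps, block_k))
  }))
  tibble::tibble(
    index = seq_len(n_trials),
    foreperiod = fp,
    prev_foreperiod = c(NA_real_, fp[-n_trials]),
    target = sample(c("left", "right"), n_trials, replace = TRUE))
}

# Seed an RNG scope restored on exit; keeps package randomness reproducible
# without clobbering the caller's stream.
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(seed, .local_envir = envir)
  invisible(seed)
}
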