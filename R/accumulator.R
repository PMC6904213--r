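#' Generative model parameters
#'
#' Parameters of the variable-onset bounded accumulator and of the forward
#' EEG model built on top of it. The behavioural core is a single signed
#' decision variable with two absorbing bounds: integration starts at an
#' endogenous onset time
#' \deqn{t_{on} = onset\_base + onset\_prev\_fp\_gain \cdot (FP_{n-1} - \bar{FP}) + jitter,}
#' anchored to stimulus onset rather than evidence onset, so that on longer
#' foreperiods the accumulator runs on noise (or on pre-evidence stimulus
#' fluctuations) before any informative evidence exists. The paper this
#' model emulates proposes, but does not formalise, such a process; the
#' equations here are this package's own construction.
#'
#' Defaults are calibrated to the task's titrated difficulty: with the mean
#' contrast step (0.055 per grating, evidence 0.11) the drift-to-noise
#' ratio gives ~70% accuracy from an unbiased start, mean decision times of
#' a few hundred ms, and pre-evidence noise accumulation that yields a
#' modest premature-response rate that grows with foreperiod.
#'
#' @param onset_base mean accumulation onset, ms post stimulus onset.
#' @param onset_prev_fp_gain onset shift (ms per ms) per deviation of the
#'   previous foreperiod from the mean foreperiod; positive means a longer
#'   previous foreperiod delays the onset.
#' @param onset_jitter_sd trial-to-trial onset jitter SD, ms.
#' @param onset_lapse_rate probability of a temporal-attention lapse on a
#'   trial: the onset is then drawn uniformly between `onset_base` and
#'   `onset_lapse_to`, often landing late in (or beyond) the trial. Lapses
#'   beyond the trial end are the model's source of missed responses, and
#'   since short-foreperiod trials end sooner they miss more often.
#' @param onset_lapse_to upper end of the lapse onset distribution, ms.
#' @param drift_gain drift per unit evidence, 1/(a.u. ms).
#' @param noise_sd accumulator diffusion SD, a.u./sqrt(ms), during the
#'   evidence period.
#' @param pre_evidence_noise_frac fraction of `noise_sd` applied before the
#'   sensory change (the pre-evidence sensory representation carries less
#'   variance than the driven one).
#' @param bound decision bound (symmetric, +bound = right), a.u.
#' @param bound_collapse optional fractional linear collapse of the bound
#'   across the response deadline, starting at the sensory change (an
#'   urgency signal: the bound falls to `1 - bound_collapse` of its
#'   starting value by the deadline, floored at 30%). Default 0: fixed
#'   bounds, which keeps the closed-form crossing-time checks exact.
#' @param motor_delay non-decision time between bound crossing and the
#'   registered response, ms. The default equals the premature cutoff, so
#'   a response classified premature (within 150 ms of the change) always
#'   reflects a crossing that happened before any evidence existed —
#'   which is the cutoff's own rationale.
#' @param start_bias starting level of the decision variable, a.u.
#'   (negative = toward left); models the flicker-induced left bias of the
#'   grating task when set below 0. Default 0.
#' @param ssvep_gain occipital tag-frequency amplitude per unit grating
#'   contrast, uV.
#' @param cpp_gain centro-parietal amplitude per unit of accumulated
#'   decision variable magnitude, uV.
#' @param mubeta_base,mubeta_dv_gain baseline 10-30 Hz envelope amplitude
#'   and its (desynchronising) reduction per unit of decision variable
#'   moving toward the chosen bound, uV.
#' @param mubeta_ipsi_frac fraction of the contralateral desynchronisation
#'   applied to the ipsilateral motor cluster.
#' @param sensor_noise_sd per-channel sensor/background noise SD, uV.
#' @param blink_rate,pop_rate expected blink / channel-pop artifacts per
#'   trial.
#' @param blink_amplitude peak blink amplitude on the bipolar EOG, uV.
#' @param pop_amplitude channel-pop amplitude, uV.
#' @param fs EEG sampling rate, Hz.
#' @return list of class `generative_params`.
#' @export
generative_params <- function(onset_base = 800,
                              onset_prev_fp_gain = 0.7,
                              onset_jitter_sd = 50,
                              onset_lapse_rate = 0.04,
                              onset_lapse_to = 5000,
                              drift_gain = 5.9e-3,
                              noise_sd = 0.044,
                              pre_evidence_noise_frac = 0.45,
                              bound = 1,
                              bound_collapse = 0,
                              motor_delay = 150,
                              start_bias = 0,
                              ssvep_gain = 8,
                              cpp_gain = 40,
                              mubeta_base = 6,
                              mubeta_dv_gain = 3,
                              mubeta_ipsi_frac = 0.4,
                              sensor_noise_sd = 10,
                              blink_rate = 0.05,
                              pop_rate = 0.02,
                              blink_amplitude = 400,
                              pop_amplitude = 150,
                              fs = 512) {
  stopifnot(bound > 0, noise_sd >= 0, motor_delay >= 0,
            all(is.finite(c(drift_gain, ssvep_gain, cpp_gain,
                            mubeta_base, mubeta_dv_gain))))
  structure(as.list(environment()), class = "generative_params")
}

#' Simulate one trial of the variable-onset accumulator
#'
#' Integrates the supplied evidence trace (signed, positive = rightward)
#' plus Gaussian diffusion from the endogenous onset time until a bound
#' crossing, the response deadline, or the end of the trial. The first
#' crossing of +bound/-bound sets the choice; the response is registered
#' `motor_delay` ms later, and only if it falls within the deadline.
#'
#' @param trial one schedule row (`foreperiod`, `prev_foreperiod`,
#'   `target`).
#' @param evidence list with `time_ms` and `value`: the signed physical
#'   evidence (contrast difference or motion energy), sampled at any
#'   resolution covering `[0, foreperiod + evidence_duration]`; held
#'   piecewise-constant between samples. Positive favours rightward.
#' @param params a [generative_params()].
#' @param config a [task_config()].
#' @param seed integer seed.
#' @return list: `choice` ("left"/"right"/"none"), `rt` (ms relative to the
#'   sensory change; NA for no response), `t_on` (true onset, ms), `lapse`
#'   (TRUE when the onset came from the lapse distribution),
#'   `crossing_ms` (bound-crossing time, NA if none), `dv` (decision
#'   variable sampled at `fs`, 0 before `t_on`), `time_ms` (its time axis,
#'   from stimulus onset), `degenerate` (TRUE when the onset fell beyond
#'   the trial end).
#' @export
simulate_trial_accumulator <- function(trial, evidence, params, config, seed) {
  local_rng(seed)
  fp <- trial$foreperiod
  trial_end <- fp + config$evidence_duration
  dt <- 1000 / params$fs
  time_ms <- seq(0, trial_end, by = dt)
  n <- length(time_ms)

  fp_mean <- mean(config$foreperiods)
  prev_dev <- if (is.na(trial$prev_foreperiod)) 0 else
    trial$prev_foreperiod - fp_mean
  lapse_rate <- if (is.null(params$onset_lapse_rate)) 0 else
    params$onset_lapse_rate
  lapse <- stats::runif(1) < lapse_rate
  if (lapse) {
    t_on <- stats::runif(1, params$onset_base,
                         max(params$onset_lapse_to, params$onset_base))
  } else {
    t_on <- params$onset_base + params$onset_prev_fp_gain * prev_dev +
      stats::rnorm(1, 0, params$onset_jitter_sd)
  }
  t_on <- max(t_on, 0)
  degenerate <- t_on >= trial_end

  ev <- stats::approx(evidence$time_ms, evidence$value, xout = time_ms,
                      method = "constant", rule = 2)$y
  sd_step <- params$noise_sd * sqrt(dt) *
    ifelse(time_ms < fp, params$pre_evidence_noise_frac, 1)
  active <- time_ms >= t_on
  inc <- ifelse(active,
                params$drift_gain * ev * dt + stats::rnorm(n, 0, 1) * sd_step,
                0)
  dv <- cumsum(inc)
  if (any(active)) dv[active] <- dv[active] + params$start_bias

  collapse <- if (is.null(params$bound_collapse)) 0 else params$bound_collapse
  bound_t <- params$bound *
    pmax(1 - collapse * pmax(time_ms - fp, 0) / config$deadline, 0.3)
  cross_idx <- which(abs(dv) >= bound_t)[1]
  choice <- "none"; rt <- NA_real_; crossing_ms <- NA_real_
  if (!is.na(cross_idx)) {
    crossing_ms <- time_ms[cross_idx]
    resp_ms <- crossing_ms + params$motor_delay
    if (resp_ms <= fp + config$deadline) {
      choice <- if (dv[cross_idx] > 0) "right" else "left"
      rt <- resp_ms - fp
      # clamp the path at the bound after commitment
      if (cross_idx < n) dv[(cross_idx + 1):n] <- dv[cross_idx]
    } else {
      crossing_ms <- NA_real_  # crossing too late to register
    }
  }
  list(choice = choice, rt = rt, t_on = t_on, lapse = lapse,
       crossing_ms = crossing_ms, dv = dv, time_ms = time_ms,
       degenerate = degenerate)
}
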