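#' Nominal 128-channel scalp layout
#'
#' BioSemi-style 128-channel montage: labels A1-A32, B1-B32, C1-C32,
#' D1-D32 assigned to a deterministic sunflower (Fibonacci) arrangement on
#' the unit scalp disc (top view, nose at +y). The geometry is a nominal
#' stand-in for the true montage — adequate for spatial weighting,
#' neighbour interpolation and cluster bookkeeping, which is all the
#' pipeline needs — and is documented as such.
#'
#' @return tibble: `channel`, `x`, `y` (unit-disc coordinates).
#' @export
biosemi128_layout <- function() {
  n <- 128
  i <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  r <- 0.95 * sqrt((i - 0.5) / n)
  th <- i * golden
  tibble::tibble(
    channel = paste0(rep(c("A", "B", "C", "D"), each = 32), rep(1:32, 4)),
    x = r * sin(th),
    y = r * cos(th))
}

# site centres on the unit scalp disc (nose +y)
site_centres <- function() {
  tibble::tribble(
    ~site,   ~x,    ~y,
    "Pz",     0.00, -0.35,
    "Oz",     0.00, -0.75,
    "C3",    -0.45,  0.05,
    "C4",     0.45,  0.05,
    "P7",    -0.60, -0.50,
    "P8",     0.60, -0.50,
    "front",  0.00,  0.80)
}

#' Candidate electrode clusters per measurement site
#'
#' Channels within `radius` of each nominal site centre; these are the
#' broad candidate sets from which the data-driven per-subject clusters
#' are picked.
#'
#' @param layout a [biosemi128_layout()] tibble.
#' @param radius candidate radius on the unit disc.
#' @return named list of character vectors of channel labels.
#' @export
site_candidates <- function(layout = biosemi128_layout(), radius = 0.3) {
  sc <- site_centres()
  out <- lapply(seq_len(nrow(sc)), function(i) {
    d <- sqrt((layout$x - sc$x[i])^2 + (layout$y - sc$y[i])^2)
    layout$channel[d <= radius]
  })
  stats::setNames(out, sc$site)
}

# Gaussian spatial weight map centred on a site, unit peak.
site_map <- function(site, layout = biosemi128_layout(), sd = 0.22) {
  sc <- site_centres()
  ctr <- sc[sc$site == site, ]
  d2 <- (layout$x - ctr$x)^2 + (layout$y - ctr$y)^2
  exp(-d2 / (2 * sd^2))
}

# leaky-integrated white noise: a cheap 1/f-like background spectrum
pink_noise <- function(n_ch, n_samp, sd, alpha = 0.98) {
  w <- matrix(stats::rnorm(n_ch * n_samp), n_samp, n_ch)
  x <- apply(w, 2, function(col) stats::filter(col, alpha, method = "recursive"))
  x <- x / sqrt(1 / (1 - alpha^2))        # unit variance, then rescale
  t(x * sd * 0.9 + w * sd * 0.45)         # mostly low-frequency + white floor
}

smooth_bump <- function(n, peak_idx, width_samp) {
  exp(-((seq_len(n) - peak_idx)^2) / (2 * (width_samp / 2.355)^2))
}

#' Forward-model one trial of 128-channel EEG
#'
#' Builds the trial's scalp signal as a sum of spatially weighted
#' components driven by the accumulator path and the stimulus:
#' \itemize{
#'   \item a centro-parietal build-up `cpp_gain * |DV(t)|` on the
#'     Pz-centred map (decaying after the response),
#'   \item tag-frequency oscillations on the Oz map whose amplitudes are
#'     `ssvep_gain * contrast(t)` per grating (gratings task only),
#'   \item 10-30 Hz narrowband noise on the C3/C4 maps whose envelope
#'     desynchronises with the decision variable's excursion toward the
#'     chosen bound (contralateral more than ipsilateral),
#'   \item 1/f-like sensor noise on every channel, and
#'   \item blink and channel-pop artifacts at the configured rates (blinks
#'     dominate the bipolar EOG and spill onto frontal channels).
#' }
#' The output is reference-free, in uV, covering `pre_pad_ms` before
#' stimulus onset to `post_pad_ms` after stimulus offset.
#'
#' @param sim a [simulate_trial_accumulator()] result.
#' @param trial the schedule row the path belongs to.
#' @param stimulus a [render_grating_timecourse()] result, or NULL for the
#'   dot-motion task (which has no frequency tags).
#' @param params a [generative_params()].
#' @param config a [task_config()].
#' @param seed integer seed.
#' @param pre_pad_ms,post_pad_ms recording padding around the trial, ms.
#' @param layout a [biosemi128_layout()].
#' @return list: `eeg` (channels x samples, uV), `eog` (bipolar VEOG,
#'   uV), `time_ms` (relative to stimulus onset), `events` (sample indices
#'   of stimulus onset, sensory change and response; response NA for
#'   misses), `n_blinks`, `pop_channels`, `fs`.
#' @export
synthesize_eeg_trial <- function(sim, trial, stimulus, params, config, seed,
                                 pre_pad_ms = 400, post_pad_ms = 700,
                                 layout = biosemi128_layout()) {
  local_rng(seed)
  fs <- params$fs
  dt <- 1000 / fs
  fp <- trial$foreperiod
  trial_end <- fp + config$evidence_duration
  time_ms <- seq(-pre_pad_ms, trial_end + post_pad_ms, by = dt)
  n <- length(time_ms)
  n_ch <- nrow(layout)

  # decision variable on the recording grid (0 outside the trial);
  # decays after the response
  dv <- stats::approx(sim$time_ms, sim$dv, xout = time_ms,
                      method = "constant", rule = 2, yleft = 0)$y
  dv[time_ms < 0] <- 0
  resp_ms <- if (!is.na(sim$rt)) fp + sim$rt else NA_real_
  if (!is.na(resp_ms)) {
    post <- time_ms > resp_ms
    dv[post] <- dv[which(!post)[sum(!post)]] * exp(-(time_ms[post] - resp_ms) / 300)
  }

  eeg <- pink_noise(n_ch, n, params$sensor_noise_sd)

  # centro-parietal accumulation component
  eeg <- eeg + site_map("Pz", layout) %o% (params$cpp_gain * abs(dv))

  # frequency-tagged occipital oscillations (gratings task); the per-trial
  # phase-reversal counterbalancing is modelled as a random sign, so the
  # tags cancel in trial averages as they do in the recorded data
  if (!is.null(stimulus)) {
    tsec <- time_ms / 1000
    phase_sign <- if (isTRUE(stimulus$phase_reversed)) -1 else 1
    for (side in c("left", "right")) {
      f <- config$flicker_freqs[[side]]
      contrast <- stats::approx(stimulus$time_ms,
                                stimulus[[paste0("contrast_", side)]],
                                xout = time_ms, method = "constant",
                                rule = 2, yleft = 0)$y
      contrast[time_ms < 0 | time_ms > trial_end] <- 0
      osc <- params$ssvep_gain * contrast * phase_sign *
        sin(2 * pi * f * tsec)
      eeg <- eeg + site_map("Oz", layout) %o% osc
    }
  }

  # effector-selective Mu/Beta desynchronisation
  bp <- signal::butter(2, c(10, 30) / (fs / 2), type = "pass")
  dv_chosen <- switch(sim$choice, right = dv, left = -dv, abs(dv))
  desync <- params$mubeta_dv_gain * pmax(dv_chosen, 0)
  env_contra <- pmax(params$mubeta_base - desync, 0.2)
  env_ipsi <- pmax(params$mubeta_base - params$mubeta_ipsi_frac * desync, 0.2)
  # left hand presses left button: left choice -> right (contralateral)
  # hemisphere C4
  contra_site <- if (sim$choice == "left") "C4" else "C3"
  ipsi_site <- if (contra_site == "C3") "C4" else "C3"
  nb <- function() as.numeric(signal::filtfilt(bp, stats::rnorm(n)))
  eeg <- eeg + site_map(contra_site, layout) %o% (env_contra * nb() * 3)
  eeg <- eeg + site_map(ipsi_site, layout) %o% (env_ipsi * nb() * 3)

  # artifacts
  eog <- stats::rnorm(n, 0, 3)
  n_blinks <- stats::rpois(1, params$blink_rate)
  blink_map <- site_map("front", layout, sd = 0.3)
  if (n_blinks > 0) {
    for (b in seq_len(n_blinks)) {
      # place blinks inside the stimulus-aligned epoch so the rejection
      # rules can see them
      at <- sample(which(time_ms >= 0 & time_ms <= trial_end), 1)
      shape <- smooth_bump(n, at, width_samp = round(0.15 * fs))
      eog <- eog + params$blink_amplitude * shape
      eeg <- eeg + blink_map %o% (0.35 * params$blink_amplitude * shape)
    }
  }
  pop_channels <- integer(0)
  n_pops <- stats::rpois(1, params$pop_rate)
  if (n_pops > 0) {
    for (p in seq_len(n_pops)) {
      ch <- sample.int(n_ch, 1)
      at <- sample(which(time_ms >= 0 & time_ms <= trial_end), 1)
      len <- round(0.2 * fs)
      idx <- at:min(at + len, n)
      eeg[ch, idx] <- eeg[ch, idx] + params$pop_amplitude
      pop_channels <- c(pop_channels, ch)
    }
  }

  events <- list(
    stimulus = which.min(abs(time_ms - 0)),
    change = which.min(abs(time_ms - fp)),
    response = if (!is.na(resp_ms)) which.min(abs(time_ms - resp_ms)) else NA_integer_)
  list(eeg = eeg, eog = eog, time_ms = time_ms, events = events,
       n_blinks = n_blinks, pop_channels = unique(pop_channels), fs = fs)
}
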