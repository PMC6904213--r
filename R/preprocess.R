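#' Filter, detrend and average-reference continuous EEG
#'
#' Applies the standard continuous-data cleaning chain: linear detrend,
#' zero-phase high-pass at 0.05 Hz (forward-backward second-order
#' Butterworth; a windowed-sinc kernel at this cutoff would be longer than
#' the recording), zero-phase windowed-sinc low-pass at 35 Hz, and
#' re-referencing to the channel average.
#'
#' @param eeg channels x samples matrix, uV.
#' @param fs sampling rate, Hz.
#' @param highpass,lowpass band edges, Hz.
#' @param fir_length low-pass kernel length (odd); the default gives a
#'   transition band of roughly 9 Hz and >40 dB stopband attenuation at
#'   50 Hz.
#' @return filtered matrix of the same shape.
#' @export
filter_and_reference <- function(eeg, fs = 512, highpass = 0.05,
                                 lowpass = 35, fir_length = 185) {
  if (!all(is.finite(eeg))) stop("non-finite samples in input")
  n <- ncol(eeg)
  tt <- seq_len(n)
  # linear detrend per channel (closed-form regression on time)
  tc <- tt - mean(tt)
  beta <- (eeg %*% tc) / sum(tc^2)
  eeg <- eeg - beta %*% t(tc) - rowMeans(eeg)

  hp <- signal::butter(2, highpass / (fs / 2), type = "high")
  for (ch in seq_len(nrow(eeg))) {
    eeg[ch, ] <- signal::filtfilt(hp, eeg[ch, ])
  }
  eeg <- apply_fir_lowpass(eeg, fs, lowpass, fir_length)
  sweep(eeg, 2, colMeans(eeg))
}

#' Low-pass FIR kernel used by the preprocessing chain
#' @param fs sampling rate, Hz.
#' @param lowpass cutoff, Hz.
#' @param fir_length kernel length (odd).
#' @return numeric kernel (unit DC gain, linear phase).
#' @export
fir_lowpass_kernel <- function(fs = 512, lowpass = 35, fir_length = 185) {
  as.numeric(signal::fir1(fir_length - 1, lowpass / (fs / 2), type = "low"))
}

# zero-phase application along rows via FFT, delay-compensated
apply_fir_lowpass <- function(eeg, fs, lowpass, fir_length) {
  h <- fir_lowpass_kernel(fs, lowpass, fir_length)
  m <- length(h); delay <- (m - 1) %/% 2
  n <- ncol(eeg)
  nfft <- n + m - 1
  H <- stats::fft(c(h, rep(0, nfft - m)))
  X <- stats::mvfft(t(cbind(eeg, matrix(0, nrow(eeg), nfft - n))))
  Y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  t(Y)[, (delay + 1):(delay + n), drop = FALSE]
}

#' Cut stimulus- or response-aligned epochs and baseline-correct
#'
#' Stimulus-aligned epochs run from stimulus onset to stimulus offset
#' (0 to foreperiod + 2000 ms, so 0-2800/0-3200/0-3600 ms by foreperiod);
#' response-aligned epochs run from -1000 ms to +600 ms around the
#' response. Every epoch is baseline-corrected by subtracting each
#' channel's mean over 500-550 ms post stimulus onset, computed in the
#' stimulus frame for both alignments. Trials whose window falls outside
#' the recording (or, for response alignment, that have no response) are
#' dropped with a logged cause.
#'
#' @param recordings per-trial list as produced by [generate_dataset()]
#'   (`$eeg`): each element has `eeg`, `eog`, `time_ms`, `events`, `fs`.
#' @param trials the matching trial tibble (needs `foreperiod`).
#' @param alignment `"stimulus"` or `"response"`.
#' @param channels channel labels (defaults to the nominal 128 montage).
#' @param filter apply [filter_and_reference()] to each recording first.
#' @return list of class `epoch_set`: `data` (list of channels x samples
#'   matrices), `eog` (list of vectors), `time` (list of ms axes relative
#'   to the alignment event), `alignment`, `fs`, `channels`, `trial_index`,
#'   `foreperiod`, `retained` (logical over the input trials),
#'   `drop_cause`, `interpolated` (empty until artifact handling).
#' @export
epoch_and_baseline <- function(recordings, trials,
                               alignment = c("stimulus", "response"),
                               channels = biosemi128_layout()$channel,
                               filter = TRUE) {
  alignment <- match.arg(alignment)
  n_in <- length(recordings)
  keep <- logical(n_in); cause <- rep(NA_character_, n_in)
  data <- list(); eogs <- list(); times <- list(); idx <- integer(0)
  for (i in seq_len(n_in)) {
    rec <- recordings[[i]]
    fs <- rec$fs
    eeg <- rec$eeg
    if (filter) eeg <- filter_and_reference(eeg, fs = fs)
    t_ms <- rec$time_ms
    fp <- trials$foreperiod[i]
    bl <- t_ms >= 500 & t_ms <= 550
    baseline <- rowMeans(eeg[, bl, drop = FALSE])
    eeg <- eeg - baseline
    if (alignment == "stimulus") {
      win <- t_ms >= 0 & t_ms <= fp + 2000 + 1e-9
      rel0 <- 0
    } else {
      if (is.na(rec$events$response)) {
        cause[i] <- "no_response"; next
      }
      resp_ms <- t_ms[rec$events$response]
      win <- t_ms >= resp_ms - 1000 & t_ms <= resp_ms + 600 + 1e-9
      if (t_ms[1] > resp_ms - 1000 || t_ms[length(t_ms)] < resp_ms + 600) {
        cause[i] <- "edge"; next
      }
      rel0 <- resp_ms
    }
    keep[i] <- TRUE
    idx <- c(idx, i)
    data[[length(data) + 1]] <- eeg[, win, drop = FALSE]
    eogs[[length(eogs) + 1]] <- rec$eog[win]
    times[[length(times) + 1]] <- t_ms[win] - rel0
  }
  structure(
    list(data = data, eog = eogs, time = times, alignment = alignment,
         fs = recordings[[1]]$fs, channels = channels,
         trial_index = idx, foreperiod = trials$foreperiod[idx],
         retained = keep, drop_cause = cause,
         interpolated = character(0)),
    class = "epoch_set")
}

#' Artifact rejection and channel interpolation
#'
#' Applies the study's artifact rules to a stimulus-aligned epoch set:
#' a channel whose own |amplitude| exceeds 100 uV on more than 10% of
#' trials is interpolated (distance-weighted average of its nearest
#' neighbours on the montage), with at most 10% of channels interpolated;
#' then a trial is rejected if the bipolar EOG exceeds 200 uV in absolute
#' value or any remaining scalp channel exceeds 100 uV anywhere in the
#' epoch. The subject is flagged for exclusion if more than 40% of trials
#' are lost.
#'
#' @param epochs a stimulus-aligned [epoch_and_baseline()] result.
#' @param layout montage coordinates, a [biosemi128_layout()] tibble.
#' @param eog_threshold,channel_threshold rejection thresholds, uV.
#' @param interp_trial_frac channel artifact-count fraction above which a
#'   channel is interpolated.
#' @param interp_channel_cap maximum fraction of channels interpolated.
#' @param exclude_frac trial-loss fraction above which the subject is
#'   flagged excluded.
#' @param n_neighbours neighbours used for interpolation.
#' @return list: `epochs` (cleaned set, rejected trials removed,
#'   `interpolated` filled in) and `report` (class `artifact_report`):
#'   per-trial flags and causes, per-channel artifact counts,
#'   interpolation decisions, trial-loss fraction, `excluded` flag.
#' @export
reject_and_interpolate <- function(epochs, layout = biosemi128_layout(),
                                   eog_threshold = 200,
                                   channel_threshold = 100,
                                   interp_trial_frac = 0.10,
                                   interp_channel_cap = 0.10,
                                   exclude_frac = 0.40,
                                   n_neighbours = 6) {
  stopifnot(epochs$alignment == "stimulus")
  n_tr <- length(epochs$data)
  n_ch <- length(epochs$channels)

  ch_max <- vapply(epochs$data, function(m) apply(abs(m), 1, max),
                   numeric(n_ch))                       # channels x trials
  counts <- rowSums(ch_max > channel_threshold)
  cand <- which(counts > interp_trial_frac * n_tr)
  cap <- floor(interp_channel_cap * n_ch)
  capped <- FALSE
  if (length(cand) > cap) {
    capped <- TRUE
    warning(length(cand), " channels qualify for interpolation; capping at ",
            cap)
    cand <- cand[order(counts[cand], decreasing = TRUE)][seq_len(cap)]
  }
  interp_ch <- sort(cand)

  if (length(interp_ch) > 0) {
    W <- interp_weights(interp_ch, layout, setdiff(seq_len(n_ch), interp_ch),
                        n_neighbours)
    for (t in seq_len(n_tr)) {
      epochs$data[[t]][interp_ch, ] <- W %*% epochs$data[[t]]
    }
    ch_max[interp_ch, ] <- vapply(epochs$data, function(m)
      apply(abs(m[interp_ch, , drop = FALSE]), 1, max),
      numeric(length(interp_ch)))
  }

  eog_max <- vapply(epochs$eog, function(v) max(abs(v)), numeric(1))
  rej_eog <- eog_max > eog_threshold
  rej_chan <- !rej_eog & (apply(ch_max > channel_threshold, 2, any))
  rejected <- rej_eog | rej_chan
  cause <- rep(NA_character_, n_tr)
  cause[rej_eog] <- "EOG"; cause[rej_chan] <- "channel"

  loss <- mean(rejected)
  report <- structure(
    list(trial_rejected = rejected, cause = cause,
         channel_counts = stats::setNames(counts, epochs$channels),
         interpolated = epochs$channels[interp_ch],
         interpolation_capped = capped,
         n_input = n_tr, n_rejected = sum(rejected),
         loss_fraction = loss, excluded = loss > exclude_frac),
    class = "artifact_report")

  keep <- !rejected
  epochs$data <- epochs$data[keep]
  epochs$eog <- epochs$eog[keep]
  epochs$time <- epochs$time[keep]
  epochs$trial_index <- epochs$trial_index[keep]
  epochs$foreperiod <- epochs$foreperiod[keep]
  epochs$interpolated <- union(epochs$interpolated, epochs$channels[interp_ch])
  list(epochs = epochs, report = report)
}

# rows: weights mapping all channels -> interpolated channels
interp_weights <- function(interp_ch, layout, good_ch, n_neighbours) {
  W <- matrix(0, length(interp_ch), nrow(layout))
  for (j in seq_along(interp_ch)) {
    i <- interp_ch[j]
    d <- sqrt((layout$x - layout$x[i])^2 + (layout$y - layout$y[i])^2)
    d[-good_ch] <- Inf
    nb <- order(d)[seq_len(n_neighbours)]
    w <- 1 / d[nb]
    W[j, nb] <- w / sum(w)
  }
  W
}
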