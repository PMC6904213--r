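#' Pick a subject's measurement electrodes within a candidate cluster
#'
#' The k candidate channels at which the grand-average topography is
#' maximal, with the sign convention of the signal being measured: most
#' positive for the centro-parietal positivity, most negative for the N2,
#' largest absolute value for Mu/Beta lateralisation. Ties break by
#' channel-label order.
#'
#' @param topography named numeric vector, one grand-average value per
#'   channel.
#' @param candidates channel labels forming the broad candidate cluster.
#' @param k number of channels to select (4 for CPP/SSVEP/Mu-Beta, 3 per
#'   N2 site).
#' @param polarity `"positive"`, `"negative"` or `"absolute"`.
#' @return character vector of k selected labels (subset of candidates).
#' @export
select_electrode_cluster <- function(topography, candidates, k,
                                     polarity = c("positive", "negative",
                                                  "absolute")) {
  polarity <- match.arg(polarity)
  if (k > length(candidates)) {
    stop("k = ", k, " exceeds the ", length(candidates),
         " candidate channels")
  }
  v <- topography[candidates]
  if (anyNA(v)) stop("topography does not cover all candidates")
  score <- switch(polarity, positive = v, negative = -v, absolute = abs(v))
  candidates[order(-score, candidates)[seq_len(k)]]
}

#' Windowed amplitude or slope of a single-trial waveform
#'
#' Amplitude is the mean over the window; slope is the ordinary
#' least-squares line slope over the window samples, in uV/ms.
#'
#' @param waveform numeric vector, one sample per time point.
#' @param time_ms its time axis (ms, relative to the alignment event).
#' @param window length-2 ms interval.
#' @param mode `"amplitude"` or `"slope"`.
#' @param trial trial identifier used in error messages.
#' @return numeric scalar.
#' @export
measure_window <- function(waveform, time_ms, window,
                           mode = c("amplitude", "slope"), trial = NA) {
  mode <- match.arg(mode)
  if (window[1] < time_ms[1] - 1e-9 ||
      window[2] > time_ms[length(time_ms)] + 1e-9) {
    stop("window [", window[1], ", ", window[2], "] ms lies outside the ",
         "epoch [", round(time_ms[1]), ", ", round(time_ms[length(time_ms)]),
         "] ms (trial ", trial, ")")
  }
  keep <- time_ms >= window[1] & time_ms <= window[2]
  if (mode == "amplitude") mean(waveform[keep])
  else ols_slope(time_ms[keep], waveform[keep])
}

#' Flag outlier trials beyond 3 SD of the within-subject mean
#'
#' Single-pass rule: flags are computed once from the mean and SD of all
#' values and are not recomputed after removal. Zero variance yields no
#' flags.
#'
#' @param values numeric vector (one value per trial, typically the
#'   pre-response measure).
#' @param n_sd rejection threshold in SD units.
#' @return logical vector of flags.
#' @export
reject_outlier_trials <- function(values, n_sd = 3) {
  if (length(values) < 3) stop("need at least 3 trials")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(values)))
  abs(values - mean(values)) > n_sd * s
}

#' Equal-count trial binning
#'
#' Assigns trials to equal-count bins by RT, to previous-foreperiod level,
#' or to the shallow/steep integral-slope split. RT binning is performed
#' within whatever trial set is passed in (bin within foreperiod levels by
#' grouping before calling); ties are broken deterministically by trial
#' order. Bin sizes differ by at most one.
#'
#' @param trials tibble with the binning variable (`rt`,
#'   `prev_foreperiod`, or `integral_slope`).
#' @param by binning mode.
#' @param n_bins number of RT bins (>= 2); ignored for the other modes.
#' @return integer bin index per trial (for `prev_foreperiod`, the level's
#'   rank among the foreperiod set).
#' @export
bin_trials <- function(trials, by = c("rt", "prev_foreperiod",
                                      "integral_slope"), n_bins = 6) {
  by <- match.arg(by)
  n <- nrow(trials)
  if (by == "rt") {
    if (n_bins < 2) stop("n_bins must be >= 2 for RT binning")
    if (n < n_bins) stop("fewer trials (", n, ") than bins (", n_bins, ")")
    ord <- order(trials$rt, seq_len(n))
    sizes <- rep(n %/% n_bins, n_bins)
    extra <- n %% n_bins
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    bins <- integer(n)
    bins[ord] <- rep(seq_len(n_bins), times = sizes)
    bins
  } else if (by == "prev_foreperiod") {
    lev <- sort(unique(stats::na.omit(trials$prev_foreperiod)))
    match(trials$prev_foreperiod, lev)
  } else {
    if (is.null(trials$integral_slope)) stop("integral_slope column missing")
    split <- split_by_integral_slope(
      lapply(trials$integral_slope, function(s) list(slope = s)))
    bins <- integer(n)
    bins[split$shallow] <- 1L; bins[split$steep] <- 2L
    bins
  }
}

#' Cluster-averaged single-trial waveforms
#'
#' @param epochs an [epoch_and_baseline()] result.
#' @param channels electrode cluster labels.
#' @return list per trial: `value` (uV), `time_ms`.
#' @export
cluster_waveform <- function(epochs, channels) {
  ch <- match(channels, epochs$channels)
  if (anyNA(ch)) stop("unknown channels")
  lapply(seq_along(epochs$data), function(t)
    list(value = colMeans(epochs$data[[t]][ch, , drop = FALSE]),
         time_ms = epochs$time[[t]]))
}

#' Grand-average topography in a window
#'
#' Mean over trials of each channel's mean amplitude in the window;
#' the input used for data-driven electrode selection.
#'
#' @param epochs an [epoch_and_baseline()] result.
#' @param window ms interval in the epoch's frame.
#' @return named numeric vector over channels.
#' @export
grand_average_topography <- function(epochs, window) {
  vals <- vapply(seq_along(epochs$data), function(t) {
    keep <- epochs$time[[t]] >= window[1] & epochs$time[[t]] <= window[2]
    rowMeans(epochs$data[[t]][, keep, drop = FALSE])
  }, numeric(length(epochs$channels)))
  stats::setNames(rowMeans(vals), epochs$channels)
}

#' Per-trial windowed decision-signal measurements
#'
#' The study's standard measurement set for a cluster-averaged waveform:
#' pre-evidence amplitude (100 ms window centred on the sensory change)
#' and slope (-250..+50 ms re change) from stimulus-aligned epochs;
#' pre-response amplitude (-150..-50 ms) and slope (-500..-200 ms) from
#' response-aligned epochs; N2 amplitude (200-300 ms post change).
#'
#' @param stim_epochs,resp_epochs stimulus- and response-aligned
#'   [epoch_and_baseline()] results (either may be NULL to skip its
#'   measures).
#' @param channels electrode cluster labels.
#' @param trials the trial tibble (for foreperiods).
#' @param pre_evidence_win,pre_evidence_slope_win,pre_response_win,
#'   pre_response_slope_win,n2_win measurement windows, ms. The
#'   pre-response slope window follows the -500..-200 ms definition; the
#'   -450..-150 ms variant can be passed instead.
#' @return tibble keyed by `trial_index` with one column per measure (NA
#'   where the trial lacks that alignment).
#' @export
measure_decision_signals <- function(stim_epochs, resp_epochs, channels,
                                     trials,
                                     pre_evidence_win = c(-50, 50),
                                     pre_evidence_slope_win = c(-250, 50),
                                     pre_response_win = c(-150, -50),
                                     pre_response_slope_win = c(-500, -200),
                                     n2_win = c(200, 300)) {
  all_idx <- sort(unique(c(
    if (!is.null(stim_epochs)) stim_epochs$trial_index,
    if (!is.null(resp_epochs)) resp_epochs$trial_index)))
  out <- tibble::tibble(trial_index = all_idx,
                        pre_evidence_amp = NA_real_,
                        pre_evidence_slope = NA_real_,
                        n2_amp = NA_real_,
                        pre_response_amp = NA_real_,
                        pre_response_slope = NA_real_)
  if (!is.null(stim_epochs)) {
    wf <- cluster_waveform(stim_epochs, channels)
    for (t in seq_along(wf)) {
      i <- match(stim_epochs$trial_index[t], out$trial_index)
      fp <- stim_epochs$foreperiod[t]
      tm <- wf[[t]]$time_ms - fp     # re sensory change
      out$pre_evidence_amp[i] <- measure_window(wf[[t]]$value, tm,
                                                pre_evidence_win, "amplitude",
                                                out$trial_index[i])
      out$pre_evidence_slope[i] <- measure_window(wf[[t]]$value, tm,
                                                  pre_evidence_slope_win,
                                                  "slope", out$trial_index[i])
      out$n2_amp[i] <- measure_window(wf[[t]]$value, tm, n2_win, "amplitude",
                                      out$trial_index[i])
    }
  }
  if (!is.null(resp_epochs)) {
    wf <- cluster_waveform(resp_epochs, channels)
    for (t in seq_along(wf)) {
      i <- match(resp_epochs$trial_index[t], out$trial_index)
      tm <- wf[[t]]$time_ms
      out$pre_response_amp[i] <- measure_window(wf[[t]]$value, tm,
                                                pre_response_win, "amplitude",
                                                out$trial_index[i])
      out$pre_response_slope[i] <- measure_window(wf[[t]]$value, tm,
                                                  pre_response_slope_win,
                                                  "slope", out$trial_index[i])
    }
  }
  out
}

#' Threshold-crossing estimate of accumulation onset
#'
#' First time at which the trial-averaged cluster waveform exceeds twice
#' the SD of its own baseline span. Epochs of different lengths are
#' aligned at stimulus onset and averaged over their common span.
#'
#' @param epochs stimulus-aligned [epoch_and_baseline()] result (typically
#'   restricted to one foreperiod).
#' @param channels electrode cluster labels.
#' @param baseline_span ms window whose SD sets the threshold.
#' @param search_from earliest time considered, ms.
#' @param sustain_ms the crossing must hold continuously for this long to
#'   count as an onset (guards against transient noise excursions).
#' @return list: `onset_ms` (NA if never crossed), `threshold`,
#'   `average` (waveform), `time_ms`.
#' @export
#' Onset recovery against simulator ground truth
#'
#' Runs the threshold-crossing onset estimator on long-foreperiod trials,
#' within each previous-foreperiod level separately (the sequential onset
#' shift makes the pooled average a mixture whose rise reflects only the
#' earliest stratum), and pairs each estimate with the mean true onset of
#' the regular (non-lapse) trials it averaged over.
#'
#' @param epochs stimulus-aligned, cleaned [epoch_and_baseline()] result.
#' @param trials the generating trial tibble with hidden-truth columns
#'   `t_on` and (optionally) `lapse`.
#' @param channels measurement cluster labels.
#' @param foreperiod foreperiod level to analyse (default the longest
#'   present).
#' @param min_n strata with fewer trials are skipped: the estimator works
#'   on a trial average, and with only a handful of trials its noise floor
#'   (hence its threshold) is too high for the crossing time to be
#'   meaningful. Block-balanced schedules make exact foreperiod repeats
#'   rare, so the repeat stratum often falls below this.
#' @return tibble: `prev_foreperiod`, `n`, `estimated_onset_ms`,
#'   `true_onset_ms`, `error_ms`.
#' @export
onset_recovery_table <- function(epochs, trials, channels,
                                 foreperiod = max(epochs$foreperiod),
                                 min_n = 20) {
  lapse <- if (!is.null(trials$lapse)) trials$lapse else
    rep(FALSE, nrow(trials))
  prev <- trials$prev_foreperiod[epochs$trial_index]
  rows <- lapply(sort(unique(stats::na.omit(prev))), function(pv) {
    keep <- epochs$foreperiod == foreperiod & !is.na(prev) & prev == pv
    if (sum(keep) < min_n) return(NULL)
    sub <- epochs
    for (f in c("data", "eog", "time")) sub[[f]] <- sub[[f]][keep]
    sub$trial_index <- sub$trial_index[keep]
    sub$foreperiod <- sub$foreperiod[keep]
    # baseline ends before the earliest stratum onset can plausibly rise
    est <- estimate_onset(sub, channels, baseline_span = c(150, 400),
                          search_from = 400)
    idx <- sub$trial_index
    truth <- mean(trials$t_on[idx][!lapse[idx]])
    tibble::tibble(prev_foreperiod = pv, n = sum(keep),
                   estimated_onset_ms = est$onset_ms,
                   true_onset_ms = truth,
                   error_ms = est$onset_ms - truth)
  })
  dplyr::bind_rows(rows)
}

estimate_onset <- function(epochs, channels, baseline_span = c(200, 600),
                           search_from = 200, sustain_ms = 100) {
  wf <- cluster_waveform(epochs, channels)
  n_min <- min(vapply(wf, function(w) length(w$value), integer(1)))
  avg <- rowMeans(vapply(wf, function(w) w$value[seq_len(n_min)],
                         numeric(n_min)))
  tm <- wf[[1]]$time_ms[seq_len(n_min)]
  bl <- tm >= baseline_span[1] & tm <= baseline_span[2]
  thr <- 2 * stats::sd(avg[bl])
  n_sustain <- max(1L, as.integer(round(sustain_ms * epochs$fs / 1000)))
  above <- tm >= search_from & avg > thr
  run <- rle(above)
  ends <- cumsum(run$lengths)
  ok <- which(run$values & run$lengths >= n_sustain)
  onset <- if (length(ok)) tm[ends[ok[1]] - run$lengths[ok[1]] + 1L] else NA_real_
  list(onset_ms = onset, threshold = thr, average = avg, time_ms = tm)
}
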