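#' Short-time Fourier amplitude decomposition
#'
#' Slides a 400 ms rectangular window in 50 ms steps across each epoch and
#' evaluates the discrete Fourier amplitude on the nominal 2.5 Hz frequency
#' grid (the reciprocal of the window length). Magnitudes are divided by
#' half the window length in samples, so a pure sinusoid of amplitude A
#' measures A at its own bin; each segment is labelled by its median time.
#' The 400 ms window spans exactly 8 cycles at 20 Hz and 10 at 25 Hz, which
#' is what makes the two tag frequencies leakage-free.
#'
#' At 512 Hz the nominal 400 ms window is 204.8 samples; segments use 205
#' samples with the DFT evaluated at the nominal 2.5 Hz bins, preserving
#' the stated resolution and the integer-cycle property to well under 1%.
#'
#' @param epochs an [epoch_and_baseline()] result.
#' @param seg_ms window length, ms.
#' @param step_ms hop between segment starts, ms.
#' @param f_max highest frequency evaluated, Hz.
#' @return list of class `tfr`: `amp` (per-trial channels x frequencies x
#'   segments arrays, uV), `freqs` (Hz), `seg_times` (per-trial median-time
#'   labels, ms in the epoch's frame), plus the epoch metadata.
#' @export
stft_amplitude <- function(epochs, seg_ms = 400, step_ms = 50, f_max = 40) {
  fs <- epochs$fs
  n_seg_samp <- as.integer(ceiling(seg_ms * fs / 1000))
  freqs <- seq(0, f_max, by = 1000 / seg_ms)
  amp <- vector("list", length(epochs$data))
  seg_times <- vector("list", length(epochs$data))
  for (t in seq_along(epochs$data)) {
    m <- epochs$data[[t]]
    tt <- epochs$time[[t]]
    ep_len <- tt[length(tt)] - tt[1]
    if (ep_len < seg_ms) {
      stop("epoch of ", round(ep_len), " ms is shorter than one ", seg_ms,
           " ms segment (trial ", epochs$trial_index[t], ")")
    }
    starts <- seq(tt[1], tt[length(tt)] - seg_ms, by = step_ms)
    n_s <- length(starts)
    a <- array(0, c(nrow(m), length(freqs), n_s))
    tsec <- (seq_len(n_seg_samp) - 1) / fs
    E <- exp(-2i * pi * outer(freqs, tsec))    # nfreq x nsamp
    for (s in seq_len(n_s)) {
      i0 <- which.min(abs(tt - starts[s]))
      idx <- i0:(i0 + n_seg_samp - 1)
      if (idx[length(idx)] > ncol(m)) idx <- (ncol(m) - n_seg_samp + 1):ncol(m)
      seg <- t(m[, idx, drop = FALSE])         # nsamp x nch
      a[, , s] <- t(Mod(E %*% seg)) / (n_seg_samp / 2)
    }
    amp[[t]] <- a
    seg_times[[t]] <- starts + seg_ms / 2
  }
  structure(
    list(amp = amp, freqs = freqs, seg_times = seg_times,
         channels = epochs$channels, alignment = epochs$alignment,
         fs = fs, trial_index = epochs$trial_index,
         foreperiod = epochs$foreperiod),
    class = "tfr")
}

# index of a frequency on the tfr grid
freq_bin <- function(tfr, f) {
  i <- which(abs(tfr$freqs - f) < 1e-6)
  if (length(i) != 1) stop("frequency ", f, " Hz is not on the bin grid")
  i
}

#' SSVEP signal-to-noise ratio
#'
#' Amplitude at a tag frequency divided by the mean amplitude at the
#' immediately adjacent frequencies (two bins on each side, excluding the
#' other tag frequency and its harmonics if they fall in that set),
#' averaged over the given electrode cluster first.
#'
#' @param tfr an [stft_amplitude()] result.
#' @param tag_freq tag frequency, Hz (must sit on the bin grid).
#' @param channels electrode cluster labels to average over.
#' @param exclude_freqs frequencies never used as noise bins (the other
#'   tag and harmonics).
#' @param n_adjacent adjacent bins per side.
#' @return list per trial of SNR vectors over segments.
#' @export
ssvep_snr <- function(tfr, tag_freq, channels,
                      exclude_freqs = c(20, 25, 40, 50), n_adjacent = 2) {
  ib <- freq_bin(tfr, tag_freq)
  ch <- match(channels, tfr$channels)
  if (anyNA(ch)) stop("unknown channels: ",
                      paste(channels[is.na(ch)], collapse = ", "))
  side <- setdiff(c(ib - seq_len(n_adjacent), ib + seq_len(n_adjacent)),
                  c(0, length(tfr$freqs) + 1))
  side <- side[side >= 1 & side <= length(tfr$freqs)]
  side <- side[!tfr$freqs[side] %in% setdiff(exclude_freqs, tag_freq)]
  if (length(side) == 0) stop("no adjacent noise bins left after exclusions")
  lapply(tfr$amp, function(a) {
    sig <- apply(a[ch, ib, , drop = FALSE], 3, mean)
    noise <- apply(a[ch, side, , drop = FALSE], 3, mean)
    sig / noise
  })
}

#' Target-minus-nontarget difference SSVEP
#'
#' Assigns the two tag-frequency SNR traces their per-trial roles (the
#' target is the contrast-incremented grating) and subtracts non-target
#' from target. Swapping the role labels negates the result exactly.
#'
#' @param tfr an [stft_amplitude()] result.
#' @param trials trial tibble covering the tfr's `trial_index` (needs
#'   `target`).
#' @param config a [task_config()] (for the side-to-frequency mapping).
#' @param channels electrode cluster labels.
#' @return list per trial: `target`, `nontarget`, `d_ssvep` (vectors over
#'   segments), `seg_times`.
#' @export
d_ssvep <- function(tfr, trials, config, channels) {
  snr <- lapply(config$flicker_freqs, function(f)
    ssvep_snr(tfr, f, channels))
  lapply(seq_along(tfr$amp), function(t) {
    tgt_side <- trials$target[trials$index == tfr$trial_index[t]]
    other <- setdiff(names(config$flicker_freqs), tgt_side)
    list(target = snr[[tgt_side]][[t]],
         nontarget = snr[[other]][[t]],
         d_ssvep = snr[[tgt_side]][[t]] - snr[[other]][[t]],
         seg_times = tfr$seg_times[[t]])
  })
}

#' Mu/Beta amplitude and lateralisation
#'
#' Averages STFT amplitude over the 10-30 Hz band (excluding the 20 and
#' 25 Hz tag bins, which carry sensory rather than motor activity) within
#' each hemisphere's electrode cluster, optionally baseline-corrects
#' against the segment labelled 550 ms post stimulus onset, and computes
#' the lateralisation index contralateral minus ipsilateral to the
#' response hand.
#'
#' @param tfr an [stft_amplitude()] result.
#' @param hands per-trial response hand ("left"/"right", NA skipped with a
#'   log), one entry per tfr trial.
#' @param clusters named list with channel vectors `C3` (left hemisphere)
#'   and `C4` (right hemisphere).
#' @param band band limits, Hz.
#' @param exclude_freqs bins dropped from the band average.
#' @param baseline `"550ms"` (stimulus-aligned epochs), a numeric
#'   per-trial list of hemisphere baselines from a stimulus-aligned run,
#'   or NULL for none.
#' @return list of class `mu_beta_trace`: per trial `contra`, `ipsi`,
#'   `lateralisation` (vectors over segments), `seg_times`, `skipped`
#'   (trials without a hand).
#' @export
mu_beta_lateralisation <- function(tfr, hands, clusters,
                                   band = c(10, 30),
                                   exclude_freqs = c(20, 25),
                                   baseline = "550ms") {
  fb <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2] &
                !tfr$freqs %in% exclude_freqs)
  ch <- lapply(clusters[c("C3", "C4")], function(cc) match(cc, tfr$channels))
  n_tr <- length(tfr$amp)
  out <- vector("list", n_tr)
  skipped <- integer(0)
  for (t in seq_len(n_tr)) {
    if (is.na(hands[t])) {
      skipped <- c(skipped, tfr$trial_index[t])
      next
    }
    hemi <- lapply(ch, function(cc)
      apply(tfr$amp[[t]][cc, fb, , drop = FALSE], 3, mean))
    if (identical(baseline, "550ms")) {
      ib <- which.min(abs(tfr$seg_times[[t]] - 550))
      # epoch grids need not contain t = 0 exactly; accept the segment
      # whose label is within half a hop of 550 ms
      if (abs(tfr$seg_times[[t]][ib] - 550) > 25) {
        stop("no segment labelled 550 ms; baseline needs stimulus-aligned epochs")
      }
      hemi <- lapply(hemi, function(v) v - v[ib])
    } else if (is.list(baseline)) {
      hemi$C3 <- hemi$C3 - baseline[[t]]["C3"]
      hemi$C4 <- hemi$C4 - baseline[[t]]["C4"]
    }
    contra <- if (hands[t] == "left") hemi$C4 else hemi$C3
    ipsi <- if (hands[t] == "left") hemi$C3 else hemi$C4
    out[[t]] <- list(contra = contra, ipsi = ipsi,
                     lateralisation = contra - ipsi,
                     seg_times = tfr$seg_times[[t]])
  }
  structure(list(trials = out, skipped = skipped), class = "mu_beta_trace")
}
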