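#' Grating contrast and flicker timecourse
#'
#' Per-frame contrast of the two overlaid tilted gratings for one trial.
#' Both gratings sit at the baseline contrast throughout the foreperiod;
#' at the sensory change the target steps up by `contrast_delta` while the
#' non-target steps down by the same amount, and both hold the new level for
#' the full evidence period. Each grating is luminance-modulated on/off at
#' its tag frequency (left 20 Hz, right 25 Hz); the per-trial phase-reversal
#' counterbalancing is carried as a binary flag that does not alter contrast
#' energy.
#'
#' @param trial one row of a [make_trial_schedule()] tibble (needs
#'   `foreperiod` and `target`).
#' @param config a [task_config()].
#' @param phase_reversed logical; the per-trial phase-reversal flag.
#' @return list of class `grating_timecourse`: `time_ms`, per-frame
#'   `contrast_left` / `contrast_right`, on/off `flicker_left` /
#'   `flicker_right`, plus the change frame index.
#' @export
render_grating_timecourse <- function(trial, config, phase_reversed = FALSE) {
  fp <- trial$foreperiod
  frame_ms <- config$frame_ms
  stopifnot(abs(fp %% frame_ms) < 1e-9,
            abs(config$evidence_duration %% frame_ms) < 1e-9)
  delta <- config$contrast_delta
  base <- config$baseline_contrast
  if (base + delta >= 1 || base - delta <= 0) {
    stop("contrast step leaves (0, 1): baseline ", base, ", delta ", delta)
  }
  nf <- n_trial_frames(fp, config)
  change_frame <- as.integer(fp * config$refresh_rate / 1000) + 1L
  time_ms <- (seq_len(nf) - 1L) * frame_ms
  pre <- time_ms < fp
  sign_left <- if (trial$target == "left") 1 else -1
  contrast_left <- ifelse(pre, base, base + sign_left * delta)
  contrast_right <- ifelse(pre, base, base - sign_left * delta)
  flicker_state <- function(freq) {
    # on/off luminance modulation: duty cycle 1/2 of the tag period
    phase <- (time_ms %% (1000 / freq)) / (1000 / freq)
    as.integer(phase < 0.5)
  }
  structure(
    list(time_ms = time_ms,
         contrast_left = contrast_left,
         contrast_right = contrast_right,
         flicker_left = flicker_state(config$flicker_freqs[["left"]]),
         flicker_right = flicker_state(config$flicker_freqs[["right"]]),
         change_frame = change_frame,
         phase_reversed = phase_reversed,
         target = trial$target,
         foreperiod = fp),
    class = "grating_timecourse")
}

#' Signed contrast-difference evidence trace
#'
#' Target-minus-nontarget contrast per frame, the physical evidence a
#' contrast-discriminating accumulator integrates. Zero during the
#' foreperiod, `2 * contrast_delta` afterwards, signed so that positive
#' favours the target side given in the timecourse.
#'
#' @param gtc a [render_grating_timecourse()] result.
#' @return numeric vector, one value per frame.
#' @export
contrast_evidence <- function(gtc) {
  d <- gtc$contrast_left - gtc$contrast_right
  if (gtc$target == "right") -d else d
}
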