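#' Random dot kinematogram frames
#'
#' Per-frame dot coordinates for one trial. During the foreperiod every dot
#' is repositioned uniformly at random within the circular aperture on each
#' frame (0% coherence). From the coherent-motion onset, each dot is
#' independently a "signal" dot with probability `coherence` on each frame:
#' signal dots are displaced by `dot_speed / refresh_rate` deg in the signal
#' direction (wrapping to the opposite side of the aperture on exit), the
#' remainder are repositioned uniformly at random.
#'
#' @param trial one row of a [make_trial_schedule()] tibble (`foreperiod`,
#'   `target`).
#' @param config a [task_config()].
#' @param seed integer seed; frames are reproducible from it.
#' @return list of class `rdk_frames`: `x`, `y` (`n_dots` x `n_frames`
#'   matrices, deg, origin at the aperture centre), `onset_frame` (first
#'   coherent frame), `direction`, `signal` (logical matrix marking the
#'   coherently displaced dots), and the generating config fields.
#' @export
generate_rdk_frames <- function(trial, config, seed) {
  stopifnot(config$coherence >= 0, config$coherence <= 1)
  local_rng(seed)
  nf <- n_trial_frames(trial$foreperiod, config)
  nd <- config$n_dots
  R <- config$aperture_radius
  onset_frame <- as.integer(trial$foreperiod * config$refresh_rate / 1000) + 1L
  step <- config$dot_speed / config$refresh_rate * # deg per frame
    if (trial$target == "right") 1 else -1

  runif_disc <- function(n) {
    r <- R * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  }

  x <- matrix(0, nd, nf)
  y <- matrix(0, nd, nf)
  signal <- matrix(FALSE, nd, nf)
  p0 <- runif_disc(nd)
  x[, 1] <- p0[, 1]; y[, 1] <- p0[, 2]
  for (f in seq_len(nf)[-1]) {
    coherent <- f >= onset_frame
    is_sig <- coherent & (stats::runif(nd) < config$coherence)
    n_noise <- sum(!is_sig)
    if (n_noise > 0) {
      pn <- runif_disc(n_noise)
      x[!is_sig, f] <- pn[, 1]; y[!is_sig, f] <- pn[, 2]
    }
    if (any(is_sig)) {
      xs <- x[is_sig, f - 1] + step
      ys <- y[is_sig, f - 1]
      # wrap dots leaving the aperture to the opposite side, same height
      xmax <- sqrt(pmax(R^2 - ys^2, 0))
      xs <- ifelse(xs > xmax, xs - 2 * xmax, ifelse(xs < -xmax, xs + 2 * xmax, xs))
      x[is_sig, f] <- xs; y[is_sig, f] <- ys
    }
    signal[, f] <- is_sig
  }
  structure(
    list(x = x, y = y, signal = signal, onset_frame = onset_frame,
         direction = trial$target, n_frames = nf,
         aperture_radius = R, refresh_rate = config$refresh_rate,
         dot_diameter_px = config$dot_diameter, coherence = config$coherence,
         dot_speed = config$dot_speed),
    class = "rdk_frames")
}

#' Mirror a kinematogram left-right
#'
#' Negates all horizontal dot coordinates and flips the nominal signal
#' direction, mapping a rightward-signal stimulus onto its leftward mirror
#' image. Used for opponent-symmetry checks of the motion-energy filter.
#'
#' @param frames an [generate_rdk_frames()] result.
#' @return the mirrored `rdk_frames`.
#' @export
mirror_rdk <- function(frames) {
  frames$x <- -frames$x
  frames$direction <- if (frames$direction == "right") "left" else "right"
  frames
}
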