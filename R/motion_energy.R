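#' Opponent motion-energy filter parameters
#'
#' Constants of the classical opponent-energy construction: a quadrature
#' pair of fourth-order Cauchy functions in the motion axis, a Gaussian
#' envelope in the orthogonal axis, and two causal temporal impulse
#' responses of the damped-polynomial family
#' \eqn{h_n(t) = (kt)^n e^{-kt} [1/n! - (kt)^2/(n+2)!]} with orders 3
#' (fast) and 5 (slow). These constants are conventions of the standard
#' reference implementation of the filter, not task constants; they are
#' exposed here so every analysis states them explicitly.
#'
#' @param sigma_c spatial scale of the Cauchy pair, deg.
#' @param sigma_g Gaussian envelope SD orthogonal to motion, deg.
#' @param k temporal rate constant, 1/s.
#' @param n_fast,n_slow orders of the two temporal impulse responses.
#' @param t_support temporal filter support, s.
#' @param x_support half-width of the spatial filter grid, deg.
#' @param resolution rasterisation grid step, deg/pixel. Energy values are
#'   unit-bearing only relative to this choice.
#' @return list of class `me_filter_params`.
#' @export
me_filter_params <- function(sigma_c = 0.35, sigma_g = 0.05, k = 60,
                             n_fast = 3, n_slow = 5,
                             t_support = 0.3, x_support = 0.7,
                             resolution = 0.05) {
  structure(as.list(environment()), class = "me_filter_params")
}

# Spatial quadrature pair: fourth-order Cauchy functions.
cauchy_pair <- function(x, sigma_c, order = 4) {
  a <- atan2(x, sigma_c)
  list(even = cos(a)^order * cos(order * a),
       odd  = cos(a)^order * sin(order * a))
}

# Damped-polynomial temporal impulse response, t in seconds.
temporal_impulse <- function(t, k, n) {
  (k * t)^n * exp(-k * t) * (1 / factorial(n) - (k * t)^2 / factorial(n + 2))
}

#' Rasterise kinematogram frames to a luminance volume
#'
#' Places each dot as a unit impulse on a square pixel grid covering the
#' aperture (dots are far smaller than the spatial filter scale, so the
#' point approximation is immaterial to the energy output).
#'
#' @param frames an [generate_rdk_frames()] result.
#' @param resolution grid step, deg/pixel.
#' @return numeric array `x` \eqn{\times} `y` \eqn{\times} frame.
#' @export
rasterise_rdk <- function(frames, resolution = 0.05) {
  R <- frames$aperture_radius
  n_px <- as.integer(ceiling(2 * R / resolution)) + 1L
  vol <- array(0, c(n_px, n_px, frames$n_frames))
  ix <- pmin(pmax(round((frames$x + R) / resolution) + 1, 1), n_px)
  iy <- pmin(pmax(round((frames$y + R) / resolution) + 1, 1), n_px)
  nd <- nrow(frames$x)
  for (f in seq_len(frames$n_frames)) {
    idx <- cbind(ix[, f], iy[, f], f)
    # accumulate (dots may share a pixel)
    for (d in seq_len(nd)) vol[idx[d, 1], idx[d, 2], f] <-
        vol[idx[d, 1], idx[d, 2], f] + 1
  }
  vol
}

# Zero-padded convolution of a 3D array along one axis, for one or several
# kernels of common length at once (a banded-matrix multiply, so the BLAS
# does the work). mode "same" keeps centred alignment (spatial axes, odd
# kernels); "causal" aligns the kernels' first tap with the current sample
# (temporal axis, zero-padded history). Returns a list, one array per
# kernel.
conv_axis <- function(arr, kernels, axis, mode = c("same", "causal")) {
  mode <- match.arg(mode)
  if (!is.list(kernels)) kernels <- list(kernels)
  d <- dim(arr)
  n <- d[axis]
  m <- length(kernels[[1]])
  stopifnot(all(vapply(kernels, length, integer(1)) == m))
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  dim(a) <- c(n, prod(d[perm[-1]]))
  pad_top <- if (mode == "causal") m - 1L else (m - 1L) %/% 2L
  a <- rbind(matrix(0, pad_top, ncol(a)), a,
             matrix(0, m - 1L - pad_top, ncol(a)))
  nk <- length(kernels)
  K <- matrix(0, nk * n, nrow(a))
  rows <- seq_len(n)
  for (k in seq_len(nk)) {
    kern <- kernels[[k]]
    for (j in seq_len(m)) {
      K[cbind((k - 1L) * n + rows, rows + m - j)] <- kern[j]
    }
  }
  out_all <- K %*% a
  lapply(seq_len(nk), function(k) {
    out <- out_all[(k - 1L) * n + rows, , drop = FALSE]
    dim(out) <- d[perm]
    aperm(out, order(perm))
  })
}

#' Opponent (rightward minus leftward) motion energy
#'
#' Classical opponent-energy computation: the luminance volume is filtered
#' with four separable space-time filters (even/odd spatial phase crossed
#' with fast/slow temporal response), the quadrature pairs are combined
#' into leftward- and rightward-oriented energies, squared and summed over
#' space, and the opponent difference is returned per frame with positive
#' values meaning rightward energy.
#'
#' Temporal filtering is causal with a zero-padded history, so the trace
#' covers every stimulus frame; the first `transient_frames` values are
#' start-up transients and are flagged as such.
#'
#' @param frames an [generate_rdk_frames()] result.
#' @param filter_params an [me_filter_params()].
#' @return list of class `motion_energy_trace`: `time_ms` (frame times),
#'   `energy` (a.u., signed), `transient_frames`.
#' @export
compute_motion_energy <- function(frames, filter_params = me_filter_params()) {
  p <- filter_params
  vol <- rasterise_rdk(frames, p$resolution)
  fs <- frames$refresh_rate
  nt_k <- as.integer(round(p$t_support * fs))
  if (dim(vol)[3] < nt_k) {
    stop("stimulus (", dim(vol)[3], " frames) is shorter than the temporal ",
         "filter support (", nt_k, " frames)")
  }
  xg <- seq(-p$x_support, p$x_support, by = p$resolution)
  sp <- cauchy_pair(xg, p$sigma_c)
  yg <- seq(-4 * p$sigma_g, 4 * p$sigma_g, by = p$resolution)
  gy <- exp(-yg^2 / (2 * p$sigma_g^2))
  tg <- (seq_len(nt_k) - 1L) / fs
  h_fast <- temporal_impulse(tg, p$k, p$n_fast)
  h_slow <- temporal_impulse(tg, p$k, p$n_slow)

  smooth_y <- conv_axis(vol, gy, 2L, "same")[[1]]
  sxy <- conv_axis(smooth_y, list(sp$even, sp$odd), 1L, "same")
  te <- conv_axis(sxy[[1]], list(h_fast, h_slow), 3L, "causal")
  to <- conv_axis(sxy[[2]], list(h_fast, h_slow), 3L, "causal")
  e_fast <- te[[1]]; e_slow <- te[[2]]
  o_fast <- to[[1]]; o_slow <- to[[2]]

  # space-time oriented quadrature pairs (sign fixed so that a rightward-
  # drifting pattern yields positive opponent energy)
  r1 <- -o_fast + e_slow; r2 <- o_slow + e_fast
  l1 <- o_fast + e_slow; l2 <- -o_slow + e_fast
  opp <- r1^2 + r2^2 - l1^2 - l2^2
  energy <- apply(opp, 3, sum)
  structure(
    list(time_ms = (seq_len(length(energy)) - 1L) * 1000 / fs,
         energy = energy,
         transient_frames = nt_k - 1L),
    class = "motion_energy_trace")
}

#' Cumulative motion-energy integral
#'
#' Running sum of momentary motion energy over the pre-evidence integration
#' window: from 100 ms after stimulus onset to the response for premature
#' responses, or to 1600 ms (the long-foreperiod evidence onset) otherwise.
#' In the choice frame, momentary values favouring the chosen response are
#' positive. The slope is the ordinary least-squares line fit to the
#' cumulative sum over the window.
#'
#' @param trace a [compute_motion_energy()] result (time relative to
#'   stimulus onset, positive = rightward).
#' @param trial trial record with `foreperiod`, `rt` (ms relative to the
#'   sensory change; may be negative) and `choice`.
#' @param frame `"stimulus"` (positive = rightward) or `"choice"`
#'   (positive = chosen direction).
#' @param window_start,window_end integration bounds, ms.
#' @return list of class `motion_integral`: `time_ms`, `cumulative`,
#'   `terminal`, `slope` (a.u./ms), `frame`.
#' @export
cumulative_motion_integral <- function(trace, trial,
                                       frame = c("stimulus", "choice"),
                                       window_start = 100,
                                       window_end = 1600) {
  frame <- match.arg(frame)
  resp_time <- if (!is.null(trial$choice) && !is.na(trial$choice) &&
                   trial$choice != "none" && is.finite(trial$rt)) {
    trial$foreperiod + trial$rt
  } else Inf
  if (frame == "choice" && (is.na(trial$choice) || trial$choice == "none")) {
    stop("choice-frame integral needs a trial with a recorded choice")
  }
  w_end <- min(window_end, resp_time)
  if (w_end <= window_start) {
    stop("empty integration window: response at ", resp_time,
         " ms precedes window start ", window_start, " ms")
  }
  keep <- trace$time_ms >= window_start & trace$time_ms <= w_end
  e <- trace$energy[keep]
  if (frame == "choice" && trial$choice == "left") e <- -e
  tt <- trace$time_ms[keep]
  cum <- cumsum(e)
  structure(
    list(time_ms = tt, cumulative = cum, terminal = cum[length(cum)],
         slope = ols_slope(tt, cum), frame = frame),
    class = "motion_integral")
}

# closed-form OLS slope
ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' Median split of trials by integral slope magnitude
#'
#' Splits trials into equally sized shallow and steep bins according to the
#' absolute slope of their pre-evidence motion integral, tie-broken by trial
#' order; bin sizes differ by at most one (the steep bin is the smaller one
#' for odd n).
#'
#' @param integrals list of [cumulative_motion_integral()] results (or any
#'   objects with a `slope` field), in trial order.
#' @return list with integer index vectors `shallow` and `steep`.
#' @export
split_by_integral_slope <- function(integrals) {
  n <- length(integrals)
  if (n < 2) stop("need at least 2 trials to split")
  s <- abs(vapply(integrals, function(i) i$slope, numeric(1)))
  ord <- order(s, seq_len(n))
  n_shallow <- ceiling(n / 2)
  list(shallow = sort(ord[seq_len(n_shallow)]),
       steep = sort(ord[(n_shallow + 1):n]))
}
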