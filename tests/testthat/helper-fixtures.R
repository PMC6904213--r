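# Shared fixtures and independent oracles for the test suite.

fixture_config <- function(task = "gratings", ...) task_config(task, ...)

one_trial <- function(foreperiod = 800, target = "right", prev = NA_real_,
                      index = 1L) {
  tibble::tibble(index = index, foreperiod = foreperiod,
                 prev_foreperiod = prev, target = target)
}

# Brute-force opponent motion energy: direct triple-loop separable
# convolution, independent of the package's banded-matrix path.
brute_force_motion_energy <- function(frames, p) {
  vol <- rasterise_rdk(frames, p$resolution)
  fs <- frames$refresh_rate
  nt_k <- as.integer(round(p$t_support * fs))
  xg <- seq(-p$x_support, p$x_support, by = p$resolution)
  a <- atan2(xg, p$sigma_c)
  f_even <- cos(a)^4 * cos(4 * a)
  f_odd <- cos(a)^4 * sin(4 * a)
  yg <- seq(-4 * p$sigma_g, 4 * p$sigma_g, by = p$resolution)
  gy <- exp(-yg^2 / (2 * p$sigma_g^2))
  tg <- (seq_len(nt_k) - 1) / fs
  ht <- function(n) (p$k * tg)^n * exp(-p$k * tg) *
    (1 / factorial(n) - (p$k * tg)^2 / factorial(n + 2))
  h_fast <- ht(p$n_fast); h_slow <- ht(p$n_slow)

  conv1_same <- function(v, k) {
    n <- length(v); m <- length(k); o <- (m - 1) %/% 2
    out <- numeric(n)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(m)) {
        ii <- i + o - (j - 1)
        if (ii >= 1 && ii <= n) s <- s + k[j] * v[ii]
      }
      out[i] <- s
    }
    out
  }
  conv1_causal <- function(v, k) {
    n <- length(v); m <- length(k)
    out <- numeric(n)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(m)) {
        ii <- i - (j - 1)
        if (ii >= 1) s <- s + k[j] * v[ii]
      }
      out[i] <- s
    }
    out
  }
  d <- dim(vol)
  sm <- vol
  for (ix in seq_len(d[1])) for (it in seq_len(d[3]))
    sm[ix, , it] <- conv1_same(vol[ix, , it], gy)
  ex <- sm; ox <- sm
  for (iy in seq_len(d[2])) for (it in seq_len(d[3])) {
    ex[, iy, it] <- conv1_same(sm[, iy, it], f_even)
    ox[, iy, it] <- conv1_same(sm[, iy, it], f_odd)
  }
  ef <- ex; es <- ex; of <- ox; os <- ox
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) {
    ef[ix, iy, ] <- conv1_causal(ex[ix, iy, ], h_fast)
    es[ix, iy, ] <- conv1_causal(ex[ix, iy, ], h_slow)
    of[ix, iy, ] <- conv1_causal(ox[ix, iy, ], h_fast)
    os[ix, iy, ] <- conv1_causal(ox[ix, iy, ], h_slow)
  }
  r1 <- -of + es; r2 <- os + ef
  l1 <- of + es; l2 <- -os + ef
  apply(r1^2 + r2^2 - l1^2 - l2^2, 3, sum)
}

# A tiny, fully deterministic dot stimulus: dots marching rightward at
# fixed speed (coherence 1 semantics) inside a small aperture.
toy_drifting_frames <- function(n_frames = 32, n_dots = 8, radius = 1.2,
                                speed = 5, fs = 100, direction = "right") {
  step <- speed / fs * if (direction == "right") 1 else -1
  set.seed(99)
  x0 <- stats::runif(n_dots, -radius / 2, radius / 2)
  y0 <- stats::runif(n_dots, -radius / 2, radius / 2)
  x <- matrix(0, n_dots, n_frames); y <- matrix(0, n_dots, n_frames)
  for (f in seq_len(n_frames)) {
    xs <- x0 + (f - 1) * step
    xmax <- sqrt(pmax(radius^2 - y0^2, 0))
    xs <- ((xs + xmax) %% (2 * xmax)) - xmax
    x[, f] <- xs; y[, f] <- y0
  }
  structure(
    list(x = x, y = y, signal = matrix(TRUE, n_dots, n_frames),
         onset_frame = 1L, direction = direction, n_frames = n_frames,
         aperture_radius = radius, refresh_rate = fs,
         dot_diameter_px = 4, coherence = 1, dot_speed = speed),
    class = "rdk_frames")
}

# Minimal hand-built epoch_set for artifact-rule tests.
make_epoch_set <- function(data, eog, fs = 512, foreperiod = 800,
                           channels = biosemi128_layout()$channel) {
  n <- length(data)
  times <- lapply(data, function(m) (seq_len(ncol(m)) - 1) / fs * 1000)
  structure(
    list(data = data, eog = eog, time = times, alignment = "stimulus",
         fs = fs, channels = channels, trial_index = seq_len(n),
         foreperiod = rep(foreperiod, n), retained = rep(TRUE, n),
         drop_cause = rep(NA_character_, n), interpolated = character(0)),
    class = "epoch_set")
}

default_gen_params <- function(...) generative_params(...)

# single-trial epoch set holding a sinusoid (plus optional noise) on every
# channel; used by the spectral and acceptance checks
make_sine_epochs <- function(freq = 20, amp = 2, n_ch = 4, dur_ms = 1200,
                             fs = 512, noise_sd = 0, seed = 1) {
  set.seed(seed)
  n <- round(dur_ms * fs / 1000)
  tt <- (seq_len(n) - 1) / fs
  data <- list(matrix(amp * sin(2 * pi * freq * tt), n_ch, n, byrow = TRUE) +
                 matrix(rnorm(n_ch * n, 0, noise_sd), n_ch, n))
  structure(
    list(data = data, eog = list(numeric(n)),
         time = list((seq_len(n) - 1) / fs * 1000),
         alignment = "stimulus", fs = fs,
         channels = paste0("ch", seq_len(n_ch)), trial_index = 1L,
         foreperiod = 800, retained = TRUE, drop_cause = NA_character_,
         interpolated = character(0)),
    class = "epoch_set")
}
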