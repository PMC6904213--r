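test_that("opponent energy matches a brute-force convolution oracle", {
  p <- me_filter_params(resolution = 0.1, x_support = 0.5, t_support = 0.2)
  fr <- toy_drifting_frames(n_frames = 32)
  oracle <- brute_force_motion_energy(fr, p)
  trace <- compute_motion_energy(fr, p)
  expect_equal(trace$energy, oracle, tolerance = 1e-10)
  # rightward drift at the preferred speed carries positive opponent energy
  expect_gt(mean(trace$energy[-seq_len(trace$transient_frames)]), 0)
})

test_that("mirroring the stimulus negates the energy trace", {
  cfg <- fixture_config("rdk", coherence = 0.25)
  fr <- generate_rdk_frames(one_trial(800, "right"), cfg, seed = 5)
  p <- me_filter_params(resolution = 0.1)
  e <- compute_motion_energy(fr, p)$energy
  em <- compute_motion_energy(mirror_rdk(fr), p)$energy
  expect_lt(max(abs(e + em)) / max(abs(e)), 1e-6)
})

test_that("zero coherence averages to zero and energy grows with coherence", {
  p <- me_filter_params(resolution = 0.1)
  tr <- one_trial(1600, "right")
  means <- vapply(c(0, 0.05, 0.25, 1), function(coh) {
    cfg <- fixture_config("rdk",
                          coherence = if (coh == 0) 1e-9 else coh)
    cfg$coherence <- coh
    fr <- generate_rdk_frames(tr, cfg, seed = 21)
    trace <- compute_motion_energy(fr, p)
    post <- trace$time_ms >= 1600 + 300
    mean(trace$energy[post])
  }, numeric(1))
  scale <- means[4]
  expect_lt(abs(means[1]) / scale, 0.05)
  expect_true(all(diff(means) > 0))
})

test_that("stimuli shorter than the temporal filter support are refused", {
  fr <- toy_drifting_frames(n_frames = 10)
  expect_error(compute_motion_energy(fr, me_filter_params(resolution = 0.1)),
               "shorter than the temporal")
})

test_that("cumulative integral handles windows, signs and slopes", {
  trace <- structure(list(time_ms = seq(0, 1600, by = 10),
                          energy = rep(2, 161), transient_frames = 0L),
                     class = "motion_energy_trace")
  tr <- one_trial(1600, "right"); tr$choice <- "right"; tr$rt <- 300
  # constant trace k: terminal = k * number of in-window samples
  mi <- cumulative_motion_integral(trace, tr)
  n_samp <- sum(trace$time_ms >= 100 & trace$time_ms <= 1600)
  expect_equal(mi$terminal, 2 * n_samp)
  # cumulative value at t equals the running sum
  expect_equal(mi$cumulative, cumsum(rep(2, n_samp)))

  # premature response at 900 ms absolute: window 100-900 ms
  trp <- one_trial(1600, "right"); trp$choice <- "right"; trp$rt <- -700
  mip <- cumulative_motion_integral(trace, trp)
  expect_equal(range(mip$time_ms), c(100, 900))

  # leftward energy with a left choice is positive in the choice frame
  trace_l <- trace; trace_l$energy <- rep(-2, 161)
  trl <- one_trial(1600, "left"); trl$choice <- "left"; trl$rt <- 300
  mil <- cumulative_motion_integral(trace_l, trl, frame = "choice")
  expect_gt(mil$terminal, 0)

  # response before the window start is an error
  tre <- one_trial(1600, "right"); tre$choice <- "right"; tre$rt <- -1550
  expect_error(cumulative_motion_integral(trace, tre), "empty integration")

  # slope of a linear cumulative sum matches the analytic rate
  expect_equal(mi$slope, 2 / 10, tolerance = 1e-10)
})

test_that("median split by |slope| is balanced with index tie-breaks", {
  mk <- function(slopes) lapply(slopes, function(s) list(slope = s))
  sp <- split_by_integral_slope(mk(c(5, 1, 4, 2, 9, 3, 8, 7, 6, 10)))
  expect_equal(length(sp$shallow), 5)
  expect_equal(length(sp$steep), 5)
  expect_setequal(c(sp$shallow, sp$steep), 1:10)
  expect_true(all(c(2, 4, 6) %in% sp$shallow))

  tied <- split_by_integral_slope(mk(rep(1, 10)))
  expect_identical(tied$shallow, 1:5)
  expect_identical(tied$steep, 6:10)

  odd <- split_by_integral_slope(mk(1:9))
  expect_equal(sort(c(length(odd$shallow), length(odd$steep))), c(4, 5))
  expect_error(split_by_integral_slope(mk(1)), "at least 2")
})
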