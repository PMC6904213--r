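test_that("noise-free accumulator reaches the bound at the closed-form time", {
  cfg <- fixture_config()
  p <- default_gen_params(noise_sd = 0, onset_jitter_sd = 0,
                          onset_base = 800, motor_delay = 100,
                          bound_collapse = 0, onset_lapse_rate = 0)
  tr <- one_trial(800, "right")
  e <- 0.11
  ev <- list(time_ms = c(0, 800), value = c(0, e))
  sim <- simulate_trial_accumulator(tr, ev, p, cfg, seed = 1)
  rt_expected <- p$bound / (p$drift_gain * e) + p$motor_delay
  expect_identical(sim$choice, "right")
  expect_equal(sim$rt, rt_expected, tolerance = 1000 / p$fs / rt_expected)

  # no evidence, no noise: never crosses -> miss
  ev0 <- list(time_ms = c(0, 800), value = c(0, 0))
  sim0 <- simulate_trial_accumulator(tr, ev0, p, cfg, seed = 1)
  expect_identical(sim0$choice, "none")
  expect_true(is.na(sim0$rt))

  # leftward evidence drives a left choice
  evl <- list(time_ms = c(0, 800), value = c(0, -e))
  expect_identical(simulate_trial_accumulator(tr, evl, p, cfg, 1)$choice,
                   "left")
})

test_that("an onset beyond the trial end degenerates to a guaranteed miss", {
  cfg <- fixture_config()
  p <- default_gen_params(onset_base = 1e6, onset_jitter_sd = 0)
  ds <- generate_dataset(cfg, p, n_trials = 30, seed = 2, eeg = FALSE)
  expect_true(all(ds$trials$degenerate))
  expect_true(all(ds$trials$outcome == "miss"))
  expect_true(all(summarize_behaviour(ds$trials, cfg)$
                    by_foreperiod$premature_rate == 0))
})

test_that("datasets are byte-identical under a repeated seed", {
  cfg <- fixture_config()
  d1 <- generate_dataset(cfg, default_gen_params(), 30, seed = 77, eeg = FALSE)
  d2 <- generate_dataset(cfg, default_gen_params(), 30, seed = 77, eeg = FALSE)
  expect_identical(d1$trials, d2$trials)
  d3 <- generate_dataset(cfg, default_gen_params(), 30, seed = 78, eeg = FALSE)
  expect_false(identical(d1$trials$rt, d3$trials$rt))
})

test_that("behaviour fields are derivable from the hidden truth columns", {
  cfg <- fixture_config()
  p <- default_gen_params()
  ds <- generate_dataset(cfg, p, n_trials = 90, seed = 3, eeg = FALSE)
  tr <- ds$trials
  got <- !is.na(tr$crossing_ms)
  expect_equal(tr$rt[got], tr$crossing_ms[got] + p$motor_delay -
                 tr$foreperiod[got])
  expect_true(all(is.na(tr$rt[!got])))
})

test_that("the EEG forward model is linear in its component gains", {
  cfg <- fixture_config()
  tr <- one_trial(800, "left")
  stim <- render_grating_timecourse(tr, cfg)
  ev <- list(time_ms = stim$time_ms,
             value = stim$contrast_right - stim$contrast_left)
  p1 <- default_gen_params(blink_rate = 0, pop_rate = 0)
  sim <- simulate_trial_accumulator(tr, ev, p1, cfg, seed = 5)
  p2 <- default_gen_params(blink_rate = 0, pop_rate = 0,
                           ssvep_gain = 2 * p1$ssvep_gain)
  p0 <- default_gen_params(blink_rate = 0, pop_rate = 0, ssvep_gain = 0)
  e1 <- synthesize_eeg_trial(sim, tr, stim, p1, cfg, seed = 9)
  e2 <- synthesize_eeg_trial(sim, tr, stim, p2, cfg, seed = 9)
  e0 <- synthesize_eeg_trial(sim, tr, stim, p0, cfg, seed = 9)
  # doubling the tag gain adds exactly one more unit-gain tag component
  expect_equal(e2$eeg - e1$eeg, e1$eeg - e0$eeg, tolerance = 1e-9)

  # with cpp_gain = 0 the Pz-cluster signal sits at the noise floor
  pz <- site_candidates()$Pz
  layout <- biosemi128_layout()
  pc0 <- default_gen_params(blink_rate = 0, pop_rate = 0, cpp_gain = 0)
  ec <- synthesize_eeg_trial(sim, tr, stim, pc0, cfg, seed = 9)
  idx <- match(pz, layout$channel)
  win <- ec$time_ms >= 1000 & ec$time_ms <= 1800  # post-change build-up
  # the accumulating component is recovered exactly by differencing, and
  # without it the cluster mean sits at the sensor-noise floor
  cpp_component <- mean(e1$eeg[idx, win] - ec$eeg[idx, win])
  expect_gt(cpp_component, 1)
  expect_lt(abs(mean(ec$eeg[idx, win])), cpp_component)
})

test_that("premature responses vanish as the onset is pushed late", {
  cfg <- fixture_config()
  early <- generate_dataset(cfg, default_gen_params(onset_base = 600),
                            90, seed = 8, eeg = FALSE)
  late <- generate_dataset(cfg, default_gen_params(onset_base = 1650),
                           90, seed = 8, eeg = FALSE)
  pr <- function(d) mean(d$trials$outcome == "premature")
  expect_gt(pr(early), pr(late))
})
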