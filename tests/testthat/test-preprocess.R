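test_that("filtering removes DC, attenuates 50 Hz and average-references", {
  fs <- 512
  n <- fs * 4
  tt <- seq_len(n) / fs
  set.seed(3)
  eeg <- matrix(rnorm(8 * n), 8, n) + 25          # DC offset
  eeg[1, ] <- eeg[1, ] + 10 * sin(2 * pi * 50 * tt)
  out <- filter_and_reference(eeg, fs = fs)
  expect_lt(abs(mean(out)), 0.5)
  expect_lt(max(abs(colMeans(out))), 1e-9)        # average reference
  expect_error(filter_and_reference(cbind(eeg, NaN)), "non-finite")

  # >20 dB attenuation at 50 Hz, straight from the designed coefficients
  h <- fir_lowpass_kernel(fs = fs)
  H50 <- abs(sum(h * exp(-2i * pi * 50 / fs * (seq_along(h) - 1))))
  expect_lt(20 * log10(H50), -20)
  # passband essentially untouched
  H10 <- abs(sum(h * exp(-2i * pi * 10 / fs * (seq_along(h) - 1))))
  expect_equal(H10, 1, tolerance = 0.01)
})

test_that("epoch spans, baselines and drop rules follow the design", {
  cfg <- fixture_config()
  p <- default_gen_params(sensor_noise_sd = 5, blink_rate = 0)
  ds <- generate_dataset(cfg, p, n_trials = 12, seed = 9, eeg = TRUE)
  ep <- epoch_and_baseline(ds$eeg, ds$trials, "stimulus")
  for (t in seq_along(ep$data)) {
    fp <- ep$foreperiod[t]
    expect_equal(ep$time[[t]][1], 0, tolerance = 2)
    expect_equal(max(ep$time[[t]]), fp + 2000, tolerance = 2)
    bl <- ep$time[[t]] >= 500 & ep$time[[t]] <= 550
    expect_lt(max(abs(rowMeans(ep$data[[t]][, bl]))), 1e-9)
  }
  # the 800 ms foreperiod yields a 0-2800 ms epoch
  i800 <- which(ep$foreperiod == 800)[1]
  expect_equal(range(ep$time[[i800]]), c(0, 2800), tolerance = 2)

  rp <- epoch_and_baseline(ds$eeg, ds$trials, "response")
  for (t in seq_along(rp$data)) {
    expect_equal(range(rp$time[[t]]), c(-1000, 600), tolerance = 2)
  }
  # trials without a response are dropped with a logged cause
  misses <- which(ds$trials$choice == "none")
  if (length(misses)) {
    expect_true(all(rp$drop_cause[misses] == "no_response"))
  }
  expect_equal(sum(rp$retained) + sum(!is.na(rp$drop_cause)),
               length(ds$eeg))
})

test_that("artifact thresholds, interpolation and exclusion match the rules", {
  n_tr <- 100
  n_ch <- 128
  n_s <- 200
  layout <- biosemi128_layout()
  set.seed(5)
  data <- lapply(seq_len(n_tr), function(t) matrix(rnorm(n_ch * n_s, 0, 5),
                                                   n_ch, n_s))
  eog <- lapply(seq_len(n_tr), function(t) rnorm(n_s, 0, 10))

  # channel 7 exceeds 100 uV on exactly 11 of 100 trials -> interpolated
  for (t in 1:11) data[[t]][7, 50] <- 120
  # channel 9 on exactly 10 trials -> not interpolated (boundary: > 10%)
  for (t in 1:10) data[[t]][9, 60] <- 130
  # trial 20: EOG excursion of 250 uV -> rejected with cause EOG
  eog[[20]][100] <- 250
  # trial 30: channel 50 peak 99.9 uV -> retained (boundary)
  data[[30]][50, 10] <- 99.9
  # trial 40: channel 60 at 150 uV -> rejected with cause channel
  data[[40]][60, 20] <- 150

  ep <- make_epoch_set(data, eog)
  res <- reject_and_interpolate(ep, layout)
  rep <- res$report
  expect_identical(rep$interpolated, "A7")
  expect_false("A9" %in% rep$interpolated)
  expect_identical(rep$cause[20], "EOG")
  expect_identical(rep$cause[40], "channel")
  expect_false(rep$trial_rejected[30])
  # channel-9 trials are still rejected (not interpolated away)
  expect_true(all(rep$trial_rejected[1:10]))
  expect_equal(rep$n_input, rep$n_rejected + length(res$epochs$data))
  expect_equal(unname(rep$channel_counts["A7"]), 11)
  expect_false(rep$excluded)

  # idempotence: a second pass over the cleaned data changes nothing
  res2 <- reject_and_interpolate(res$epochs, layout)
  expect_equal(res2$report$n_rejected, 0)
  expect_identical(res2$epochs$data, res$epochs$data)
})

test_that("interpolation is capped at 10% of channels with a warning", {
  n_tr <- 20; n_ch <- 128; n_s <- 50
  set.seed(6)
  data <- lapply(seq_len(n_tr), function(t) matrix(rnorm(n_ch * n_s, 0, 5),
                                                   n_ch, n_s))
  bad <- 1:20                       # 20 channels qualify; cap is 12
  for (t in seq_len(n_tr)) data[[t]][bad, 1] <- 150
  ep <- make_epoch_set(data, lapply(seq_len(n_tr), function(t) rnorm(n_s)))
  expect_warning(res <- reject_and_interpolate(ep), "capping")
  expect_equal(length(res$report$interpolated), floor(0.1 * n_ch))
  expect_true(res$report$interpolation_capped)
  # losing every trial flags the subject for exclusion
  expect_true(res$report$excluded || res$report$loss_fraction <= 0.4)
})

test_that("injected blinks are caught by the EOG rule with high recall", {
  cfg <- fixture_config()
  p <- default_gen_params(blink_rate = 1.2, pop_rate = 0)
  ds <- generate_dataset(cfg, p, n_trials = 51, seed = 14, eeg = TRUE)
  ep <- epoch_and_baseline(ds$eeg, ds$trials, "stimulus")
  res <- reject_and_interpolate(ep)
  blink_trials <- which(ds$trials$n_blinks > 0)
  flagged <- which(res$report$trial_rejected & res$report$cause == "EOG")
  recall <- mean(blink_trials %in% flagged)
  expect_gte(recall, 0.95)
})
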