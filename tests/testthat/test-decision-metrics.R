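test_that("electrode selection picks maxima with the right polarity", {
  layout <- biosemi128_layout()
  topo <- stats::setNames(rep(0, 128), layout$channel)
  cand <- site_candidates(layout)$Pz
  hot <- cand[1:4]
  topo[hot] <- 10
  expect_setequal(select_electrode_cluster(topo, cand, 4), hot)
  expect_error(select_electrode_cluster(topo, cand, length(cand) + 1),
               "exceeds")

  # N2-style selection: most negative
  topo2 <- stats::setNames(rep(0, 128), layout$channel)
  cold <- cand[2:4]
  topo2[cold] <- -5
  expect_setequal(
    select_electrode_cluster(topo2, cand, 3, polarity = "negative"), cold)

  # deterministic tie-break by label order
  topo3 <- stats::setNames(rep(1, 128), layout$channel)
  expect_identical(select_electrode_cluster(topo3, cand, 4),
                   sort(cand)[1:4])
})

test_that("windowed amplitude and slope measures are exact on known inputs", {
  tt <- seq(-400, 400, by = 2)
  lin <- 1.5 + 0.03 * tt
  expect_equal(measure_window(lin, tt, c(-250, 50), "slope"), 0.03)
  expect_equal(measure_window(lin, tt, c(-100, 300), "slope"), 0.03)
  cst <- rep(4.2, length(tt))
  expect_equal(measure_window(cst, tt, c(-50, 50), "amplitude"), 4.2)
  expect_equal(measure_window(cst, tt, c(-50, 50), "slope"), 0)
  expect_error(measure_window(lin, tt, c(-500, 50), "slope", trial = 12),
               "trial 12")

  # OLS slope equals the normal-equations solution on noisy data
  set.seed(4)
  y <- rnorm(length(tt))
  keep <- tt >= -250 & tt <= 50
  X <- cbind(1, tt[keep])
  beta <- solve(t(X) %*% X, t(X) %*% y[keep])
  expect_equal(measure_window(y, tt, c(-250, 50), "slope"), beta[2],
               tolerance = 1e-12)
})

test_that("3 SD outlier flags are single-pass and handle zero variance", {
  set.seed(9)
  v <- rnorm(99)
  v <- (v - mean(v)) / stats::sd(v)
  vals <- c(v, 10)
  flags <- reject_outlier_trials(vals)
  expect_identical(which(flags), 100L)
  expect_identical(reject_outlier_trials(rep(3, 10)), rep(FALSE, 10))
  expect_error(reject_outlier_trials(c(1, 2)), "at least 3")
  # flags are not recomputed after removal: borderline survivors stay
  vals2 <- c(rnorm(50), 4, 20)
  f2 <- reject_outlier_trials(vals2)
  f_recursive <- reject_outlier_trials(vals2[!f2])
  expect_true(sum(f2) <= 2)   # single pass flagged at most the crafted pair
})

test_that("equal-count RT bins and level binnings are deterministic", {
  tr <- tibble::tibble(rt = c(stats::runif(60, 200, 1500)))
  b <- bin_trials(tr, "rt", n_bins = 6)
  expect_equal(unname(table(b)), rep(10L, 6), ignore_attr = TRUE)
  expect_true(all(tapply(tr$rt, b, max)[-6] <=
                    tapply(tr$rt, b, min)[-1] + 1e-9))

  # ties broken by trial order
  tied <- tibble::tibble(rt = rep(500, 9))
  bt <- bin_trials(tied, "rt", n_bins = 3)
  expect_identical(bt, rep(1:3, each = 3))

  expect_error(bin_trials(tibble::tibble(rt = 1:3), "rt", n_bins = 6),
               "fewer trials")
  expect_error(bin_trials(tibble::tibble(rt = 1:3), "rt", n_bins = 1),
               ">= 2")

  cfg <- fixture_config()
  s <- make_trial_schedule(30, cfg, seed = 2)
  pb <- bin_trials(s, "prev_foreperiod")
  expect_equal(sum(is.na(pb)), 1)
  expect_equal(as.numeric(table(pb)),
               as.numeric(table(s$prev_foreperiod)))

  sl <- tibble::tibble(integral_slope = c(0.1, -3, 0.5, 2, -0.2, 1))
  sb <- bin_trials(sl, "integral_slope")
  expect_equal(sum(sb == 1), 3)
  expect_equal(sum(sb == 2), 3)
  expect_true(all(abs(sl$integral_slope[sb == 2]) >=
                    max(abs(sl$integral_slope[sb == 1]))))
})

test_that("grand-average topography and cluster waveforms are consistent", {
  cfg <- fixture_config()
  p <- default_gen_params(blink_rate = 0, pop_rate = 0)
  ds <- generate_dataset(cfg, p, n_trials = 6, seed = 31, eeg = TRUE)
  ep <- epoch_and_baseline(ds$eeg, ds$trials, "stimulus", filter = FALSE)
  topo <- grand_average_topography(ep, c(600, 800))
  expect_named(topo, ep$channels)
  wf <- cluster_waveform(ep, ep$channels[5])
  keep <- ep$time[[1]] >= 600 & ep$time[[1]] <= 800
  manual <- mean(ep$data[[1]][5, keep])
  expect_equal(mean(vapply(seq_along(wf), function(t) {
    k <- ep$time[[t]] >= 600 & ep$time[[t]] <= 800
    mean(wf[[t]]$value[k])
  }, numeric(1))), unname(topo[5]), tolerance = 1e-12)
})
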