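#!/usr/bin/env Rscript
# Full EEG pipeline on a 300-trial synthetic gratings session: filtering,
# epoching, artifact handling, electrode-cluster selection, windowed CPP /
# SSVEP / Mu-Beta / N2 measurements, and accumulation-onset estimation.

library(premacc)
suppressMessages(library(dplyr))

seed <- 20260902
cfg <- task_config("gratings")
params <- generative_params()

message("Generating 300 trials with 128-channel EEG ...")
ds <- generate_dataset(cfg, params, n_trials = 300, seed = seed, eeg = TRUE)

ep <- epoch_and_baseline(ds$eeg, ds$trials, "stimulus")
res <- reject_and_interpolate(ep)
stim <- res$epochs
message("Artifact rejection: ", res$report$n_rejected, "/",
        res$report$n_input, " trials lost (",
        round(100 * res$report$loss_fraction, 1), "%), interpolated: ",
        paste(res$report$interpolated, collapse = ", "))
resp <- epoch_and_baseline(ds$eeg, ds$trials, "response")

cand <- site_candidates()
cpp_clust <- select_electrode_cluster(
  grand_average_topography(stim, c(1100, 1600)), cand$Pz, 4)
n2_p7 <- select_electrode_cluster(
  grand_average_topography(stim, c(1000, 1100)), cand$P7, 3, "negative")

ms <- measure_decision_signals(stim, resp, cpp_clust, ds$trials)
ms <- ms |>
  left_join(ds$trials |> select(index, foreperiod, prev_foreperiod, rt,
                                outcome, t_on),
            by = c(trial_index = "index"))
ms$outlier <- FALSE
ok <- !is.na(ms$pre_response_amp)
ms$outlier[ok] <- reject_outlier_trials(ms$pre_response_amp[ok])
readr::write_csv(ms, "results/cpp_measurements.csv")

summ <- ms |>
  filter(!outlier) |>
  group_by(foreperiod) |>
  summarise(pre_evidence_amp = mean(pre_evidence_amp, na.rm = TRUE),
            pre_evidence_slope = mean(pre_evidence_slope, na.rm = TRUE),
            pre_response_amp = mean(pre_response_amp, na.rm = TRUE),
            n = n(), .groups = "drop")
readr::write_csv(summ, "results/cpp_by_foreperiod.csv")

# accumulation-onset recovery on long-foreperiod trials, per
# previous-foreperiod stratum, against the generator's ground truth
rec <- onset_recovery_table(stim, ds$trials, cpp_clust)
readr::write_csv(rec, "results/onset_recovery.csv")
message("Onset recovery (by previous foreperiod):")
print(rec)

# SSVEP SNR time courses at the Oz cluster
tfr <- stft_amplitude(stim)
dsv <- d_ssvep(tfr, ds$trials, cfg, cand$Oz[1:4])
d_tab <- do.call(rbind, lapply(seq_along(dsv), function(i) {
  fp <- stim$foreperiod[i]
  data.frame(trial_index = stim$trial_index[i], foreperiod = fp,
             seg_time = dsv[[i]]$seg_times, d_ssvep = dsv[[i]]$d_ssvep,
             rel_change = dsv[[i]]$seg_times - fp)
}))
readr::write_csv(
  d_tab |> group_by(foreperiod, rel_change) |>
    summarise(d_ssvep = mean(d_ssvep), .groups = "drop"),
  "results/d_ssvep_timecourse.csv")

# Mu/Beta lateralisation relative to the response hand
hands <- ds$trials$choice[stim$trial_index]
hands[hands == "none"] <- NA
mb <- mu_beta_lateralisation(tfr, hands,
                             clusters = list(C3 = cand$C3[1:4],
                                             C4 = cand$C4[1:4]))
lat <- do.call(rbind, lapply(seq_along(mb$trials), function(i) {
  if (is.null(mb$trials[[i]])) return(NULL)
  data.frame(trial_index = stim$trial_index[i],
             foreperiod = stim$foreperiod[i],
             seg_time = mb$trials[[i]]$seg_times,
             lateralisation = mb$trials[[i]]$lateralisation)
}))
readr::write_csv(
  lat |> group_by(foreperiod, seg_time) |>
    summarise(lateralisation = mean(lateralisation), .groups = "drop"),
  "results/mu_beta_lateralisation.csv")

message("EEG measurement tables written under results/.")
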