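#!/usr/bin/env Rscript
# Simulate the two tasks from the variable-onset accumulator.
#
# Writes to results/: the gratings-task trial table with hidden truth
# columns (onset time, bound-crossing time), and a smaller dot-motion
# table whose evidence traces come from each trial's own kinematogram.
# Later scripts consume these tables; EEG is regenerated where needed
# (storing ~GB of synthetic recordings is pointless when the generator is
# seeded).

library(premacc)

seed <- 20260901
dir.create("results", showWarnings = FALSE)

cfg <- task_config("gratings")
params <- generative_params()

message("Simulating ", 5400, " gratings trials (behaviour only) ...")
ds <- generate_dataset(cfg, params, n_trials = 5400, seed = seed, eeg = FALSE)
readr::write_csv(ds$trials, "results/trials_gratings.csv")

message("Simulating 240 dot-motion trials with per-trial motion energy ...")
cfg_rdk <- task_config("rdk", foreperiods = c(800, 1200, 1600))
ds_rdk <- generate_dataset(cfg_rdk, params, n_trials = 240,
                           seed = seed + 1, eeg = FALSE,
                           me_params = me_filter_params(resolution = 0.1))
readr::write_csv(ds_rdk$trials, "results/trials_rdk.csv")
saveRDS_path <- file.path("results", "rdk_energy_traces.csv")
# store the energy traces long-form (trial, time, energy)
energy_long <- do.call(rbind, lapply(seq_along(ds_rdk$energy), function(i) {
  tr <- ds_rdk$energy[[i]]
  data.frame(trial = i, time_ms = tr$time_ms, energy = tr$energy)
}))
readr::write_csv(energy_long, saveRDS_path)

message("Done. Outcome rates by foreperiod:")
print(summarize_behaviour(ds$trials, cfg)$by_foreperiod)
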