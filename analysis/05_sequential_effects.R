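#!/usr/bin/env Rscript
# Sequential foreperiod effects: behaviour and pre-evidence CPP as a
# function of the previous trial's foreperiod.

library(premacc)
suppressMessages(library(dplyr))

cfg <- task_config("gratings")
trials <- readr::read_csv("results/trials_gratings.csv",
                          show_col_types = FALSE)

# two-way rm-ANOVA (FPn x FPn-1) over simulated subjects
trials$subject <- (trials$index - 1) %/% 600 + 1
cells <- trials |>
  filter(!is.na(prev_foreperiod)) |>
  group_by(subject, foreperiod, prev_foreperiod) |>
  summarise(rt = mean(rt[outcome %in% c("correct", "error")]),
            accuracy = 100 * mean(outcome == "correct"),
            .groups = "drop")
for (m in c("rt", "accuracy")) {
  d <- data.frame(subject = cells$subject, fp = cells$foreperiod,
                  prev = cells$prev_foreperiod, value = cells[[m]])
  res <- rm_anova(d, c("fp", "prev"))
  readr::write_csv(cbind(measure = m, res),
                   paste0("results/sequential_anova_", m, ".csv"))
}

# response-time course over previous foreperiod on long-FP trials,
# over every trial with a recorded response (premature responses carry
# real response times; excluding them would bias the sequential contrast)
seq_rt <- trials |>
  filter(foreperiod == 1600, !is.na(prev_foreperiod), !is.na(rt)) |>
  group_by(prev_foreperiod) |>
  summarise(mean_rt = mean(rt), n = n(), .groups = "drop")
readr::write_csv(seq_rt, "results/sequential_rt_long_fp.csv")

# pre-evidence CPP by previous foreperiod (from 04_eeg_pipeline.R output)
if (file.exists("results/cpp_measurements.csv")) {
  ms <- readr::read_csv("results/cpp_measurements.csv",
                        show_col_types = FALSE)
  cpp_prev <- ms |>
    filter(!outlier, !is.na(prev_foreperiod)) |>
    group_by(prev_foreperiod) |>
    summarise(pre_evidence_amp = mean(pre_evidence_amp, na.rm = TRUE),
              pre_evidence_slope = mean(pre_evidence_slope, na.rm = TRUE),
              n = n(), .groups = "drop")
  readr::write_csv(cpp_prev, "results/cpp_by_prev_foreperiod.csv")
  message("Pre-evidence CPP amplitude by previous foreperiod:")
  print(cpp_prev)
}

message("Mean RT (all responded trials) on long-foreperiod trials:")
print(seq_rt)
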