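#!/usr/bin/env Rscript
# Behavioural analyses: per-foreperiod summaries, conditional accuracy
# functions, sequential (previous x current foreperiod) grids, and the
# repeated-measures ANOVAs over simulated subjects.
#
# Reads results/trials_gratings.csv (from 01_simulate.R); writes tidy
# summary tables and ANOVA results under results/.

library(premacc)
suppressMessages(library(dplyr))

cfg <- task_config("gratings")
trials <- readr::read_csv("results/trials_gratings.csv",
                          show_col_types = FALSE)

bs <- summarize_behaviour(trials, cfg)
readr::write_csv(bs$by_foreperiod, "results/behaviour_by_foreperiod.csv")
readr::write_csv(bs$caf, "results/conditional_accuracy.csv")
readr::write_csv(bs$grid, "results/sequential_grid.csv")
readr::write_csv(bs$miss_by_prev, "results/miss_by_prev_foreperiod.csv")
readr::write_csv(bs$premature_by_prev,
                 "results/premature_by_prev_foreperiod.csv")

# Split the session into 18 simulated subjects of 300 trials each and run
# the one-way foreperiod ANOVAs the behavioural analysis prescribes.
trials$subject <- (trials$index - 1) %/% 300 + 1
subj <- trials |>
  group_by(subject, foreperiod) |>
  summarise(
    rt = mean(rt[outcome %in% c("correct", "error")]),
    accuracy = 100 * mean(outcome == "correct"),
    miss = 100 * mean(outcome == "miss"),
    premature = 100 * mean(outcome == "premature"),
    points = mean(points), .groups = "drop")

anovas <- lapply(c("rt", "accuracy", "miss", "premature", "points"),
                 function(m) {
  d <- data.frame(subject = subj$subject, cond = subj$foreperiod,
                  value = subj[[m]])
  cbind(measure = m, rm_anova(d, "cond"))
})
readr::write_csv(do.call(rbind, anovas), "results/behaviour_anovas.csv")

# pairwise foreperiod comparisons with the Bonferroni-corrected alpha
wide <- tidyr::pivot_wider(subj[, c("subject", "foreperiod", "rt")],
                           names_from = foreperiod, values_from = rt)
tests <- t_test_suite(
  list(wide$`800` - wide$`1200`, wide$`800` - wide$`1600`,
       wide$`1200` - wide$`1600`),
  labels = c("rt_800_vs_1200", "rt_800_vs_1600", "rt_1200_vs_1600"))
readr::write_csv(tests, "results/behaviour_pairwise_rt.csv")

message("Behavioural tables written; corrected alpha = ",
        unique(tests$corrected_alpha))
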