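#!/usr/bin/env Rscript

# Multi-generation comparison of resistance-management strategies:
# sequential monotherapies versus a two-insecticide mixture, with and
# without insecticide decay, across three scenarios (matched insecticides;
# mismatched initial resistance; mismatched heritabilities). Each
# comparison runs both arms from identical conditions and reports the
# strategy-lifespan difference in years (positive = mixture lasts longer).

suppressPackageStartupMessages(library(irmsim))
library(dplyr)

dir.create("results", recursive = TRUE, showWarnings = FALSE)

all <- lapply(1:3, function(sc) {
  res <- run_scenario(sc)
  write_results_csv(res, sprintf("results/scenario%d_comparisons.csv", sc),
                    meta = list(scenario = sc,
                                units = "lifespans: generations and years; difference_years = mixture - sequence"))
  res
})

summary_tbl <- bind_rows(all) |>
  mutate(dose = factor(mixture_omega0, levels = c(1, 0.75, 0.5),
                       labels = c("full", "3/4", "half")),
         decay = ifelse(decay_mode == "none", "no decay", "two-stage")) |>
  group_by(scenario, decay, dose) |>
  summarise(median_diff_years = median(difference_years),
            share_mixture_wins = mean(difference_years > 0),
            .groups = "drop")

cat("Lifespan difference (mixture - sequence), by scenario, decay and mixture dose:\n")
print(as.data.frame(summary_tbl), digits = 3)

nd <- filter(bind_rows(all), scenario == 1, decay_mode == "none",
             mixture_omega0 == 1)
dd <- filter(bind_rows(all), scenario == 1, decay_mode == "two_stage",
             mixture_omega0 == 1, base_rate_i == 0.015, base_rate_j == 0.015)
cat(sprintf(paste0(
  "\nScenario 1 headline: without decay the full-dose mixture outlasts the\n",
  "sequence by %.1f-%.1f years depending on cross-resistance; with the default\n",
  "two-stage decay that advantage shrinks to %.1f-%.1f years. Reduced-dose\n",
  "mixtures lose their advantage in %.0f%% of comparisons.\n"),
  min(nd$difference_years), max(nd$difference_years),
  min(dd$difference_years), max(dd$difference_years),
  100 * mean(filter(bind_rows(all), mixture_omega0 == 0.5)$difference_years <= 0)))
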