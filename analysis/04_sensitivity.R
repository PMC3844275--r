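#!/usr/bin/env Rscript
# Stage 4 — validation machinery:
#   (a) Monte-Carlo confidence-interval coverage at the protocol scale
#       (10 datasets) and at calibration scale (200 datasets);
#   (b) per-replicate parameter comparison against the mean-series
#       optimum, for both conditions.
# Run analysis/02_generate_data.R first.

suppressPackageStartupMessages(library(lhpriming))
dir.create("results/sensitivity", recursive = TRUE, showWarnings = FALSE)

fp <- params_first_pulse()
sch <- pulse_schedule(c(223, 283))
# calibration regime: see the methods vignette for why the coverage study
# runs at low noise where the linearised intervals apply
des <- experiment_design(200, 360, dt = 2, pulse_times = c(223, 283),
                         noise_sd = 0.25, n_replicates = 6L)

cat("== Monte-Carlo coverage, protocol scale (10 datasets) ==\n")
cov10 <- monte_carlo_coverage(fp, des, n_datasets = 10, seed = 401)
print(cov10)

cat("\n== Monte-Carlo coverage, calibration scale (200 datasets) ==\n")
cov200 <- monte_carlo_coverage(fp, des, n_datasets = 200, seed = 402)
print(cov200)

cov_tab <- data.frame(
  scale = c("protocol_n10", "calibration_n200"),
  pooled_coverage = c(cov10$overall_coverage, cov200$overall_coverage),
  n_intervals = c(cov10$n_intervals, cov200$n_intervals),
  excluded = c(cov10$n_excluded, cov200$n_excluded))
write.csv(cov_tab, "results/sensitivity/coverage.csv", row.names = FALSE)
write.csv(data.frame(parameter = names(cov200$per_parameter_coverage),
                     coverage = cov200$per_parameter_coverage),
          "results/sensitivity/coverage_per_parameter.csv",
          row.names = FALSE)

for (cond in c("gnrh_only", "oxytocin")) {
  reps <- lapply(1:6, function(j)
    read_series(sprintf("results/data/%s/replicate_%d.csv", cond, j),
                label = sprintf("%s replicate %d", cond, j)))
  mean_ser <- read_series(sprintf("results/data/%s/mean_series.csv", cond))
  cmp <- suppressMessages(
    per_dataset_comparison(reps, sch, fp, mean_series = mean_ser))
  cat(sprintf("\n== Per-replicate comparison: %s ==\n", cond))
  print(cmp)
  write.csv(cmp$summary,
            sprintf("results/sensitivity/per_replicate_%s.csv", cond),
            row.names = FALSE)
}
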