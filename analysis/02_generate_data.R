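#!/usr/bin/env Rscript
# Stage 2 — generate the synthetic perifusion datasets used by the fitting
# and sensitivity stages: a GnRH-only condition and an oxytocin condition,
# each six replicate chambers sampled every 2 min with two GnRH pulses
# 60 min apart. Writes replicate and mean series plus a reproducibility
# manifest per condition.

suppressPackageStartupMessages(library(lhpriming))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

fp <- params_first_pulse()
conditions <- list(
  gnrh_only = list(params = fp, seed = 101L),
  # oxytocin raises basal secretion and the effective drive (a + OT),
  # with the kinetics unchanged — the model's account of the oxytocin data
  oxytocin = list(params = update_params(fp, OT = 3.51638 - fp$a,
                                         L0 = 1.4655),
                  seed = 102L)
)

for (nm in names(conditions)) {
  cond <- conditions[[nm]]
  des <- default_figure2_design(seed = cond$seed)
  gen <- generate_series(cond$params, des)
  dir <- file.path("results/data", nm)
  dir.create(dir, showWarnings = FALSE)
  for (j in seq_along(gen$replicates))
    write_series(gen$replicates[[j]],
                 file.path(dir, sprintf("replicate_%d.csv", j)))
  write_series(gen$mean, file.path(dir, "mean_series.csv"))
  write_trajectory(gen$truth, file.path(dir, "noise_free_truth.csv"))
  write_manifest(file.path(dir, "manifest.yaml"), params = cond$params,
                 design = des, seed = cond$seed,
                 extra = list(condition = nm))
  cat(sprintf("%-10s: %d replicates, mean peak %.2f ng/mL, basal %.3f\n",
              nm, length(gen$replicates), max(gen$mean$lh),
              cond$params$L0))
}
cat("Datasets written under results/data/\n")
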