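#!/usr/bin/env Rscript
# Stage 5 — predictive scenarios under the two-surge optimum: third-pulse
# spacing (60 vs 180 min after the second pulse), protein-synthesis
# inhibition (m = 0), and constant GnRH input.

suppressPackageStartupMessages(library(lhpriming))
dir.create("results/scenarios", recursive = TRUE, showWarnings = FALSE)

pp <- params_two_surge()

tab <- NULL
for (nm in c("third_pulse_60", "third_pulse_180",
             "inhibit_protein_synthesis")) {
  sc <- run_scenario(nm, pp)
  print(sc)
  write_trajectory(sc$trajectory,
                   file.path("results/scenarios", paste0(nm, ".csv")))
  tab <- rbind(tab, data.frame(
    scenario = nm, surge = seq_along(sc$peak_values),
    peak_time_min = sc$peak_times, peak_lh_ng_ml = sc$peak_values,
    raw_ratio = sc$priming_ratios,
    increment_ratio = sc$increment_ratios))
}
write.csv(tab, "results/scenarios/peaks.csv", row.names = FALSE)

s60 <- tab[tab$scenario == "third_pulse_60" & tab$surge == 3, ]
s180 <- tab[tab$scenario == "third_pulse_180" & tab$surge == 3, ]
cat(sprintf(
  "\nThird-surge priming (increment ratio): %.2f at 60 min vs %.2f at 180 min\n",
  s60$increment_ratio, s180$increment_ratio))

# constant GnRH: biphasic with protein synthesis, monophasic without
grid <- seq(200, 500, by = 0.25)
cg <- simulate_constant_gnrh(update_params(pp, T0 = 223, TP = 223 + pp$tp),
                             G = 1, t_on = 223, grid = grid)
write_trajectory(cg, "results/scenarios/constant_gnrh.csv")
cg0 <- simulate_constant_gnrh(update_params(pp, T0 = 223,
                                            TP = 223 + pp$tp, m = 0),
                              G = 1, t_on = 223, grid = grid)
write_trajectory(cg0, "results/scenarios/constant_gnrh_m0.csv")
slope_maxima <- function(tr) {
  sl <- diff(tr$lh) / diff(tr$time)
  tm <- (tr$time[-1] + tr$time[-length(tr$time)]) / 2
  i <- which(diff(sign(diff(sl))) == -2) + 1
  tm[i[sl[i] > max(sl) * 1e-6]]
}
cat(sprintf(
  "Constant GnRH: %d secretion phase(s) with protein synthesis (at %s min), %d without\n",
  length(slope_maxima(cg)),
  paste(round(slope_maxima(cg), 1), collapse = ", "),
  length(slope_maxima(cg0))))
cat("Scenario outputs written under results/scenarios/\n")
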