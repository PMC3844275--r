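# Shared fixtures for the test suite. Everything is generated in code;
# seeds are fixed so all stochastic checks are reproducible.

# Two-surge optimum re-anchored on the integer-minute pulse grid used by
# the synthetic designs (delay tp preserved).
two_surge_223 <- function() {
  pp <- params_two_surge()
  update_params(pp, T0 = 223, TP = 223 + pp$tp)
}

# The standard two-pulse sampling layout at a chosen noise level.
design_2pulse <- function(noise_sd, seed = NULL, n_replicates = 6L) {
  experiment_design(t_start = 200, t_end = 360, dt = 2,
                    pulse_times = c(223, 283), noise_sd = noise_sd,
                    n_replicates = n_replicates, seed = seed)
}

# Mean-of-replicates series carrying the KNOWN standard deviation of the
# mean, for well-specified weighting in simulation studies.
mean_series_known_sd <- function(gen, noise_sd, n_replicates = 6L) {
  perifusion_series(gen$mean$times, gen$mean$lh,
                    sd = rep(noise_sd / sqrt(n_replicates),
                             length(gen$mean$times)),
                    label = "mean series, known SD")
}

# Random nonnegative parameter set for property-style loops.
random_params <- function() {
  pathway_params(a = stats::runif(1, 0.5, 3),
                 p = stats::runif(1, 0.05, 0.3),
                 q = stats::runif(1, 0.02, 0.1),
                 m = stats::runif(1, 0, 20),
                 r = stats::runif(1, 0.05, 1),
                 s = stats::runif(1, 0.01, 0.2),
                 T0 = 223, TP = 223 + stats::runif(1, 5, 40),
                 OT = 0, L0 = stats::runif(1, 0, 1))
}
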