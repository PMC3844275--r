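test_that("weighted objective: exact fit, weight scaling, and a hand-computed sum", {
  pp <- two_surge_223()
  sch <- pulse_schedule(c(223, 283))
  grid <- seq(200, 360, by = 2)
  lh <- simulate_lh(pp, sch, grid)$lh
  exact <- perifusion_series(grid, lh, sd = rep(1, length(grid)))
  expect_equal(weighted_objective(pp, sch, exact), 0)
  # residuals are divided by sd, so doubling every sd quarters the objective
  noisy <- perifusion_series(grid, lh + 0.5, sd = rep(1, length(grid)))
  noisy2 <- perifusion_series(grid, lh + 0.5, sd = rep(2, length(grid)))
  expect_equal(weighted_objective(pp, sch, noisy2),
               weighted_objective(pp, sch, noisy) / 4)
  # 3-point hand computation against model values obtained separately
  t3 <- c(210, 240, 300)
  m3 <- simulate_lh(pp, sch, c(200, t3))$lh[-1]
  obs <- c(0.8, 12.0, 9.5)
  sd3 <- c(0.5, 1.5, 1.0)
  hand <- sum(((m3 - obs) / sd3)^2)
  ser3 <- perifusion_series(c(200, t3), c(pp$L0, obs),
                            sd = c(1, sd3))
  # first point is exact basal, contributing zero
  expect_equal(weighted_objective(pp, sch, ser3), hand, tolerance = 1e-12)
})

test_that("objective stays finite when the model cannot be simulated", {
  # a pulse before the observation window cannot be simulated from rest;
  # the objective must return the documented penalty, not NaN
  pp <- update_params(two_surge_223(), T0 = 100, TP = 130)
  ser <- perifusion_series(seq(200, 300, 2), rep(1, 51))
  obj <- suppressMessages(
    weighted_objective(pp, pulse_schedule(c(100, 160)), ser))
  expect_true(is.finite(obj))
  expect_equal(obj, 51 * 1e12)
})

test_that("R^2 follows its definition exactly", {
  obs <- c(1, 3, 2, 5)
  pred <- c(1.2, 2.8, 2.1, 4.6)
  # long-hand: SS_res = 0.25, SS_tot about mean 2.75 = 8.75
  expect_equal(r_squared(obs, pred), 1 - 0.25 / 8.75, tolerance = 1e-12)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_error(r_squared(rep(2, 4), pred), "zero variance")
  expect_error(r_squared(obs, pred[1:3]), "equal length")
})

test_that("noise-free two-surge data refit from a perturbed start recovers the truth", {
  pp <- two_surge_223()
  sch <- pulse_schedule(c(223, 283))
  grid <- seq(200, 360, by = 2)
  tr <- simulate_lh(pp, sch, grid)
  ser <- perifusion_series(grid, tr$lh, label = "noise-free two-surge")
  init <- update_params(pp, a = pp$a * 1.2, p = pp$p * 0.8,
                        q = pp$q * 1.2, m = pp$m * 0.8, r = pp$r * 1.2,
                        s = pp$s * 0.8, T0 = 222, TP = 222 + pp$tp * 1.2)
  fit <- suppressMessages(
    fit_parameters(ser, sch, init, mode = "unconstrained", n_starts = 1))
  expect_true(fit$converged)
  est <- setNames(fit$estimates$estimate, fit$estimates$parameter)
  truth <- c(a = pp$a, p = pp$p, q = pp$q, m = pp$m, r = pp$r, s = pp$s)
  expect_true(all(abs(est[names(truth)] - truth) / truth < 0.01))
  expect_lt(abs(est["T0"] - pp$T0), 0.5)
  expect_lt(abs(est["TP"] - pp$TP), 0.5)
  expect_lt(fit$weighted_sse, 1e-10)
  expect_gt(fit$r2, 1 - 1e-10)
})

test_that("each packaged optimum round-trips through its own noise-free output", {
  sets <- list(params_first_pulse(), params_two_surge(),
               params_oxytocin_full())
  for (pp in sets) {
    sch <- pulse_schedule(c(pp$T0, pp$T0 + 60))
    grid <- seq(200, 360, by = 2)
    ser <- perifusion_series(grid, simulate_lh(pp, sch, grid)$lh)
    fit <- suppressMessages(
      fit_parameters(ser, sch, pp, mode = "unconstrained", n_starts = 1,
                     L0 = pp$L0))
    expect_true(fit$converged)
    expect_lt(fit$weighted_sse, 1e-10)
    est <- setNames(fit$estimates$estimate, fit$estimates$parameter)
    truth <- c(a = pp$a, p = pp$p, q = pp$q, m = pp$m, r = pp$r,
               s = pp$s, T0 = pp$T0, TP = pp$TP)
    expect_equal(est[names(truth)], truth, tolerance = 1e-5)
  }
})

test_that("constrained mode rejects invalid initialisations instead of clipping", {
  pp <- update_params(two_surge_223(), p = -0.05)
  ser <- perifusion_series(seq(200, 360, 2),
                           rep(1, length(seq(200, 360, 2))))
  expect_error(
    fit_parameters(ser, pulse_schedule(c(223, 283)), pp,
                   mode = "constrained"),
    "nonnegative")
})

test_that("the fit needs more points than free parameters", {
  pp <- two_surge_223()
  ser <- perifusion_series(seq(210, 224, 2), rep(1, 8))
  expect_error(
    fit_parameters(ser, pulse_schedule(c(223, 283)), pp),
    "more data points")
})

test_that("OT-only refit recovers the combined coefficient and fixes the kinetics", {
  fp <- params_first_pulse()
  sch <- pulse_schedule(c(223, 283))
  # generating truth: the predicted oxytocin drive with elevated basal
  ot_truth <- update_params(fp, OT = 3.51638 - fp$a, L0 = 1.4655)
  des <- design_2pulse(noise_sd = 1.0, seed = 11)
  gen <- generate_series(ot_truth, des)
  ser <- perifusion_series(gen$mean$times, gen$mean$lh, sd = gen$mean$sd)
  fit <- suppressMessages(fit_ot_only(ser, sch, fp))
  expect_true(fit$converged)
  expect_identical(fit$estimates$parameter, "a_plus_OT")
  # the generating combined coefficient lies inside the 95% CI
  expect_gt(3.51638, fit$estimates$ci_low)
  expect_lt(3.51638, fit$estimates$ci_high)
  # all kinetic parameters are reported unchanged from the base fit
  for (nm in c("p", "q", "m", "r", "s", "T0", "TP"))
    expect_identical(fit$params[[nm]], fp[[nm]])

  # OT truth of zero: the refit returns the base drive strength
  gen0 <- generate_series(update_params(fp, L0 = 1.4655),
                          design_2pulse(noise_sd = 0, seed = 1))
  ser0 <- suppressMessages(fit_ot_only(
    perifusion_series(gen0$mean$times, gen0$mean$lh), sch, fp))
  expect_equal(ser0$estimates$estimate, fp$a, tolerance = 1e-6)
})

test_that("the combined coefficient scales linearly with the surge amplitude", {
  # with the slow pathway off, the LH deviation is proportional to
  # (a + OT); doubling the surges must exactly double the estimate
  fp0 <- update_params(params_first_pulse(), m = 0)
  sch <- pulse_schedule(c(223, 283))
  grid <- seq(200, 360, by = 2)
  base_lh <- simulate_lh(fp0, sch, grid)$lh
  ser1 <- perifusion_series(grid, base_lh)
  ser2 <- perifusion_series(grid, fp0$L0 + 2 * (base_lh - fp0$L0))
  f1 <- suppressMessages(fit_ot_only(ser1, sch, fp0))
  f2 <- suppressMessages(fit_ot_only(ser2, sch, fp0))
  expect_equal(f1$estimates$estimate, fp0$a, tolerance = 1e-6)
  expect_equal(f2$estimates$estimate, 2 * f1$estimates$estimate,
               tolerance = 1e-4)
})

test_that("augmentation ratios compare the two conditions on both scales", {
  ratios <- augmentation_ratios(params_two_surge(), params_oxytocin_full())
  expect_equal(unname(ratios["surge"]), 4.50872 / 1.98351,
               tolerance = 1e-12)
  expect_equal(unname(ratios["basal"]), 1.4655 / 0.7178,
               tolerance = 1e-12)
  same <- augmentation_ratios(params_two_surge(), params_two_surge())
  expect_equal(unname(same), c(1, 1))
})

test_that("parameters are recovered in the information-sufficient regime", {
  # at this noise level every parameter, including the slow-pathway pair,
  # carries enough information for accurate point estimation
  fp <- params_first_pulse()
  sch <- pulse_schedule(c(223, 283))
  truth <- c(fp$a, fp$p, fp$q, fp$m, fp$r, fp$s, fp$T0, fp$TP)
  errs <- NULL
  for (k in 1:20) {
    gen <- generate_series(fp, design_2pulse(noise_sd = 0.25,
                                             seed = 4000 + k))
    ser <- mean_series_known_sd(gen, 0.25)
    fit <- suppressMessages(
      fit_parameters(ser, sch, fp, mode = "unconstrained", n_starts = 1,
                     L0 = fp$L0))
    errs <- rbind(errs, abs(fit$estimates$estimate - truth) / abs(truth))
  }
  expect_true(all(apply(errs, 2, median) <= 0.10))
})

test_that("the fitted trajectory is accurate even where single parameters are not", {
  # at realistic perifusion noise the slow-pathway parameters (m, r) are
  # only weakly identified, but the identifiable functional — the LH
  # curve itself — is recovered to well within the data's noise
  fp <- params_first_pulse()
  sch <- pulse_schedule(c(223, 283))
  sd_mean <- 1.0 / sqrt(6)
  rmse <- sapply(1:5, function(k) {
    gen <- generate_series(fp, design_2pulse(noise_sd = 1.0,
                                             seed = 5000 + k))
    ser <- mean_series_known_sd(gen, 1.0)
    fit <- suppressMessages(
      fit_parameters(ser, sch, fp, mode = "unconstrained", n_starts = 1,
                     L0 = fp$L0))
    sqrt(mean((simulate_lh(fit$params, fit$schedule,
                           gen$truth$time)$lh - gen$truth$lh)^2))
  })
  expect_true(all(rmse < sd_mean))
})
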