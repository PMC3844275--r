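test_that("the intermediate jumps to a immediately after each pulse, not at it", {
  pp <- params_first_pulse()
  sch <- pulse_schedule(223)
  expect_identical(intermediate_i1(pp, sch, 220), 0)       # before the pulse
  expect_identical(intermediate_i1(pp, sch, 223), 0)       # H(0) = 0
  expect_equal(intermediate_i1(pp, sch, 223 + 1e-9), pp$a, tolerance = 1e-9)
  # pulses superpose
  pp2 <- two_surge_223()
  sch2 <- pulse_schedule(c(223, 283))
  t <- 290
  expect_equal(intermediate_i1(pp2, sch2, t),
               pp2$a * exp(-pp2$p * (t - 223)) +
                 pp2$a * exp(-pp2$p * (t - 283)))
})

test_that("closed-form intermediate agrees with impulse-response ODE integration", {
  # independent oracle: integrate d i1/dt = -p i1 from the post-impulse
  # state i1(T0+) = a and compare with the closed form at t = T0 + 10
  pp <- params_first_pulse()
  sol <- deSolve::ode(y = c(i1 = pp$a), times = c(223, 233),
                      func = function(t, y, parms) list(-pp$p * y),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-14)
  ode_val <- unname(sol[2, 2])
  closed <- intermediate_i1(pp, pulse_schedule(223), 233)
  expect_equal(closed, pp$a * exp(-0.846), tolerance = 1e-12)
  expect_equal(closed, ode_val, tolerance = 1e-8)
})

test_that("protein synthesis is delayed, nonnegative, and vanishes with m = 0", {
  pp <- params_first_pulse()
  sch <- pulse_schedule(223)
  t <- seq(200, 360, by = 0.25)
  pt <- protein_pt(pp, sch, t)
  expect_true(all(pt[t <= 252] == 0))          # inactive through TP
  expect_true(all(pt[t > 252] > 0))
  expect_true(all(pt >= 0))
  pp0 <- update_params(pp, m = 0)
  expect_true(all(protein_pt(pp0, sch, t) == 0))
})

test_that("protein kinetics are continuous through r = s", {
  # the fitted oxytocin kinetics actually land on r = s, a case the
  # general double-exponential formula cannot evaluate directly
  po <- params_oxytocin_full()
  sch <- pulse_schedule(po$T0)
  t_eval <- po$TP + 10
  val_degenerate <- protein_pt(po, sch, t_eval)
  # independent evaluation of the general r != s formula just off the
  # degeneracy, written out directly
  for (eps in c(1e-6, -1e-6)) {
    r_off <- po$s * (1 + eps)
    u <- t_eval - po$T0 - po$tp
    general <- po$m / (r_off - po$s) *
      (exp(-po$s * u) - exp(-r_off * u))
    expect_equal(val_degenerate, general, tolerance = 1e-4)
  }
  # and the exact limit form m * u * exp(-r u)
  u <- t_eval - po$T0 - po$tp
  expect_equal(val_degenerate, po$m * u * exp(-po$r * u),
               tolerance = 1e-12)
})

test_that("the combined rhs reduces to the pure cascade without synergy", {
  pp2 <- two_surge_223()
  sch <- pulse_schedule(c(223, 283))
  # before the first pulse, at basal: no drive
  expect_identical(lh_rhs(pp2, sch, 210, 0), 0)
  # m = 0 and OT = 0: rhs is exactly i1 - q * dev
  pp0 <- update_params(pp2, m = 0)
  t <- seq(224, 350, by = 7)
  dev <- seq_along(t) * 0.3
  expect_equal(lh_rhs(pp0, sch, t, dev),
               intermediate_i1(pp0, sch, t) - pp0$q * dev)
  # in the pre-delay window the protein is not yet active, so the full
  # model coincides with the pure cascade there
  tw <- seq(223.5, pp2$TP - 0.5, by = 2.5)
  expect_equal(lh_rhs(pp2, sch, tw, 0.1),
               intermediate_i1(pp2, sch, tw) - pp2$q * 0.1)
})

test_that("simulated LH matches the analytically integrated pure cascade", {
  # with m = 0 the LH deviation for a single pulse integrates in closed
  # form to a / (q - p) * (exp(-p tau) - exp(-q tau)); derived from the
  # cascade equations by elementary integration and written out here
  # independently of the simulator
  pp <- update_params(two_surge_223(), m = 0, L0 = 0)
  grid <- seq(200, 400, by = 0.5)
  tr <- simulate_lh(pp, pulse_schedule(223), grid)
  tau <- grid - 223
  closed <- ifelse(tau > 0,
                   pp$a / (pp$q - pp$p) * (exp(-pp$p * tau) -
                                             exp(-pp$q * tau)), 0)
  expect_lt(max(abs(tr$lh - closed) / pmax(abs(closed), 1e-12)), 1e-6)
  # before the pulse LH sits exactly at basal
  pp_b <- update_params(pp, L0 = 0.7178)
  tr_b <- simulate_lh(pp_b, pulse_schedule(223), grid)
  expect_true(all(tr_b$lh[grid <= 223] == 0.7178))
})

test_that("exact superposition and adaptive ODE integration agree", {
  pp2 <- two_surge_223()
  sch <- pulse_schedule(c(223, 283))
  grid <- seq(200, 400, by = 1)
  tr_a <- simulate_lh(pp2, sch, grid)
  tr_o <- simulate_lh(pp2, sch, grid, method = "ode")
  expect_lt(max(abs(tr_a$lh - tr_o$lh)), 1e-5)
  # also through the r = s degeneracy
  po <- params_oxytocin_full()
  scho <- pulse_schedule(c(po$T0, po$T0 + 60))
  tr_ao <- simulate_lh(po, scho, grid)
  tr_oo <- simulate_lh(po, scho, grid, method = "ode")
  expect_lt(max(abs(tr_ao$lh - tr_oo$lh)), 1e-5)
})

test_that("pulse responses superpose in i1 and PT, and in LH only without synergy", {
  set.seed(42)
  grid <- seq(200, 420, by = 1)
  for (rep in 1:5) {
    pp <- update_params(random_params(), L0 = 0)
    s1 <- pulse_schedule(223)
    s2 <- pulse_schedule(263)
    s12 <- pulse_schedule(c(223, 263))
    pp2 <- update_params(pp, T0 = 263, TP = 263 + pp$tp)
    # linear stages superpose exactly
    expect_equal(intermediate_i1(pp, s12, grid),
                 intermediate_i1(pp, s1, grid) +
                   intermediate_i1(pp2, s2, grid))
    expect_equal(protein_pt(pp, s12, grid),
                 protein_pt(pp, s1, grid) + protein_pt(pp2, s2, grid))
    # LH superposes iff the synergy term is off
    lh_sum <- simulate_lh(pp, s1, grid)$lh +
      simulate_lh(pp2, s2, grid)$lh
    lh_joint <- simulate_lh(pp, s12, grid)$lh
    if (pp$m > 0) {
      expect_gt(max(abs(lh_joint - lh_sum)), 1e-3)
    }
    pp0 <- update_params(pp, m = 0)
    pp20 <- update_params(pp2, m = 0)
    lh_sum0 <- simulate_lh(pp0, s1, grid)$lh +
      simulate_lh(pp20, s2, grid)$lh
    expect_equal(simulate_lh(pp0, s12, grid)$lh, lh_sum0,
                 tolerance = 1e-8)
  }
})

test_that("trajectories stay nonnegative and protein respects the delay", {
  set.seed(7)
  grid <- seq(200, 420, by = 1)
  for (rep in 1:5) {
    pp <- random_params()
    sch <- pulse_schedule(c(223, 273))
    tr <- simulate_lh(pp, sch, grid)
    expect_true(all(tr$i1 >= 0))
    expect_true(all(tr$pt >= 0))
    expect_true(all(tr$lh >= 0))
    expect_true(all(tr$pt[grid <= 223 + pp$tp] == 0))
  }
})

test_that("the second surge is primed under the two-surge optimum", {
  pp2 <- two_surge_223()
  grid <- seq(200, 400, by = 0.5)
  tr <- simulate_lh(pp2, pulse_schedule(c(223, 283)), grid)
  expect_gt(max(tr$lh[grid >= 283]), max(tr$lh[grid < 283]))
})

test_that("simulation rejects invalid grids and inconsistent schedules", {
  pp <- params_first_pulse()
  expect_error(simulate_lh(pp, pulse_schedule(223), c(250, 240)),
               "strictly increasing")
  expect_error(simulate_lh(pp, pulse_schedule(223), seq(230, 300, 2)),
               "at rest")
  expect_error(simulate_lh(pp, pulse_schedule(250), seq(200, 300, 2)),
               "inconsistent")
})

test_that("constant GnRH input: off means basal, on approaches the analytic fixed point", {
  pp2 <- two_surge_223()
  grid <- seq(200, 1400, by = 1)
  flat <- simulate_constant_gnrh(pp2, G = 0, t_on = 223, grid = grid)
  expect_true(all(flat$lh == pp2$L0))
  cg <- simulate_constant_gnrh(pp2, G = 1, t_on = 223, grid = grid)
  # fixed point: i1 -> aG/p, PT -> mG/(r s), dev -> synergy * i1 / q
  i1_ss <- pp2$a / pp2$p
  pt_ss <- pp2$m / (pp2$r * pp2$s)
  lh_ss <- pp2$L0 + (1 + pt_ss / pp2$a) * i1_ss / pp2$q
  expect_equal(cg$lh[length(grid)], lh_ss, tolerance = 1e-3)
  expect_error(simulate_constant_gnrh(update_params(pp2, p = 0), 1, 223,
                                      grid), "p > 0")
  expect_error(simulate_constant_gnrh(pp2, G = -1, t_on = 223, grid),
               "nonnegative")
})

test_that("finite-duration pulses converge to the impulse model as duration shrinks", {
  pp <- two_surge_223()
  sch <- pulse_schedule(c(223, 283))
  grid <- seq(200, 360, by = 2)
  impulse <- simulate_lh(pp, sch, grid)
  short <- simulate_finite_pulse(pp, sch, grid, duration = 0.05)
  long <- simulate_finite_pulse(pp, sch, grid, duration = 4)
  err_short <- max(abs(short$lh - impulse$lh))
  err_long <- max(abs(long$lh - impulse$lh))
  # same delivered stimulus: convergence to the impulse response, and a
  # 4-min pulse deviates more than a 0.05-min one
  expect_lt(err_short / max(impulse$lh), 0.005)
  expect_gt(err_long, err_short)
  expect_error(simulate_finite_pulse(pp, sch, grid, duration = 0),
               "positive")
})
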