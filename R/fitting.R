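# Build a parameter object without running validation. Used inside
# optimiser loops, where bounds already guarantee the structurally
# necessary constraints (a > 0, tp > 0) and transiently out-of-range
# proposals for the remaining fields must not abort the search.
.params_raw <- function(a, p, q, m, r, s, T0, TP, OT = 0, L0 = 0) {
  structure(list(a = a, p = p, q = q, m = m, r = r, s = s,
                 T0 = T0, TP = TP, OT = OT, L0 = L0, tp = TP - T0),
            class = "pathway_params")
}

# Each residual is replaced by this value when the model cannot be
# evaluated (non-finite trajectory, invalid transient parameter set), so
# the objective stays large but finite and the optimiser can back out.
.penalty_residual <- 1e6

.free_names <- c("a", "p", "q", "m", "r", "s", "T0", "tp")

#' Weighted least-squares objective
#'
#' The fitting criterion: the sum over sample points of squared residuals
#' between the simulated and observed LH, each divided by the point's
#' experimental standard deviation, `sum(((model - obs)/sd)^2)`. When the
#' series carries no SDs, unit weights are used and a notice is emitted.
#' If the model cannot be evaluated at the given parameters the objective
#' returns the documented large-but-finite penalty
#' (`n * 1e12`, i.e. every residual set to `1e6`) rather than `NaN`, so
#' optimisers can recover.
#'
#' @inheritParams intermediate_i1
#' @param series A [perifusion_series()].
#' @return Scalar objective value.
#' @export
weighted_objective <- function(params, schedule, series) {
  stopifnot(inherits(series, "perifusion_series"))
  res <- .weighted_residuals(params, schedule, series,
                             notify_unit_weights = TRUE)
  sum(res^2)
}

.weighted_residuals <- function(params, schedule, series,
                                notify_unit_weights = FALSE) {
  w <- series$sd
  if (is.null(w)) {
    if (notify_unit_weights)
      message("series has no per-point SD; using unit weights")
    w <- rep(1, length(series$times))
  }
  model <- tryCatch(
    simulate_lh(params, schedule, series$times)$lh,
    error = function(e) NULL)
  if (is.null(model) || !all(is.finite(model)))
    return(rep(.penalty_residual, length(series$times)))
  (model - series$lh) / w
}

#' Coefficient of determination
#'
#' Unweighted `R^2 = 1 - SS_res/SS_tot`, with the total sum of squares
#' taken about the observed mean. Used to summarise fit quality on the
#' fitted points; the weighted objective, not `R^2`, is what the optimiser
#' minimises.
#'
#' @param observed A [perifusion_series()] or numeric vector.
#' @param predicted Numeric vector of model values, same length.
#' @return Scalar `R^2` (at most 1; negative when the model does worse
#'   than the observed mean).
#' @export
r_squared <- function(observed, predicted) {
  obs <- if (inherits(observed, "perifusion_series")) observed$lh
         else as.numeric(observed)
  if (length(obs) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0)
    stop("R^2 undefined: observations have zero variance", call. = FALSE)
  1 - sum((obs - predicted)^2) / ss_tot
}

# Forward-difference Jacobian of a residual-vector function.
.num_jacobian <- function(fn, theta) {
  f0 <- fn(theta)
  J <- matrix(0, nrow = length(f0), ncol = length(theta))
  for (j in seq_along(theta)) {
    h <- max(1e-6 * abs(theta[j]), 1e-8)
    th <- theta
    th[j] <- th[j] + h
    J[, j] <- (fn(th) - f0) / h
  }
  colnames(J) <- names(theta)
  J
}

# Fix basal LH from the pre-pulse samples of a series.
.fix_L0 <- function(series, first_pulse, fallback) {
  pre <- series$times < first_pulse
  if (any(pre)) mean(series$lh[pre])
  else {
    message("no pre-pulse samples; keeping initial L0 = ", fallback)
    fallback
  }
}

#' Fit the two-pathway model to an LH series
#'
#' Weighted nonlinear least-squares estimation of the model parameters by
#' bounded Levenberg-Marquardt minimisation ([minpack.lm::nls.lm()]) of
#' [weighted_objective()]. The free parameters are, by default, the rates
#' and strengths `a, p, q, m, r, s` together with the timing parameters:
#' internally the fit works in `(T0, tp)` coordinates (first-pulse arrival
#' time and protein-synthesis delay) so the requirement `TP > T0` is a
#' simple lower bound on `tp`; `TP = T0 + tp` is reported with a
#' delta-method standard error. Later pulses keep their offsets from the
#' first pulse fixed while `T0` moves (the second surge stays 60 min after
#' the first, and so on). Basal LH `L0` is not optimised: it is fixed to
#' the mean of the pre-pulse samples.
#'
#' In `"constrained"` mode the rates and strengths are bounded below by
#' zero (negative values are biologically meaningless), `T0` is confined to
#' the observation window, and `tp >= 1` min; an initialisation violating
#' the constraints is rejected at validation, never clipped silently. In
#' `"unconstrained"` mode only the structurally necessary bounds remain
#' (`a > 0`, since it divides the synergy term, and `tp > 0`).
#'
#' Because the objective can be multimodal, the optimiser is restarted from
#' `n_starts` seeded perturbations of the initialisation (the first start
#' is the initialisation itself): strengths, rates and the delay are
#' perturbed multiplicatively by up to +/-20%, the clock time `T0` by up to
#' +/-2 min. The best final objective is kept.
#'
#' Confidence intervals are linearised: the covariance of the free
#' parameters is `s^2 (J'J)^-1` with `J` the numeric Jacobian of the
#' weighted residuals at the optimum and `s^2` the weighted SSE over
#' `n - k` degrees of freedom; 95% intervals use the t-quantile.
#'
#' @param series A [perifusion_series()] (weights come from its per-point
#'   SDs; unit weights with a notice when absent).
#' @param schedule A [pulse_schedule()]; its first pulse provides the `T0`
#'   initialisation anchor and later pulses their fixed offsets.
#' @param init A [pathway_params()] initialisation, consistent with
#'   `schedule`.
#' @param mode `"constrained"` or `"unconstrained"` (see above).
#' @param free Character vector naming the free parameters among
#'   `"a", "p", "q", "m", "r", "s", "T0", "tp"`; default all eight.
#' @param n_starts Number of multi-start optimisations (default 3).
#' @param seed Integer seed for the start perturbations, or `NULL`.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start
#'   (default 500; weakly identified directions can need long ridge walks).
#' @param L0 Optional fixed basal LH value (ng/mL). By default basal is
#'   fixed to the pre-pulse mean of the series; supply a number to pin it
#'   instead (e.g. in simulation studies where the generating basal is
#'   known, mirroring a protocol in which basal is set once from the
#'   original data and reused across refits).
#' @param variance How the residual variance entering the covariance is
#'   obtained. `"estimated"` (default) uses `s^2 = SSE/(n - k)` with a
#'   t-quantile, which makes the intervals invariant to a uniform
#'   misstatement of the weights; `"known"` takes the series' SDs at face
#'   value (`sigma^2 = 1`, normal quantile), so intervals shrink with the
#'   stated SDs — the construction to use when probing weight
#'   misspecification.
#' @return An object of class `lh_fit`: estimates table (estimate, SE, 95%
#'   CI, free flag, for `a, p, q, m, r, s, T0, TP`), the fitted
#'   [pathway_params()], weighted SSE, unweighted `R^2`, free-parameter
#'   covariance, convergence flag and iteration count, mode, and the fitted
#'   pulse schedule.
#' @export
fit_parameters <- function(series, schedule, init,
                           mode = c("constrained", "unconstrained"),
                           free = .free_names, n_starts = 3L, seed = NULL,
                           maxiter = 500L, L0 = NULL,
                           variance = c("estimated", "known")) {
  variance <- match.arg(variance)
  mode <- match.arg(mode)
  stopifnot(inherits(series, "perifusion_series"),
            inherits(schedule, "pulse_schedule"))
  # the schedule supplies the pulse offsets; init$T0 is the starting value
  # of the fitted anchor and may differ from the schedule's first pulse
  validate_params(init, constrained = (mode == "constrained"))
  free <- match.arg(free, .free_names, several.ok = TRUE)
  k <- length(free)
  n <- length(series$times)
  if (n <= k)
    stop("need more data points (", n, ") than free parameters (", k, ")",
         call. = FALSE)

  offsets <- schedule$pulse_times - schedule$pulse_times[1L]
  L0_fix <- if (is.null(L0)) {
    .fix_L0(series, schedule$pulse_times[1L], init$L0)
  } else L0
  OT_fix <- init$OT
  if (is.null(series$sd))
    message("series has no per-point SD; using unit weights")

  theta_full <- c(a = init$a, p = init$p, q = init$q, m = init$m,
                  r = init$r, s = init$s, T0 = init$T0, tp = init$tp)
  span <- range(series$times)
  if (mode == "constrained") {
    lower <- c(a = 1e-8, p = 0, q = 0, m = 0, r = 0, s = 0,
               T0 = span[1L], tp = 1)
    upper <- c(a = Inf, p = Inf, q = Inf, m = Inf, r = Inf, s = Inf,
               T0 = span[2L], tp = diff(span))
  } else {
    lower <- c(a = 1e-8, p = -Inf, q = -Inf, m = -Inf, r = -Inf, s = -Inf,
               T0 = -Inf, tp = 1e-3)
    upper <- c(a = Inf, p = Inf, q = Inf, m = Inf, r = Inf, s = Inf,
               T0 = Inf, tp = Inf)
  }

  resid_fn <- function(theta_free) {
    th <- theta_full
    th[free] <- theta_free
    pp <- .params_raw(th[["a"]], th[["p"]], th[["q"]], th[["m"]],
                      th[["r"]], th[["s"]], th[["T0"]],
                      th[["T0"]] + th[["tp"]], OT = OT_fix, L0 = L0_fix)
    sch <- tryCatch(pulse_schedule(th[["T0"]] + offsets),
                    error = function(e) NULL)
    if (is.null(sch)) return(rep(.penalty_residual, n))
    .weighted_residuals(pp, sch, series)
  }

  if (!is.null(seed)) set.seed(seed)
  starts <- vector("list", n_starts)
  starts[[1L]] <- theta_full[free]
  if (n_starts > 1L) {
    for (i in seq(2L, n_starts)) {
      th <- theta_full
      mult <- setdiff(.free_names, "T0")
      th[mult] <- th[mult] * (1 + stats::runif(length(mult), -0.2, 0.2))
      th["T0"] <- th["T0"] + stats::runif(1, -2, 2)
      th <- pmin(pmax(th, lower + 1e-10), upper)
      starts[[i]] <- th[free]
    }
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower[free], upper = upper[free],
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("all optimisation starts failed", call. = FALSE)

  theta_hat <- theta_full
  theta_hat[free] <- best$par
  converged <- best$info %in% 1:4
  .finish_fit(theta_hat, free, best, resid_fn, series, offsets,
              OT_fix, L0_fix, mode, converged, variance)
}

# Shared post-processing: covariance, CIs, estimates table, R^2.
.finish_fit <- function(theta_hat, free, best, resid_fn, series, offsets,
                        OT_fix, L0_fix, mode, converged,
                        variance = "estimated") {
  n <- length(series$times)
  k <- length(free)
  params_hat <- .params_raw(theta_hat[["a"]], theta_hat[["p"]],
                            theta_hat[["q"]], theta_hat[["m"]],
                            theta_hat[["r"]], theta_hat[["s"]],
                            theta_hat[["T0"]],
                            theta_hat[["T0"]] + theta_hat[["tp"]],
                            OT = OT_fix, L0 = L0_fix)
  schedule_hat <- pulse_schedule(theta_hat[["T0"]] + offsets)

  sse <- best$deviance
  sigma2 <- if (variance == "known") 1
            else if (n > k) sse / (n - k) else NA_real_
  J <- .num_jacobian(resid_fn, theta_hat[free])
  # invert J'J by symmetric eigendecomposition, flooring eigenvalues at
  # max(d) * 1e-12: directions the data barely constrain then get honestly
  # enormous variances instead of a failed solve
  eg <- eigen(crossprod(J), symmetric = TRUE)
  d <- pmax(eg$values, max(eg$values, 0) * 1e-12)
  cov <- if (all(d > 0)) {
    sigma2 * (eg$vectors %*% (t(eg$vectors) / d))
  } else matrix(NA_real_, k, k)
  dimnames(cov) <- list(free, free)

  tq <- if (variance == "known") stats::qnorm(0.975)
        else if (n > k) stats::qt(0.975, df = n - k) else NA_real_
  se_of <- function(name) {
    if (!(name %in% free) || anyNA(cov)) return(NA_real_)
    sqrt(max(cov[name, name], 0))
  }
  report <- c("a", "p", "q", "m", "r", "s", "T0", "TP")
  est <- se <- numeric(length(report))
  isfree <- logical(length(report))
  for (i in seq_along(report)) {
    nm <- report[i]
    if (nm == "TP") {
      est[i] <- theta_hat[["T0"]] + theta_hat[["tp"]]
      isfree[i] <- any(c("T0", "tp") %in% free)
      if (anyNA(cov) || !isfree[i]) {
        se[i] <- if (isfree[i]) NA_real_ else 0
      } else {
        v <- 0
        if ("T0" %in% free) v <- v + cov["T0", "T0"]
        if ("tp" %in% free) v <- v + cov["tp", "tp"]
        if (all(c("T0", "tp") %in% free)) v <- v + 2 * cov["T0", "tp"]
        se[i] <- sqrt(max(v, 0))
      }
    } else {
      est[i] <- theta_hat[[nm]]
      isfree[i] <- nm %in% free
      se[i] <- if (isfree[i]) se_of(nm) else 0
    }
  }
  estimates <- data.frame(
    parameter = report, estimate = est, se = se,
    ci_low = est - tq * se, ci_high = est + tq * se, free = isfree)
  fixed <- !estimates$free
  estimates$ci_low[fixed] <- estimates$estimate[fixed]
  estimates$ci_high[fixed] <- estimates$estimate[fixed]

  model_lh <- simulate_lh(params_hat, schedule_hat, series$times)$lh
  structure(list(
    params = params_hat, schedule = schedule_hat, estimates = estimates,
    free = free, weighted_sse = sse, r2 = r_squared(series, model_lh),
    cov = cov, converged = converged, iterations = best$niter,
    mode = mode, n = n, label = series$label), class = "lh_fit")
}

#' @export
print.lh_fit <- function(x, ...) {
  cat(sprintf("Two-pathway LH model fit (%s mode, %s)\n", x$mode,
              if (x$converged) sprintf("converged in %d iterations",
                                       x$iterations)
              else "DID NOT CONVERGE"))
  cat(sprintf("  %d points, weighted SSE = %.6g, R^2 = %.4f\n",
              x$n, x$weighted_sse, x$r2))
  print(format(x$estimates, digits = 6), row.names = FALSE)
  cat(sprintf("  fixed: L0 = %g ng/mL (pre-pulse mean), OT = %g\n",
              x$params$L0, x$params$OT))
  invisible(x)
}

#' Refit the oxytocin augmentation coefficient only
#'
#' Given a converged GnRH-only fit, estimates from an oxytocin-condition
#' series the single scalar the model can identify there: the combined
#' coefficient `a + OT`. Oxytocin enters additively with `a` in the drive
#' term, so `a` and `OT` are not separately identifiable; this routine
#' therefore optimises the sum, holding every other parameter at its base
#' value, and reports it as the parameter `a_plus_OT`. Basal LH is fixed to
#' the oxytocin series' pre-pulse mean.
#'
#' @param series A [perifusion_series()] recorded with oxytocin present.
#' @param schedule A [pulse_schedule()]; offsets of later pulses from the
#'   first are taken from it, the anchor from `base$T0`.
#' @param base A [pathway_params()] or converged `lh_fit` holding the
#'   GnRH-only parameter values.
#' @param maxiter Maximum optimiser iterations.
#' @return An `lh_fit` with mode `"ot_only"`, whose estimates table has the
#'   single row `a_plus_OT`; its `params` carry the base values with `OT`
#'   set so that `a + OT` equals the estimate.
#' @export
fit_ot_only <- function(series, schedule, base, maxiter = 500L) {
  if (inherits(base, "lh_fit")) {
    if (!base$converged)
      stop("base fit did not converge", call. = FALSE)
    base <- base$params
  }
  stopifnot(inherits(base, "pathway_params"),
            inherits(series, "perifusion_series"))
  offsets <- schedule$pulse_times - schedule$pulse_times[1L]
  sched <- pulse_schedule(base$T0 + offsets)
  L0_fix <- .fix_L0(series, sched$pulse_times[1L], base$L0)
  if (is.null(series$sd))
    message("series has no per-point SD; using unit weights")
  n <- length(series$times)

  resid_fn <- function(cc) {
    pp <- .params_raw(base$a, base$p, base$q, base$m, base$r, base$s,
                      base$T0, base$TP, OT = cc[[1L]] - base$a, L0 = L0_fix)
    .weighted_residuals(pp, sched, series)
  }
  start <- c(a_plus_OT = base$a + base$OT)
  best <- minpack.lm::nls.lm(par = start, lower = c(a_plus_OT = 0),
                             fn = resid_fn,
                             control = minpack.lm::nls.lm.control(
                               maxiter = maxiter))
  c_hat <- best$par[[1L]]
  converged <- best$info %in% 1:4

  sse <- best$deviance
  sigma2 <- sse / (n - 1L)
  J <- .num_jacobian(resid_fn, best$par)
  se <- sqrt(sigma2 / sum(J^2))
  tq <- stats::qt(0.975, df = n - 1L)
  estimates <- data.frame(
    parameter = "a_plus_OT", estimate = c_hat, se = se,
    ci_low = c_hat - tq * se, ci_high = c_hat + tq * se, free = TRUE)

  params_hat <- .params_raw(base$a, base$p, base$q, base$m, base$r, base$s,
                            base$T0, base$TP, OT = c_hat - base$a,
                            L0 = L0_fix)
  model_lh <- simulate_lh(params_hat, sched, series$times)$lh
  structure(list(
    params = params_hat, schedule = sched, estimates = estimates,
    free = "a_plus_OT", weighted_sse = sse,
    r2 = r_squared(series, model_lh),
    cov = matrix(se^2, 1, 1, dimnames = list("a_plus_OT", "a_plus_OT")),
    converged = converged, iterations = best$niter, mode = "ot_only",
    n = n, label = series$label), class = "lh_fit")
}

#' Oxytocin augmentation ratios
#'
#' Compares the oxytocin condition with the GnRH-only condition on two
#' scales: the surge scale, `(a + OT)` under oxytocin over `(a + OT)`
#' without (the latter normally just `a`), and the basal scale,
#' `L0` under oxytocin over `L0` without. Similar values on the two scales
#' indicate that oxytocin augments basal and pulse-driven secretion to a
#' similar degree.
#'
#' @param fit_gnrh,fit_ot `lh_fit` objects or [pathway_params()] for the
#'   GnRH-only and oxytocin conditions.
#' @return Named numeric vector `c(surge = ..., basal = ...)`.
#' @export
#' @examples
#' augmentation_ratios(params_two_surge(), params_oxytocin_full())
augmentation_ratios <- function(fit_gnrh, fit_ot) {
  pick <- function(x) {
    if (inherits(x, "lh_fit")) {
      if (!x$converged) stop("fit did not converge", call. = FALSE)
      x <- x$params
    }
    stopifnot(inherits(x, "pathway_params"))
    x
  }
  g <- pick(fit_gnrh)
  o <- pick(fit_ot)
  if ((g$a + g$OT) == 0 || g$L0 == 0)
    stop("GnRH-only drive coefficient and basal level must be nonzero",
         call. = FALSE)
  c(surge = (o$a + o$OT) / (g$a + g$OT), basal = o$L0 / g$L0)
}
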