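#' Perifusion LH time series
#'
#' Container for an observed or synthetic LH series: sampling times, LH
#' concentrations, and optionally a per-point standard deviation (in a
#' perifusion experiment, the SD across replicate chambers of the RIA
#' measurement at each fraction).
#'
#' @param times Strictly increasing sample times (min).
#' @param lh LH concentrations (ng/mL), same length.
#' @param sd Optional per-point standard deviations (ng/mL), strictly
#'   positive where given.
#' @param label Free-text provenance tag.
#' @return An object of class `perifusion_series`.
#' @export
perifusion_series <- function(times, lh, sd = NULL, label = "") {
  times <- as.numeric(times); lh <- as.numeric(lh)
  if (length(times) != length(lh))
    stop("times and lh must have equal length", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != length(times))
      stop("sd must match times in length", call. = FALSE)
    if (any(!is.finite(sd)) || any(sd <= 0))
      stop("sd must be strictly positive where present", call. = FALSE)
  }
  structure(list(times = times, lh = lh, sd = sd, label = label),
            class = "perifusion_series")
}

#' @export
print.perifusion_series <- function(x, ...) {
  cat(sprintf("Perifusion LH series '%s': %d points, t in [%g, %g] min%s\n",
              x$label, length(x$times), min(x$times), max(x$times),
              if (is.null(x$sd)) "" else ", with per-point SD"))
  invisible(x)
}

#' Synthetic perifusion experiment design
#'
#' Describes the sampling and noise structure of a simulated perifusion
#' run: the observation window, the fraction-collection interval, the GnRH
#' pulse schedule, the Gaussian noise level, and the number of replicate
#' chambers averaged into the reported mean series.
#'
#' @param t_start,t_end Observation window (min).
#' @param dt Sampling interval (min); perifusion fractions here are
#'   collected every 2 min by default.
#' @param pulse_times GnRH pulse times (min), a [pulse_schedule()] or
#'   numeric vector.
#' @param noise_sd Additive Gaussian noise SD (ng/mL): a scalar applied to
#'   every point, or a vector with one value per sample time.
#' @param n_replicates Number of independent replicate series (default 6,
#'   the number of chambers averaged in the reference experiment).
#' @param seed Integer seed for reproducible noise, or `NULL`.
#' @param pulse_duration Nominal duration of the delivered GnRH pulse
#'   (min); recorded for provenance only — the model treats each pulse as
#'   an instantaneous impulse.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(t_start, t_end, dt = 2, pulse_times,
                              noise_sd = 1.0, n_replicates = 6L,
                              seed = NULL, pulse_duration = 4) {
  if (inherits(pulse_times, "pulse_schedule"))
    pulse_times <- pulse_times$pulse_times
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (t_start >= t_end) stop("t_start must precede t_end", call. = FALSE)
  if (any(noise_sd < 0)) stop("noise_sd must be nonnegative", call. = FALSE)
  if (n_replicates < 1L) stop("need at least one replicate", call. = FALSE)
  times <- seq(t_start, t_end, by = dt)
  if (!(length(noise_sd) %in% c(1L, length(times))))
    stop("noise_sd must be scalar or one value per sample time",
         call. = FALSE)
  structure(list(t_start = t_start, t_end = t_end, dt = dt,
                 times = times,
                 pulse_times = as.numeric(pulse_times),
                 noise_sd = noise_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = seed, pulse_duration = pulse_duration),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(paste0(
    "Perifusion experiment design: [%g, %g] min every %g min, pulses at ",
    "%s min,\n  noise SD %s ng/mL, %d replicate(s)%s\n"),
    x$t_start, x$t_end, x$dt, paste(x$pulse_times, collapse = ", "),
    paste(signif(unique(x$noise_sd), 3), collapse = "/"),
    x$n_replicates,
    if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Default design emulating the two-pulse perifusion experiment
#'
#' The reference sampling layout: a 200-360 min observation window sampled
#' every 2 min, a first 4-min GnRH pulse arriving at 223 min and a second
#' 60 min later, and six replicate chambers. The default noise SD of
#' 1 ng/mL is a package constant chosen to resemble the spread of the
#' replicate error bars in such experiments (roughly 4-5% of the first
#' surge's peak); it is not a measured quantity.
#'
#' @param noise_sd Gaussian noise SD (ng/mL); see above for the default.
#' @param seed Integer seed, or `NULL`.
#' @return An [experiment_design()].
#' @export
default_figure2_design <- function(noise_sd = 1.0, seed = NULL) {
  experiment_design(t_start = 200, t_end = 360, dt = 2,
                    pulse_times = c(223, 283), noise_sd = noise_sd,
                    n_replicates = 6L, seed = seed, pulse_duration = 4)
}

#' Generate synthetic perifusion LH datasets
#'
#' Simulates the noise-free model on the design's sampling grid, then adds
#' independent Gaussian noise to each replicate. Returns the replicates,
#' their across-replicate mean series with per-point sample SD (the
#' mean-plus-error-bars structure in which perifusion data are reported),
#' and the underlying noise-free trajectory. Negative noisy values are kept
#' as drawn — truncating them would bias the stated noise model — and the
#' fitting routines tolerate them.
#'
#' @param params A [pathway_params()] object; the generating truth.
#' @param design An [experiment_design()]. Its pulse schedule must be
#'   anchored at `params$T0`.
#' @return A list with elements `replicates` (list of
#'   [perifusion_series()]), `mean` (a `perifusion_series` with per-point
#'   sample SD when there are at least two replicates), and `truth` (the
#'   noise-free `lh_trajectory`).
#' @export
#' @examples
#' des <- default_figure2_design(seed = 1)
#' pp <- update_params(params_two_surge(), T0 = 223, TP = 253.889)
#' gen <- generate_series(pp, des)
#' gen$mean
generate_series <- function(params, design) {
  stopifnot(inherits(design, "experiment_design"))
  schedule <- pulse_schedule(design$pulse_times)
  truth <- simulate_lh(params, schedule, design$times)
  n <- design$n_replicates
  npt <- length(design$times)
  sd_vec <- rep(design$noise_sd, length.out = npt)
  if (!is.null(design$seed)) set.seed(design$seed)
  reps <- matrix(truth$lh, nrow = npt, ncol = n) +
    matrix(stats::rnorm(npt * n, sd = sd_vec), nrow = npt, ncol = n)
  replicates <- lapply(seq_len(n), function(j)
    perifusion_series(design$times, reps[, j],
                      label = sprintf("synthetic replicate %d", j)))
  if (n >= 2L) {
    m <- rowMeans(reps)
    s <- apply(reps, 1L, stats::sd)
    mean_series <- perifusion_series(design$times, m,
                                     sd = if (all(s > 0)) s else NULL,
                                     label = "synthetic mean of replicates")
  } else {
    mean_series <- perifusion_series(design$times, reps[, 1L],
                                     label = "synthetic single replicate")
  }
  list(replicates = replicates, mean = mean_series, truth = truth)
}
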