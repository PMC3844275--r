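#' Read and write perifusion LH series files
#'
#' Plain comma-delimited text with a header row; columns `time_min`,
#' `lh_ng_ml` and optionally `sd_ng_ml`. Decimal point is `'.'`, encoding
#' UTF-8. The writer and reader round-trip exactly at full double
#' precision.
#'
#' @param series A [perifusion_series()].
#' @param path File path.
#' @return `read_series()` returns a [perifusion_series()];
#'   `write_series()` returns `path` invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "perifusion_series"))
  df <- data.frame(time_min = series$times, lh_ng_ml = series$lh)
  if (!is.null(series$sd)) df$sd_ng_ml <- series$sd
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @param label Provenance label attached to the series read back.
#' @export
read_series <- function(path, label = basename(path)) {
  df <- utils::read.csv(path)
  need <- c("time_min", "lh_ng_ml")
  if (!all(need %in% names(df)))
    stop("series file must have columns time_min, lh_ng_ml", call. = FALSE)
  perifusion_series(df$time_min, df$lh_ng_ml,
                    sd = if ("sd_ng_ml" %in% names(df)) df$sd_ng_ml,
                    label = label)
}

#' Read and write model trajectories
#'
#' Comma-delimited text with header `time_min,i1,pt,lh_ng_ml`.
#'
#' @param trajectory An `lh_trajectory` from [simulate_lh()].
#' @param path File path.
#' @return `read_trajectory()` returns an `lh_trajectory`;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "lh_trajectory"))
  df <- data.frame(time_min = trajectory$time, i1 = trajectory$i1,
                   pt = trajectory$pt, lh_ng_ml = trajectory$lh)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_min", "i1", "pt", "lh_ng_ml")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns time_min, i1, pt, lh_ng_ml",
         call. = FALSE)
  .new_trajectory(df$time_min, df$i1, df$pt, df$lh_ng_ml)
}

#' Read and write parameter sets as flat YAML
#'
#' Flat key-value YAML with keys exactly `a, p, q, m, r, s, T0, TP, OT,
#' L0`.
#'
#' @param params A [pathway_params()] object.
#' @param path File path.
#' @return `read_params()` returns a [pathway_params()];
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "pathway_params"))
  yaml::write_yaml(params[c("a", "p", "q", "m", "r", "s",
                            "T0", "TP", "OT", "L0")],
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  v <- yaml::read_yaml(path)
  need <- c("a", "p", "q", "m", "r", "s", "T0", "TP", "OT", "L0")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop("parameter file missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pathway_params(v$a, v$p, v$q, v$m, v$r, v$s, v$T0, v$TP, v$OT, v$L0)
}

#' Export a fit report
#'
#' Writes the per-parameter table (estimate, standard error, 95% CI,
#' free/fixed flag) followed by the fit summary (mode, convergence,
#' weighted SSE, unweighted R-squared, point count) as flat
#' tab-delimited text.
#'
#' @param fit An `lh_fit` from [fit_parameters()] or [fit_ot_only()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "lh_fit"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(format(fit$estimates, digits = 10, trim = TRUE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(c(
    sprintf("mode\t%s", fit$mode),
    sprintf("converged\t%s", fit$converged),
    sprintf("iterations\t%d", fit$iterations),
    sprintf("weighted_sse\t%.10g", fit$weighted_sse),
    sprintf("r2\t%.10g", fit$r2),
    sprintf("n_points\t%d", fit$n)), con)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records, as YAML, everything needed to regenerate a synthetic dataset or
#' rerun an analysis stage: the generating parameters, the experiment
#' design, the seed, and the package version.
#'
#' @param path File path.
#' @param params A [pathway_params()] object, or `NULL`.
#' @param design An [experiment_design()], or `NULL`.
#' @param seed Integer seed, or `NULL`.
#' @param extra Named list of further fields to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params = NULL, design = NULL, seed = NULL,
                           extra = list()) {
  man <- list(package = "lhpriming",
              version = as.character(utils::packageVersion("lhpriming")))
  if (!is.null(params))
    man$params <- params[c("a", "p", "q", "m", "r", "s",
                           "T0", "TP", "OT", "L0")]
  if (!is.null(design))
    man$design <- design[c("t_start", "t_end", "dt", "pulse_times",
                           "noise_sd", "n_replicates", "seed",
                           "pulse_duration")]
  if (!is.null(seed)) man$seed <- seed
  if (length(extra)) man <- c(man, extra)
  yaml::write_yaml(man, path, precision = 15)
  invisible(path)
}
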