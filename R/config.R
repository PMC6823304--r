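#' Pipeline configuration
#'
#' Bundles every threshold used along the pipeline. Defaults encode the
#' operational tachycardia definition (heart rate >= 130 beats/min sustained
#' for >= 5 min at >= 10% duty cycle, suprathreshold clusters merged across
#' gaps <= 30 min) and the 30-min analysis-window design with a 3-h internal
#' control baseline.
#'
#' @param tachy_threshold Heart-rate threshold in beats/min; samples at or
#'   above it count as suprathreshold.
#' @param merge_gap_min Maximum threshold-free gap, in minutes, across which
#'   suprathreshold samples are merged into one potential episode. A gap of
#'   exactly `merge_gap_min` still merges.
#' @param min_duration_min Minimum episode duration (first to last
#'   suprathreshold sample), minutes.
#' @param min_duty Minimum duty cycle: fraction of available heart-rate
#'   samples inside the episode span that are suprathreshold.
#' @param window_min Analysis-window length, minutes.
#' @param baseline_hours Offset of the internal-control / lift baseline
#'   segment: the baseline is the 3-h stretch ending this many hours before
#'   first-episode onset.
#' @param lag_min Lag between window end and episode onset, minutes
#'   (0 = window ends at onset).
#' @param min_coverage Minimum fraction of expected heart-rate samples a
#'   window must contain to be usable.
#' @param n_folds Number of cross-validation folds.
#' @param group_folds Keep all windows of a subject in the same fold
#'   (recommended; set `FALSE` for plain window-level stratification).
#' @param rng_seed Integer seed controlling every random step downstream.
#' @return A list of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$tachy_threshold
#' @export
pipeline_config <- function(tachy_threshold = 130,
                            merge_gap_min = 30,
                            min_duration_min = 5,
                            min_duty = 0.10,
                            window_min = 30,
                            baseline_hours = 3,
                            lag_min = 0,
                            min_coverage = 0.20,
                            n_folds = 10,
                            group_folds = TRUE,
                            rng_seed = 1L) {
  cfg <- list(
    tachy_threshold = tachy_threshold,
    merge_gap_min = merge_gap_min,
    min_duration_min = min_duration_min,
    min_duty = min_duty,
    window_min = window_min,
    baseline_hours = baseline_hours,
    lag_min = lag_min,
    min_coverage = min_coverage,
    n_folds = as.integer(n_folds),
    group_folds = isTRUE(group_folds),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$merge_gap_min > 0, cfg$min_duration_min > 0, cfg$window_min > 0,
    cfg$baseline_hours > 0, cfg$lag_min >= 0,
    cfg$min_duty > 0, cfg$min_duty <= 1,
    cfg$min_coverage >= 0, cfg$min_coverage <= 1,
    cfg$n_folds >= 2
  )
  structure(cfg, class = "pipeline_config")
}

#' @method print pipeline_config
#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  tachycardia: HR >= %g bpm, >= %g min, duty >= %g, merge gap <= %g min\n",
              x$tachy_threshold, x$min_duration_min, x$min_duty, x$merge_gap_min))
  cat(sprintf("  windows: %g min, min coverage %g, lag %g min\n",
              x$window_min, x$min_coverage, x$lag_min))
  cat(sprintf("  baseline: %g h; CV: %d folds (%s); seed %d\n",
              x$baseline_hours, x$n_folds,
              if (x$group_folds) "subject-grouped" else "window-level",
              x$rng_seed))
  invisible(x)
}
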