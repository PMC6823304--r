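#' Minute-by-minute risk trajectory for one subject
#'
#' At every minute `t >= window_min` of the record, the preceding
#' 30-minute window `[t - window_min, t)` is featurized and scored with the
#' trained model (mean over fold models), producing a risk value in [0, 1].
#' The first `window_min` minutes of the record carry no risk value, and
#' minutes whose window fails the heart-rate coverage rule are missing.
#'
#' @param record A [vital_record()].
#' @param bundle A `risk_model_cv` from [crossval_train()].
#' @param cfg A [pipeline_config()].
#' @param minutes Optional integer vector of record minutes (relative to
#'   the heart-rate start) at which to evaluate; defaults to every minute
#'   from `window_min` to the end of the record.
#' @return A data frame of class `"risk_trajectory"` with columns
#'   `subject`, `minute`, `time_s`, `risk` (`NA` = missing).
#' @export
rolling_risk <- function(record, bundle, cfg = pipeline_config(),
                         minutes = NULL) {
  stopifnot(inherits(record, "vital_record"))
  ext <- record_extent(record, "hr")
  total_min <- floor((ext[2] - ext[1]) / 60)
  empty <- trajectory_(record$subject_id, integer(0), numeric(0), numeric(0))
  if (!is.finite(total_min) || total_min < cfg$window_min) return(empty)
  minutes <- minutes %||% seq.int(cfg$window_min, total_min)
  minutes <- minutes[minutes >= cfg$window_min & minutes <= total_min]
  if (!length(minutes)) return(empty)
  t_end <- ext[1] + minutes * 60
  wins <- data.frame(t_start_s = t_end - cfg$window_min * 60, t_end_s = t_end)
  feats <- t(vapply(seq_len(nrow(wins)), function(i)
    featurize_window(record, wins[i, ], cfg), numeric(42)))
  covered <- window_coverage_vec_(record, wins, cfg) >= cfg$min_coverage
  risk <- rep(NA_real_, length(minutes))
  if (any(covered))
    risk[covered] <- predict(bundle, feats[covered, , drop = FALSE])
  trajectory_(record$subject_id, minutes, t_end, risk)
}

window_coverage_vec_ <- function(record, wins, cfg) {
  vapply(seq_len(nrow(wins)), function(i)
    window_coverage_(record, wins$t_start_s[i], wins$t_end_s[i], cfg),
    numeric(1))
}

trajectory_ <- function(subject, minute, time_s, risk, lift = NULL,
                        anchor = NA_real_) {
  out <- data.frame(subject = rep(as.character(subject), length(minute)),
                    minute = minute, time_s = time_s, risk = risk)
  if (!is.null(lift)) out$lift <- lift
  attr(out, "anchor") <- anchor
  class(out) <- c("risk_trajectory", "data.frame")
  out
}

#' Build a lagged case/control modeling dataset
#'
#' Constructs the group-1 dataset whose case windows end `lag_min` minutes
#' before episode onsets (a lag-0 dataset reproduces the group-1 design
#' exactly); control windows are unaffected by the lag. Cases whose
#' shifted window exits the data are dropped and logged by the window
#' builder. The result feeds [crossval_train()] directly.
#'
#' @param records Named list of [vital_record()] objects.
#' @param episodes Episode table for the cohort.
#' @param lag_min Lag in minutes (0, 10, 20, 30 are the usual horizons).
#' @param cfg A [pipeline_config()].
#' @param group Modeling group for the window design (default 1).
#' @param n_controls Control count target; defaults to the case count.
#' @return List with `features` (feature table of all windows) and
#'   `labels` (1 = case, 0 = control).
#' @export
lagged_dataset <- function(records, episodes, lag_min = 0,
                           cfg = pipeline_config(), group = 1,
                           n_controls = NULL) {
  cases <- case_windows(episodes, records, group = group, lag_min = lag_min,
                        cfg = cfg)
  controls <- control_windows(records, episodes, group = group, cfg = cfg,
                              n_target = n_controls %||% nrow(cases),
                              rng_seed = cfg$rng_seed)
  windows <- rbind(as.data.frame(cases), as.data.frame(controls))
  feats <- featurize_windows(records, windows, cfg)
  list(features = feats, labels = as.integer(windows$label == "case"))
}

#' Risk and lift trajectory ahead of a subject's first episode
#'
#' For a case subject with enough episode-free data, the patient-specific
#' baseline risk is the mean rolling risk over the 3-h segment ending
#' `baseline_hours` before first-episode onset; the lift at each minute of
#' the 3 h preceding onset is that minute's risk divided by the baseline.
#' Lift is scale-free: it measures each patient against their own
#' baseline, so a uniformly scaled risk model yields the same lift.
#'
#' @param record A [vital_record()] for one case subject.
#' @param bundle A `risk_model_cv`.
#' @param episodes Episode table (this subject's episodes are used).
#' @param cfg A [pipeline_config()].
#' @return A `"risk_trajectory"` data frame over the 3 h before onset with
#'   columns `subject`, `minute` (minutes relative to onset, negative),
#'   `time_s`, `risk`, `lift`; attribute `"baseline"` holds the baseline
#'   risk. `NULL` when the subject lacks the required baseline data (the
#'   reason is messaged); `lift` is all-`NA` when the baseline risk is
#'   numerically zero.
#' @export
lift_trajectory <- function(record, bundle, episodes, cfg = pipeline_config()) {
  eps <- episodes[episodes$subject == record$subject_id, , drop = FALSE]
  if (!nrow(eps)) { message("lift: no episode for ", record$subject_id); return(NULL) }
  onset <- min(eps$start_s)
  ext <- record_extent(record, "hr")
  base_s <- cfg$baseline_hours * 3600
  seg_len <- 3 * 3600
  base_start <- onset - base_s - seg_len
  if (base_start - cfg$window_min * 60 < ext[1] || onset - base_s < ext[1]) {
    message("lift: insufficient baseline data for ", record$subject_id)
    return(NULL)
  }
  if (overlaps_episode_(eps, record$subject_id, base_start, onset - 1e-9)) {
    message("lift: episode intrudes into baseline for ", record$subject_id)
    return(NULL)
  }
  onset_min <- round((onset - ext[1]) / 60)
  base_minutes <- seq.int(onset_min - (base_s + seg_len) / 60,
                          onset_min - base_s / 60)
  pre_minutes <- seq.int(onset_min - seg_len / 60, onset_min - 1)
  tr_base <- rolling_risk(record, bundle, cfg, minutes = base_minutes)
  tr_pre <- rolling_risk(record, bundle, cfg, minutes = pre_minutes)
  baseline <- mean(tr_base$risk, na.rm = TRUE)
  lift <- compute_lift(tr_pre$risk, tr_base$risk)
  if (all(is.na(lift)))
    message("lift: baseline risk ~0 for ", record$subject_id)
  out <- trajectory_(record$subject_id, tr_pre$minute - onset_min,
                     tr_pre$time_s, tr_pre$risk, lift = lift, anchor = onset)
  attr(out, "baseline") <- baseline
  out
}

#' Lift from risk and baseline risk
#'
#' The lift at each minute is the minute's risk divided by the subject's
#' mean baseline risk. Scale-free by construction: multiplying all of a
#' subject's risks (pre-onset and baseline alike) by any c > 0 leaves the
#' lift unchanged. A numerically zero baseline (below `1e-6`) makes the
#' lift undefined.
#'
#' @param risk Minute-by-minute risk over the pre-onset segment.
#' @param baseline_risk Risk values over the baseline segment.
#' @return Numeric vector of lifts (all `NA` when the baseline is ~0).
#' @export
compute_lift <- function(risk, baseline_risk) {
  baseline <- mean(baseline_risk, na.rm = TRUE)
  if (!is.finite(baseline) || baseline < 1e-6)
    return(rep(NA_real_, length(risk)))
  risk / baseline
}

#' Minute-aligned group summary of trajectories
#'
#' Aligns trajectories either on the episode onset (`"to_onset"`, using
#' the minute index already expressed relative to the anchor, as
#' [lift_trajectory()] returns) or on the raw record minute
#' (`"to_window"`), and computes the per-minute across-subject mean, SD,
#' and normal-approximation 95% confidence band, excluding missing minutes
#' pairwise.
#'
#' @param trajectories List of `"risk_trajectory"` data frames (>= 2).
#' @param alignment `"to_onset"` or `"to_window"`.
#' @param value Column to aggregate, `"risk"` or `"lift"`.
#' @return Data frame `minute`, `n`, `mean`, `sd`, `ci_lo`, `ci_hi`.
#' @export
aggregate_trajectories <- function(trajectories,
                                   alignment = c("to_onset", "to_window"),
                                   value = c("risk", "lift")) {
  alignment <- match.arg(alignment)
  value <- match.arg(value)
  stopifnot(length(trajectories) >= 2)
  rows <- do.call(rbind, lapply(trajectories, function(tr)
    data.frame(minute = tr$minute, v = tr[[value]])))
  rows <- rows[is.finite(rows$v), , drop = FALSE]
  agg <- lapply(split(rows$v, rows$minute), function(v)
    c(n = length(v), mean = mean(v),
      sd = if (length(v) > 1) stats::sd(v) else 0))
  m <- do.call(rbind, agg)
  se <- ifelse(m[, "n"] > 0, m[, "sd"] / sqrt(m[, "n"]), NA_real_)
  data.frame(minute = as.numeric(rownames(m)), n = m[, "n"],
             mean = m[, "mean"], sd = m[, "sd"],
             ci_lo = m[, "mean"] - 1.96 * se,
             ci_hi = m[, "mean"] + 1.96 * se,
             row.names = NULL)
}
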