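#' Detect tachycardia episodes in one record
#'
#' Implements the operational episode definition. All heart-rate samples at
#' or above `tachy_threshold` are suprathreshold; consecutive suprathreshold
#' samples separated by at most `merge_gap_min` of threshold-free time are
#' clustered into one potential episode; a potential episode is retained
#' when it lasts at least `min_duration_min` (first to last suprathreshold
#' sample) and its duty cycle is at least `min_duty`. The duty cycle is the
#' fraction of *available* heart-rate samples inside the episode span that
#' are suprathreshold, so stretches of missing data do not dilute the
#' density.
#'
#' @param record A [vital_record()] with an `hr` channel.
#' @param cfg A [pipeline_config()].
#' @return A data frame of class `"episode_table"`, one row per retained
#'   episode, sorted by `start_s`, with columns `subject`, `start_s`,
#'   `end_s`, `duration_s`, `n_samples`, `n_supra`, `duty`.
#' @examples
#' rec <- vital_record("s1", list(hr = data.frame(time_s = 0:9 * 60,
#'                                                value = rep(140, 10))))
#' detect_episodes(rec, pipeline_config())
#' @export
detect_episodes <- function(record, cfg = pipeline_config()) {
  stopifnot(inherits(record, "vital_record"))
  hr <- record$channels[["hr"]]
  if (is.null(hr)) stop("record ", record$subject_id, " has no hr channel")
  empty <- episode_table_(record$subject_id, numeric(0), numeric(0),
                          integer(0), integer(0))
  if (!nrow(hr)) return(empty)
  t <- hr$time_s
  supra <- hr$value >= cfg$tachy_threshold
  ts <- t[supra]
  if (!length(ts)) return(empty)
  gap_s <- cfg$merge_gap_min * 60
  # gaps strictly larger than the merge gap split clusters
  cl <- cumsum(c(1, as.integer(diff(ts) > gap_s)))
  start_s <- tapply(ts, cl, min)
  end_s <- tapply(ts, cl, max)
  n_supra <- as.integer(table(cl))
  n_samples <- vapply(seq_along(start_s), function(i)
    sum(t >= start_s[i] & t <= end_s[i]), integer(1))
  ep <- episode_table_(record$subject_id, as.numeric(start_s),
                       as.numeric(end_s), n_samples, n_supra)
  keep <- ep$duration_s >= cfg$min_duration_min * 60 & ep$duty >= cfg$min_duty
  ep <- ep[keep, , drop = FALSE]
  rownames(ep) <- NULL
  ep[order(ep$start_s), , drop = FALSE]
}

episode_table_ <- function(subject, start_s, end_s, n_samples, n_supra) {
  structure(
    data.frame(subject = rep(as.character(subject), length(start_s)),
               start_s = start_s, end_s = end_s,
               duration_s = end_s - start_s,
               n_samples = n_samples, n_supra = n_supra,
               duty = as.numeric(ifelse(n_samples > 0,
                                        n_supra / n_samples, NA_real_))),
    class = c("episode_table", "data.frame"))
}

#' Detect episodes across a cohort
#'
#' @param records List of [vital_record()] objects.
#' @inheritParams detect_episodes
#' @return One `episode_table` with all subjects' episodes.
#' @export
detect_episodes_cohort <- function(records, cfg = pipeline_config()) {
  out <- do.call(rbind, lapply(records, detect_episodes, cfg = cfg))
  if (is.null(out))
    out <- episode_table_(character(0), numeric(0), numeric(0),
                          integer(0), integer(0))
  rownames(out) <- NULL
  out
}

#' Tachycardia-free intervals of a record
#'
#' Returns the stretches of the record (heart-rate extent) that lie at
#' least `guard_min` minutes away from every detected episode and contain
#' no suprathreshold heart-rate sample (stray suprathreshold samples that
#' did not form an episode split the intervals at their time points).
#' Used to place control windows and baseline segments.
#'
#' @param record A [vital_record()].
#' @param episodes Episode table from [detect_episodes()] on this record.
#' @param guard_min Guard margin around episodes, minutes.
#' @param cfg A [pipeline_config()] (supplies the threshold).
#' @return Data frame with columns `start_s`, `end_s` (possibly 0 rows).
#' @export
tachyfree_mask <- function(record, episodes, guard_min = 30,
                           cfg = pipeline_config()) {
  hr <- record_channel(record, "hr")
  if (!nrow(hr)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  lo <- min(hr$time_s); hi <- max(hr$time_s)
  g <- guard_min * 60
  eps <- episodes[episodes$subject == record$subject_id, , drop = FALSE]
  cut <- if (nrow(eps)) cbind(eps$start_s - g, eps$end_s + g) else NULL
  segs <- subtract_intervals(lo, hi, cut)
  # split remaining intervals at stray suprathreshold samples
  stray <- hr$time_s[hr$value >= cfg$tachy_threshold]
  if (length(stray) && nrow(segs)) {
    eps_tol <- 1e-9
    segs <- subtract_intervals_many_(segs, cbind(stray - eps_tol, stray + eps_tol))
  }
  segs <- segs[segs[, 2] > segs[, 1], , drop = FALSE]
  data.frame(start_s = segs[, 1], end_s = segs[, 2])
}

subtract_intervals_many_ <- function(segs, cut) {
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(segs)))
    out <- rbind(out, subtract_intervals(segs[i, 1], segs[i, 2], cut))
  out
}
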