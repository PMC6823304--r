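#' Case windows for the three modeling groups
#'
#' Builds labeled 30-min analysis windows ending `lag_min` minutes before
#' episode onsets. Group 1 anchors one window to every episode; groups 2
#' and 3 anchor one window per subject to that subject's earliest episode.
#' A window spans `[t_end - window_min, t_end)` so the onset sample itself
#' is never part of the window. Windows that would precede the start of the
#' subject's heart-rate data, or that contain fewer than `min_coverage` of
#' the expected heart-rate samples, are dropped; dropped windows are listed
#' in the `"dropped"` attribute.
#'
#' @param episodes Episode table from [detect_episodes_cohort()].
#' @param records Named list of [vital_record()] objects.
#' @param group Modeling group, 1, 2 or 3.
#' @param lag_min Minutes between window end and episode onset.
#' @param cfg A [pipeline_config()].
#' @return A window table: data frame with columns `subject`, `t_start_s`,
#'   `t_end_s`, `label`, `group`, `lag_min`, `episode_ref`.
#' @export
case_windows <- function(episodes, records, group = 1, lag_min = 0,
                         cfg = pipeline_config()) {
  stopifnot(group %in% 1:3, lag_min >= 0)
  eps <- episodes
  if (group %in% c(2, 3) && nrow(eps)) {
    first <- tapply(seq_len(nrow(eps)), eps$subject, function(i)
      i[which.min(eps$start_s[i])])
    eps <- eps[unlist(first), , drop = FALSE]
  }
  win_s <- cfg$window_min * 60
  out <- list(); dropped <- list()
  for (i in seq_len(nrow(eps))) {
    sub <- eps$subject[i]
    rec <- records[[sub]]
    if (is.null(rec)) { dropped[[length(dropped) + 1]] <- c(sub, "no record"); next }
    t_end <- eps$start_s[i] - lag_min * 60
    t_start <- t_end - win_s
    ext <- record_extent(rec, "hr")
    if (t_start < ext[1]) {
      dropped[[length(dropped) + 1]] <- c(sub, "window precedes data"); next
    }
    if (window_coverage_(rec, t_start, t_end, cfg) < cfg$min_coverage) {
      dropped[[length(dropped) + 1]] <- c(sub, "insufficient coverage"); next
    }
    out[[length(out) + 1]] <- window_row_(sub, t_start, t_end, "case", group,
                                          lag_min, episode_id_(eps[i, ]))
  }
  finish_windows_(out, dropped)
}

episode_id_ <- function(ep) paste0(ep$subject, "@", ep$start_s)

window_row_ <- function(subject, t_start, t_end, label, group, lag_min, ref) {
  data.frame(subject = subject, t_start_s = t_start, t_end_s = t_end,
             label = label, group = group, lag_min = lag_min,
             episode_ref = ref %||% NA_character_)
}

finish_windows_ <- function(rows, dropped) {
  out <- if (length(rows)) do.call(rbind, rows) else
    window_row_(character(0), numeric(0), numeric(0), character(0),
                integer(0), numeric(0), character(0))
  rownames(out) <- NULL
  if (length(dropped)) {
    log <- do.call(rbind, dropped)
    attr(out, "dropped") <- data.frame(subject = log[, 1], reason = log[, 2])
    message("windows: dropped ", nrow(log), " window(s)/subject(s)")
  }
  class(out) <- c("window_table", "data.frame")
  out
}

window_coverage_ <- function(record, t_start, t_end, cfg) {
  hr <- record_channel(record, "hr")
  n <- sum(hr$time_s >= t_start & hr$time_s < t_end)
  n / ((t_end - t_start) / record$nominal_period_s)
}

# the control-window artifact screen: physiologically implausible values or
# single-step jumps mark a window as artifactual
window_is_clean_ <- function(record, t_start, t_end) {
  hr <- record_channel(record, "hr")
  v <- hr$value[hr$time_s >= t_start & hr$time_s < t_end]
  if (!length(v)) return(FALSE)
  all(v >= 20 & v <= 300) && (length(v) < 2 || max(abs(diff(v))) <= 60)
}

#' Control windows for the three modeling groups
#'
#' Groups 1 and 2 draw one uniformly random 30-min window from each sampled
#' never-tachycardic subject, count-matched approximately 1:1 to the case
#' windows; windows failing the coverage rule or the artifact screen (no
#' heart-rate sample outside 20-300 beats/min, no single-step change above
#' 60 beats/min) are redrawn, and subjects with no acceptable window are
#' excluded. Group 3 places internal-control windows on the case subjects
#' themselves: the window ends exactly `baseline_hours` before the
#' subject's first-episode onset, and subjects lacking that much
#' episode-free heart-rate data beforehand are excluded.
#'
#' @param records Named list of [vital_record()] objects.
#' @param episodes Episode table for the cohort.
#' @param group Modeling group, 1, 2 or 3.
#' @param cfg A [pipeline_config()].
#' @param n_target Number of control windows wanted (groups 1-2); defaults
#'   to one per eligible subject. Ignored for group 3.
#' @param rng_seed Seed making the random draws reproducible.
#' @return A window table (see [case_windows()]) with `label = "control"`.
#' @export
control_windows <- function(records, episodes, group = 1,
                            cfg = pipeline_config(), n_target = NULL,
                            rng_seed = cfg$rng_seed) {
  stopifnot(group %in% 1:3)
  win_s <- cfg$window_min * 60
  if (group == 3) return(internal_controls_(records, episodes, cfg))
  ep_subjects <- unique(episodes$subject)
  candidates <- names(records)[!(names(records) %in% ep_subjects)]
  out <- list(); dropped <- list()
  with_seed(rng_seed, {
    candidates <- sample(candidates)
    n_target <- n_target %||% length(candidates)
    for (sub in candidates) {
      if (length(out) >= n_target) break
      rec <- records[[sub]]
      ext <- record_extent(rec, "hr")
      if (any(is.na(ext)) || diff(ext) < win_s) {
        dropped[[length(dropped) + 1]] <- c(sub, "record shorter than window")
        next
      }
      ok <- FALSE
      for (try in 1:50) {
        t_start <- stats::runif(1, ext[1], ext[2] - win_s)
        t_end <- t_start + win_s
        if (window_coverage_(rec, t_start, t_end, cfg) >= cfg$min_coverage &&
            window_is_clean_(rec, t_start, t_end) &&
            !overlaps_episode_(episodes, sub, t_start, t_end)) {
          out[[length(out) + 1]] <- window_row_(sub, t_start, t_end, "control",
                                                group, 0, NA_character_)
          ok <- TRUE
          break
        }
      }
      if (!ok) dropped[[length(dropped) + 1]] <- c(sub, "no eligible window")
    }
  })
  finish_windows_(out, dropped)
}

overlaps_episode_ <- function(episodes, subject, t_start, t_end) {
  eps <- episodes[episodes$subject == subject, , drop = FALSE]
  any(eps$start_s < t_end & eps$end_s > t_start)
}

internal_controls_ <- function(records, episodes, cfg) {
  win_s <- cfg$window_min * 60
  base_s <- cfg$baseline_hours * 3600
  out <- list(); dropped <- list()
  for (sub in unique(episodes$subject)) {
    eps <- episodes[episodes$subject == sub, , drop = FALSE]
    onset <- min(eps$start_s)
    rec <- records[[sub]]
    if (is.null(rec)) { dropped[[length(dropped) + 1]] <- c(sub, "no record"); next }
    t_end <- onset - base_s
    t_start <- t_end - win_s
    ext <- record_extent(rec, "hr")
    free <- tachyfree_mask(rec, eps, guard_min = 0, cfg = cfg)
    pre_ok <- any(free$start_s <= onset - base_s & free$end_s >= onset - 1e-9) ||
      nrow(eps) == 0
    # the subject needs baseline_hours of episode-free data before onset and
    # room for the window before that
    if (t_start < ext[1] || !pre_ok) {
      dropped[[length(dropped) + 1]] <- c(sub, "insufficient pre-episode baseline")
      next
    }
    if (window_coverage_(rec, t_start, t_end, cfg) < cfg$min_coverage) {
      dropped[[length(dropped) + 1]] <- c(sub, "insufficient coverage")
      next
    }
    if (overlaps_episode_(episodes, sub, t_start, t_end)) {
      dropped[[length(dropped) + 1]] <- c(sub, "window overlaps an episode")
      next
    }
    out[[length(out) + 1]] <- window_row_(sub, t_start, t_end, "control", 3,
                                          0, NA_character_)
  }
  finish_windows_(out, dropped)
}
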