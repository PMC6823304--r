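#' Simulator configuration
#'
#' Parameters of the multichannel vital-sign generator. Each channel is a
#' subject-specific baseline (population mean plus a between-subject
#' offset) overlaid with stationary AR(1) noise on the one-minute grid.
#' Case subjects receive a linear heart-rate ramp starting
#' `drift_lead_min` minutes before a scheduled episode onset, with coupled
#' respiratory-rate rise and SpO2 decline, followed by an episode period
#' in which each minute's heart rate exceeds the tachycardia threshold
#' with probability `episode_duty` (the onset minute always does, and at
#' least 10% of episode minutes are forced suprathreshold). Outside
#' scheduled episodes every heart-rate sample is clipped below the
#' threshold, so the scheduled episodes are the only ground truth. Samples
#' are deleted independently at `missing_rate`; control records receive
#' single-sample artifact spikes (HR 180-250 beats/min) at `artifact_rate`
#' per hour, thinned so spikes are farther apart than the merge gap and
#' can never satisfy the episode definition by themselves.
#'
#' Defaults describe a stable adult ICU population (HR 85 +/- 8 between
#' subjects, minute-to-minute SD 4 with lag-1 autocorrelation 0.85; RR 18,
#' SpO2 97, ABP 120/62, MAP 82), a 0.3 beats/min/min pre-episode ramp over
#' 90 min, a 30-min episode at the 35% mean duty cycle observed for
#' operationally defined episodes, 10% missingness, and 0.2 artifacts/h.
#'
#' @param n_case_subjects,n_control_subjects Cohort sizes.
#' @param record_hours Record length, hours.
#' @param hr_mean,hr_sd,hr_subject_sd Heart-rate population mean, within-
#'   subject noise SD, and between-subject SD (beats/min).
#' @param rr_mean,rr_sd,rr_subject_sd Respiratory rate (breaths/min).
#' @param spo2_mean,spo2_sd,spo2_subject_sd Oxygen saturation (%).
#' @param abpsys_mean,abpsys_sd,abpdias_mean,abpdias_sd,abpmean_mean,abpmean_sd
#'   Arterial pressures (mmHg); between-subject SD `abp_subject_sd`.
#' @param abp_subject_sd Between-subject SD shared by the pressure channels.
#' @param ar_coeff Lag-1 autocorrelation of each channel's noise, in [0, 1).
#' @param drift_lead_min Minutes before onset at which the ramp starts.
#' @param drift_slope Heart-rate ramp, beats/min per minute.
#' @param rr_drift_slope,spo2_drift_slope Coupled drifts (breaths/min per
#'   minute; percent per minute, negative for decline).
#' @param episode_duty Per-minute probability of a suprathreshold sample
#'   during the episode.
#' @param episode_len_min Episode length, minutes.
#' @param missing_rate Independent per-sample deletion probability.
#' @param artifact_rate Artifact spikes per hour (control records).
#' @param rng_seed Master seed; per-subject seeds derive from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_case_subjects = 20, n_control_subjects = 20,
                       record_hours = 12,
                       hr_mean = 85, hr_sd = 4, hr_subject_sd = 8,
                       rr_mean = 18, rr_sd = 2, rr_subject_sd = 2.5,
                       spo2_mean = 97, spo2_sd = 0.8, spo2_subject_sd = 1,
                       abpsys_mean = 120, abpsys_sd = 7,
                       abpdias_mean = 62, abpdias_sd = 5,
                       abpmean_mean = 82, abpmean_sd = 6,
                       abp_subject_sd = 8,
                       ar_coeff = 0.85,
                       drift_lead_min = 90, drift_slope = 0.3,
                       rr_drift_slope = 0.06, spo2_drift_slope = -0.03,
                       episode_duty = 0.35, episode_len_min = 30,
                       missing_rate = 0.10, artifact_rate = 0.2,
                       rng_seed = 1L) {
  sim <- as.list(environment())
  stopifnot(sim$missing_rate >= 0, sim$missing_rate <= 1,
            sim$episode_duty >= 0, sim$episode_duty <= 1,
            sim$ar_coeff >= 0, sim$ar_coeff < 1,
            sim$drift_lead_min > 30, sim$record_hours > 0,
            sim$episode_len_min > 0)
  structure(sim, class = "sim_config")
}

ar1_noise_ <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  as.numeric(stats::arima.sim(list(ar = phi), n,
                              sd = sd * sqrt(1 - phi^2)))
}

#' Simulate one subject's record
#'
#' Generates a fully seeded [vital_record()] on the one-minute grid plus a
#' ground-truth episode table (empty for controls). See [sim_config()] for
#' the generative model.
#'
#' @param sim A [sim_config()].
#' @param is_case Whether the subject receives a drift plus episode.
#' @param seed Integer seed fully determining the subject.
#' @param subject_id Subject identifier.
#' @param tachy_threshold Heart-rate threshold the episode is built around.
#' @return List with `record` (a [vital_record()]) and `truth` (data frame
#'   `subject`, `onset_s`, `end_s`; 0 rows for controls).
#' @export
simulate_subject <- function(sim, is_case, seed = sim$rng_seed,
                             subject_id = "S1", tachy_threshold = 130) {
  total_min <- round(sim$record_hours * 60)
  if (is_case) {
    lo <- max(sim$drift_lead_min + 35, ceiling(0.55 * total_min))
    hi <- total_min - sim$episode_len_min - 10
    if (lo > hi)
      stop("infeasible config: episode would extend beyond the record end")
  }
  with_seed(seed, {
    minute <- seq_len(total_min) - 1
    specs <- list(
      hr = c(sim$hr_mean, sim$hr_sd, sim$hr_subject_sd),
      rr = c(sim$rr_mean, sim$rr_sd, sim$rr_subject_sd),
      spo2 = c(sim$spo2_mean, sim$spo2_sd, sim$spo2_subject_sd),
      abpsys = c(sim$abpsys_mean, sim$abpsys_sd, sim$abp_subject_sd),
      abpdias = c(sim$abpdias_mean, sim$abpdias_sd, sim$abp_subject_sd),
      abpmean = c(sim$abpmean_mean, sim$abpmean_sd, sim$abp_subject_sd))
    base <- lapply(specs, function(p)
      p[1] + stats::rnorm(1, 0, p[3]) + ar1_noise_(total_min, p[2], sim$ar_coeff))
    onset_min <- NA_real_
    if (is_case) {
      onset_min <- floor(stats::runif(1, lo, hi + 1))
      elapsed <- pmin(pmax(minute - (onset_min - sim$drift_lead_min), 0),
                      sim$drift_lead_min)
      base$hr <- base$hr + sim$drift_slope * elapsed
      base$rr <- base$rr + sim$rr_drift_slope * elapsed
      base$spo2 <- base$spo2 + sim$spo2_drift_slope * elapsed
    }
    # scheduled episodes are the only ground truth: clip everything else
    hr <- pmin(base$hr, tachy_threshold - 1)
    if (is_case) {
      ep_idx <- which(minute >= onset_min &
                        minute < onset_min + sim$episode_len_min)
      supra <- stats::runif(length(ep_idx)) < sim$episode_duty
      supra[1] <- TRUE
      need <- ceiling(0.10 * length(ep_idx))
      while (sum(supra) < need)
        supra[sample(which(!supra), 1)] <- TRUE
      hr[ep_idx[supra]] <- tachy_threshold + 5 +
        abs(stats::rnorm(sum(supra), 0, 8))
    }
    channels <- list(hr = pmax(hr, 20),
                     rr = pmax(base$rr, 4),
                     spo2 = pmin(pmax(base$spo2, 60), 100),
                     abpsys = pmax(base$abpsys, 30),
                     abpdias = pmax(base$abpdias, 15),
                     abpmean = pmax(base$abpmean, 20))
    if (!is_case && sim$artifact_rate > 0) {
      n_art <- stats::rpois(1, sim$artifact_rate * sim$record_hours)
      art <- integer(0)
      # greedy thinning: spikes stay > merge_gap apart so they can never
      # cluster into something satisfying the episode definition
      for (cand in sample.int(total_min, total_min) - 1) {
        if (length(art) >= n_art) break
        if (!length(art) || min(abs(art - cand)) > 31) art <- c(art, cand)
      }
      channels$hr[art + 1] <- stats::runif(length(art), 180, 250)
    }
    keep <- lapply(channels, function(v)
      stats::runif(length(v)) >= sim$missing_rate)
    chans <- lapply(names(channels), function(nm)
      data.frame(time_s = minute[keep[[nm]]] * 60,
                 value = channels[[nm]][keep[[nm]]]))
    names(chans) <- names(channels)
    truth <- if (is_case) {
      data.frame(subject = subject_id,
                 onset_s = onset_min * 60,
                 end_s = (onset_min + sim$episode_len_min - 1) * 60)
    } else data.frame(subject = character(0), onset_s = numeric(0),
                      end_s = numeric(0))
    list(record = vital_record(subject_id, chans, nominal_period_s = 60),
         truth = truth)
  })
}

#' Simulate a cohort with ground truth
#'
#' Simulates `n_case_subjects` case and `n_control_subjects` control
#' records with per-subject seeds derived deterministically from
#' `sim$rng_seed`. Optionally writes the cohort to `dir` as the same long
#' CSV [read_records()] consumes (`records.csv`) plus the ground-truth
#' episode table (`truth_episodes.csv`).
#'
#' @param sim A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `records` (named list of [vital_record()]), `truth`
#'   (data frame `subject`, `onset_s`, `end_s`, scheduled episodes only),
#'   `is_case` (named logical), and `sim`.
#' @export
simulate_cohort <- function(sim = sim_config(), dir = NULL) {
  n <- sim$n_case_subjects + sim$n_control_subjects
  is_case <- c(rep(TRUE, sim$n_case_subjects),
               rep(FALSE, sim$n_control_subjects))
  ids <- sprintf("%s%03d", ifelse(is_case, "C", "N"),
                 c(seq_len(sim$n_case_subjects),
                   seq_len(sim$n_control_subjects)))
  sims <- lapply(seq_len(n), function(i)
    simulate_subject(sim, is_case[i], seed = derive_seed(sim$rng_seed, i),
                     subject_id = ids[i]))
  records <- lapply(sims, `[[`, "record")
  names(records) <- ids
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  rownames(truth) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_records(records, file.path(dir, "records.csv"))
    write_table(truth, file.path(dir, "truth_episodes.csv"))
  }
  list(records = records, truth = truth,
       is_case = stats::setNames(is_case, ids), sim = sim)
}
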