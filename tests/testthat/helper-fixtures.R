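# Small fixture builders used across test files.

hr_record <- function(minutes, values, subject = "s1", ...) {
  vital_record(subject,
               c(list(hr = data.frame(time_s = minutes * 60, value = values)),
                 list(...)))
}

# a random HR series whose suprathreshold pattern stresses the clusterer
random_hr_series <- function(n, p_supra = 0.1, gappy = TRUE) {
  gaps <- if (gappy) sample(c(rep(1, 8), 2, 5, 20, 35, 45), n, replace = TRUE)
  else rep(1, n)
  minutes <- cumsum(gaps)
  hr <- ifelse(runif(n) < p_supra, runif(n, 130, 180), runif(n, 60, 129))
  list(time_s = minutes * 60, hr = hr)
}

# a fully populated 30-min window on all six channels; slow oscillation +
# noise keeps every feature (incl. sample entropy) defined
full_window_record <- function(seed = 1, subject = "w1") {
  set.seed(seed)
  mins <- 0:29
  chans <- lapply(c(hr = 80, rr = 18, spo2 = 96, abpsys = 120,
                    abpdias = 60, abpmean = 80), function(mu)
    data.frame(time_s = mins * 60,
               value = mu + 1.5 * sin(2 * pi * mins / 8) + rnorm(30, 0, 0.3)))
  chans$spo2$value <- pmin(chans$spo2$value, 100)
  vital_record(subject, chans)
}

window_at <- function(t_start_s, window_min = 30) {
  list(t_start_s = t_start_s, t_end_s = t_start_s + window_min * 60)
}

# feature table of pure noise plus optional planted signal in mean_hr
noise_features <- function(n, seed = 1, signal = 0, labels = NULL) {
  set.seed(seed)
  labels <- labels %||% rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * 42), n, 42, dimnames = list(NULL, feature_names()))
  x[, "mean_hr"] <- x[, "mean_hr"] + signal * labels
  df <- cbind(data.frame(subject = sprintf("s%04d", seq_len(n))),
              as.data.frame(x))
  list(features = df, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
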