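#' Canonical feature names
#'
#' The 42 window predictors, in canonical column order: per-channel means
#' (all six channels), standard deviations and record densities (hr, rr,
#' spo2), first-order regression slopes (all six), total spectral power,
#' autocorrelation sums, approximate and sample entropies (hr, rr, spo2),
#' and last-5/last-10-minute means and slopes (hr, rr, spo2).
#'
#' @return Character vector of length 42.
#' @export
feature_names <- function() {
  c(paste0("mean_", c("abpdias", "abpmean", "abpsys", "hr", "rr", "spo2")),
    paste0("sd_", SPECTRAL_CHANNELS),
    paste0("reg_", c("abpdias", "abpmean", "abpsys", "hr", "rr", "spo2")),
    paste0("fft_", SPECTRAL_CHANNELS),
    paste0("acs_", SPECTRAL_CHANNELS),
    paste0("aes_", SPECTRAL_CHANNELS),
    paste0("ses_", SPECTRAL_CHANNELS),
    paste0("density_", SPECTRAL_CHANNELS),
    paste0("last_5min_mean_", SPECTRAL_CHANNELS),
    paste0("last_5min_reg_", SPECTRAL_CHANNELS),
    paste0("last_10min_mean_", SPECTRAL_CHANNELS),
    paste0("last_10min_reg_", SPECTRAL_CHANNELS))
}

#' Window mean and standard deviation
#'
#' Arithmetic mean (>= 1 sample) and sample (n-1) standard deviation
#' (>= 2 samples); `NA` when too few samples.
#'
#' @param values Numeric samples inside the window.
#' @return Named vector `c(mean = , sd = )`.
#' @export
feat_mean_sd <- function(values) {
  values <- values[is.finite(values)]
  c(mean = if (length(values) >= 1) mean(values) else NA_real_,
    sd = if (length(values) >= 2) stats::sd(values) else NA_real_)
}

#' First-order regression slope
#'
#' Ordinary-least-squares slope of value against time, reported per minute.
#' Requires at least two samples at distinct times.
#'
#' @param time_s Sample times, seconds.
#' @param values Sample values.
#' @return Slope in units per minute, or `NA`.
#' @export
feat_slope <- function(time_s, values) {
  ok <- is.finite(time_s) & is.finite(values)
  t <- time_s[ok] / 60; v <- values[ok]
  if (length(t) < 2 || length(unique(t)) < 2) return(NA_real_)
  tm <- t - mean(t)
  sum(tm * (v - mean(v))) / sum(tm^2)
}

#' Resample window samples onto the uniform 1-min grid
#'
#' Cubic-spline interpolation onto one grid point per nominal period across
#' the window. The spline never extrapolates: when the first/last observed
#' samples fall inside the window, the boundary grid points are anchored to
#' the nearest observed value before splining. Returns `NULL` when fewer
#' than `min_coverage` of the expected samples (or fewer than 4 samples)
#' are available.
#'
#' @param time_s,values Observed samples inside `[t_start, t_start +
#'   window_min * 60)`.
#' @param t_start Window start, seconds.
#' @param window_min Window length, minutes.
#' @param period_s Nominal sampling period, seconds.
#' @param min_coverage Minimum available fraction of expected samples.
#' @return Numeric vector of `window_min * 60 / period_s` grid values, or
#'   `NULL` when coverage is insufficient.
#' @export
interp_minute_grid <- function(time_s, values, t_start, window_min = 30,
                               period_s = 60, min_coverage = 0.20) {
  ok <- is.finite(time_s) & is.finite(values)
  t <- time_s[ok]; v <- values[ok]
  n_grid <- round(window_min * 60 / period_s)
  if (length(t) < max(4, ceiling(min_coverage * n_grid)) ||
      length(t) / n_grid < min_coverage) return(NULL)
  grid <- t_start + period_s * (seq_len(n_grid) - 1)
  # nearest-value extension at the edges, then cubic spline through samples
  if (min(t) > grid[1]) { t <- c(grid[1], t); v <- c(v[1], v) }
  if (max(t) < grid[n_grid]) { t <- c(t, grid[n_grid]); v <- c(v, v[length(v)]) }
  stats::spline(t, v, xout = grid, method = "fmm")$y
}

#' Total spectral power of a window
#'
#' The window samples are resampled onto the uniform 1-min grid by cubic
#' spline (see [interp_minute_grid()]); the unnormalized discrete Fourier
#' transform is taken with the mean retained, and the sum of squared
#' amplitudes over all bins with frequency between 0 and 1/120 Hz
#' (both ends included, DC included) is returned. Windows with less than
#' `min_coverage` of the expected samples yield `NA`.
#'
#' @inheritParams interp_minute_grid
#' @param fmax_hz Upper edge of the summed band, Hz.
#' @return Total power (sum of squared DFT amplitudes), or `NA`.
#' @export
feat_fft_power <- function(time_s, values, t_start = min(time_s),
                           window_min = 30, period_s = 60,
                           min_coverage = 0.20, fmax_hz = 1 / 120) {
  g <- interp_minute_grid(time_s, values, t_start, window_min, period_s,
                          min_coverage)
  if (is.null(g)) return(NA_real_)
  fft_band_power_(g, period_s, fmax_hz)
}

fft_band_power_ <- function(g, period_s, fmax_hz = 1 / 120) {
  N <- length(g)
  X <- stats::fft(g)
  freq <- (seq_len(N) - 1) / (N * period_s)
  sum(Mod(X[freq <= fmax_hz + 1e-12])^2)
}

#' Autocorrelation summary of a window
#'
#' Sum of the sample autocorrelation coefficients at lags 1 to `max_lag`
#' minutes, computed on the interpolated 1-min grid. `NA` when coverage is
#' below `min_coverage`, when fewer than `max_lag + 2` grid samples exist,
#' or when the grid series has zero variance.
#'
#' @inheritParams interp_minute_grid
#' @param max_lag Largest lag, in grid steps (minutes).
#' @return Sum of autocorrelations at lags `1:max_lag`, or `NA`.
#' @export
feat_autocorr <- function(time_s, values, t_start = min(time_s),
                          window_min = 30, period_s = 60,
                          min_coverage = 0.20, max_lag = 10) {
  g <- interp_minute_grid(time_s, values, t_start, window_min, period_s,
                          min_coverage)
  if (is.null(g) || length(g) < max_lag + 2 || stats::var(g) == 0)
    return(NA_real_)
  rho <- stats::acf(g, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf
  sum(rho[-1])
}

# Chebyshev distance matrix between all m-length templates of x,
# restricted to the first n_templates rows/columns.
template_dist_ <- function(x, m, n_templates) {
  D <- abs(outer(x, x, "-"))
  M <- D[seq_len(n_templates), seq_len(n_templates), drop = FALSE]
  if (m > 1) for (k in seq_len(m - 1))
    M <- pmax(M, D[seq_len(n_templates) + k, seq_len(n_templates) + k,
                   drop = FALSE])
  M
}

#' Approximate entropy
#'
#' Standard ApEn(m, r) with self-matches included: the difference of the
#' mean log template-match frequencies at pattern lengths `m` and `m + 1`,
#' with matching under the Chebyshev distance at tolerance `r`. A constant
#' series has ApEn 0. Requires at least `m + 2` samples.
#'
#' @param x Numeric series (typically the interpolated 1-min grid).
#' @param m Pattern length.
#' @param r Match tolerance, in the units of `x`. The conventional choice
#'   `0.2 * sd(x)` is the package default at featurization time.
#' @return ApEn value, or `NA` when the series is too short.
#' @export
feat_apen <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  N <- length(x)
  if (N < m + 2 || !is.finite(r)) return(NA_real_)
  phi <- function(mm) {
    n <- N - mm + 1
    M <- template_dist_(x, mm, n)
    mean(log(rowSums(M <= r) / n))
  }
  phi(m) - phi(m + 1)
}

#' Sample entropy
#'
#' Standard SampEn(m, r): with `B` the number of template pairs (distinct
#' indices, self-matches excluded) matching at length `m` and `A` the number
#' matching at length `m + 1`, SampEn = -log(A/B). Both counts run over the
#' first `N - m` templates. `NA` when `A` or `B` is zero (undefined) or the
#' series is too short.
#'
#' @inheritParams feat_apen
#' @return SampEn value, or `NA`.
#' @export
feat_sampen <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  N <- length(x)
  if (N < m + 2 || !is.finite(r)) return(NA_real_)
  n <- N - m
  Mm <- template_dist_(x, m, n)
  Mm1 <- template_dist_(x, m + 1, n)
  B <- (sum(Mm <= r) - n) / 2
  A <- (sum(Mm1 <= r) - n) / 2
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

#' Record density of a window
#'
#' Fraction of expected samples (at the nominal period) actually observed
#' in the window, clipped to `[0, 1]`.
#'
#' @param time_s Observed sample times inside the window.
#' @param window_min Window length, minutes.
#' @param period_s Nominal sampling period, seconds.
#' @return Fraction in `[0, 1]`.
#' @export
feat_density <- function(time_s, window_min = 30, period_s = 60) {
  expected <- window_min * 60 / period_s
  min(1, max(0, sum(is.finite(time_s)) / expected))
}

#' Compute the 42 predictors for one analysis window
#'
#' Assembles the full feature vector from one record and one window
#' `[t_start_s, t_end_s)`. Slots whose preconditions fail (absent channel,
#' coverage below the interpolation floor, zero variance, too few samples)
#' are explicit `NA`; nothing is imputed here.
#'
#' @param record A [vital_record()].
#' @param window One row of a window table, or any list with `t_start_s`
#'   and `t_end_s`.
#' @param cfg A [pipeline_config()].
#' @param m,r_factor Entropy parameters: pattern length and the tolerance
#'   as a fraction of the window grid's standard deviation.
#' @param acf_max_lag Largest autocorrelation lag, minutes.
#' @return Named numeric vector with the 42 entries of [feature_names()].
#' @export
featurize_window <- function(record, window, cfg = pipeline_config(),
                             m = 2, r_factor = 0.2, acf_max_lag = 10) {
  t0 <- window$t_start_s; t1 <- window$t_end_s
  period <- record$nominal_period_s
  out <- stats::setNames(rep(NA_real_, 42), feature_names())
  for (ch in CHANNELS) {
    samp <- record$channels[[ch]]
    if (is.null(samp)) next       # absent channel: all its slots stay NA
    i <- findInterval(c(t0 - 1e-9, t1 - 1e-9), samp$time_s)
    idx <- if (i[2] > i[1]) (i[1] + 1):i[2] else integer(0)
    t <- samp$time_s[idx]; v <- samp$value[idx]
    ms <- feat_mean_sd(v)
    out[paste0("mean_", ch)] <- ms[["mean"]]
    out[paste0("reg_", ch)] <- feat_slope(t, v)
    if (!(ch %in% SPECTRAL_CHANNELS)) next
    out[paste0("sd_", ch)] <- ms[["sd"]]
    out[paste0("density_", ch)] <- feat_density(t, cfg$window_min, period)
    for (sub in c(5, 10)) {
      keep <- t >= t1 - sub * 60
      out[sprintf("last_%dmin_mean_%s", sub, ch)] <-
        feat_mean_sd(v[keep])[["mean"]]
      out[sprintf("last_%dmin_reg_%s", sub, ch)] <- feat_slope(t[keep], v[keep])
    }
    g <- interp_minute_grid(t, v, t0, cfg$window_min, period, cfg$min_coverage)
    if (is.null(g)) next
    out[paste0("fft_", ch)] <- fft_band_power_(g, period)
    if (length(g) >= acf_max_lag + 2 && stats::var(g) > 0) {
      rho <- stats::acf(g, lag.max = acf_max_lag, plot = FALSE)$acf
      out[paste0("acs_", ch)] <- sum(rho[-1])
    }
    r <- r_factor * stats::sd(g)
    out[paste0("aes_", ch)] <- feat_apen(g, m, r)
    out[paste0("ses_", ch)] <- feat_sampen(g, m, r)
  }
  out
}

#' Featurize a table of analysis windows
#'
#' @param records Named list of [vital_record()] objects.
#' @param windows A window table ([case_windows()], [control_windows()]).
#' @inheritParams featurize_window
#' @return Data frame: the window metadata columns followed by the 42
#'   feature columns (`NA` = missing).
#' @export
featurize_windows <- function(records, windows, cfg = pipeline_config(), ...) {
  feats <- t(vapply(seq_len(nrow(windows)), function(i) {
    rec <- records[[windows$subject[i]]]
    if (is.null(rec)) return(stats::setNames(rep(NA_real_, 42), feature_names()))
    featurize_window(rec, windows[i, ], cfg, ...)
  }, numeric(42)))
  out <- cbind(as.data.frame(windows), as.data.frame(feats))
  rownames(out) <- NULL
  out
}
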