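cfg <- pipeline_config()

test_that("window mean/sd and slope match closed forms", {
  expect_equal(feat_mean_sd(c(60, 70, 80)), c(mean = 70, sd = 10))
  expect_equal(feat_mean_sd(rep(5, 4))[["sd"]], 0)
  expect_equal(feat_mean_sd(42), c(mean = 42, sd = NA_real_))
  expect_true(is.na(feat_mean_sd(numeric(0))[["mean"]]))

  t <- (0:29) * 60
  expect_equal(feat_slope(t, 60 + t / 60), 1.0)
  expect_equal(feat_slope(t, rep(7, 30)), 0)
  expect_true(is.na(feat_slope(60, 80)))
  expect_true(is.na(feat_slope(c(60, 60), c(80, 90))))
  set.seed(21)
  for (i in 1:10) {
    tt <- sort(runif(sample(3:20, 1), 0, 1800))
    vv <- rnorm(length(tt), 80, 5)
    expect_equal(feat_slope(tt, vv), oracle_slope(tt, vv), tolerance = 1e-10)
  }
})

test_that("spectral power matches the direct DFT oracle and honours coverage", {
  t <- (0:29) * 60
  expect_equal(feat_fft_power(t, rep(0, 30), 0), 0)
  # constant series: DC-only power
  expect_equal(feat_fft_power(t, rep(3, 30), 0), (30 * 3)^2)
  set.seed(22)
  for (i in 1:15) {
    v <- 80 + 5 * sin(2 * pi * (0:29) / sample(4:15, 1)) + rnorm(30)
    got <- feat_fft_power(t, v, 0)
    expect_equal(got, oracle_dft_power(v), tolerance = 1e-9)
  }
  # 19% coverage -> missing; 20% -> value
  expect_true(is.na(feat_fft_power(t[1:5], rnorm(5, 80), 0)))
  expect_false(is.na(feat_fft_power(t[seq(1, 30, 5)], rnorm(6, 80), 0)))
})

test_that("gap-free windows take the direct path: spline changes nothing", {
  set.seed(23)
  v <- rnorm(30, 80, 4)
  g <- interp_minute_grid((0:29) * 60, v, 0)
  expect_equal(g, v, tolerance = 1e-12)
  # with interior gaps the interpolant still passes through observed samples
  keep <- sort(sample(30, 18))
  g2 <- interp_minute_grid((keep - 1) * 60, v[keep], 0)
  expect_equal(g2[keep], v[keep], tolerance = 1e-8)
})

test_that("autocorrelation summary matches lagged-product oracle", {
  t <- (0:29) * 60
  expect_true(is.na(feat_autocorr(t, rep(5, 30), 0)))   # zero variance
  set.seed(24)
  for (i in 1:10) {
    v <- as.numeric(arima.sim(list(ar = 0.8), 30))
    expect_equal(feat_autocorr(t, v, 0), oracle_acf_sum(v, 10),
                 tolerance = 1e-10)
  }
  # independent noise at large N: summary near zero (Bartlett SE per lag
  # 1/sqrt(N); the 10-lag sum has SE sqrt(10/N))
  long <- as.numeric(arima.sim(list(), 3000))
  s <- oracle_acf_sum(long, 10)
  expect_lt(abs(s), 3 * sqrt(10 / 3000))
})

test_that("approximate and sample entropy match exhaustive template counting", {
  expect_equal(feat_apen(rep(4, 12)), 0)
  expect_equal(feat_sampen(rep(4, 12)), 0)
  x12 <- rep(c(1, -1), 6)
  expect_equal(feat_apen(x12, 2, 0.5), oracle_apen(x12, 2, 0.5),
               tolerance = 1e-12)
  set.seed(25)
  for (i in 1:12) {
    x <- rnorm(sample(10:60, 1))
    r <- 0.2 * sd(x)
    expect_equal(feat_apen(x, 2, r), oracle_apen(x, 2, r), tolerance = 1e-10)
    expect_equal(feat_sampen(x, 2, r), oracle_sampen(x, 2, r),
                 tolerance = 1e-10)
  }
  # too short, or no m+1 matches -> missing
  expect_true(is.na(feat_apen(c(1, 2, 3))))
  expect_true(is.na(feat_sampen(c(0, 10, -10, 20, -20, 40), 2, 0.1)))
})

test_that("template matching behaves monotonically in the tolerance", {
  # counting properties that must hold exactly: match counts grow with r,
  # and A <= B makes SampEn nonnegative whenever it is defined
  count_matches <- function(x, m, r) {
    n <- length(x) - m
    cnt <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) cnt <- cnt + 1L
    cnt
  }
  set.seed(26)
  for (i in 1:8) {
    x <- as.numeric(arima.sim(list(ar = 0.8), 40))
    r <- 0.2 * sd(x)
    expect_gte(count_matches(x, 2, 2 * r), count_matches(x, 2, r))
    expect_gte(count_matches(x, 3, 2 * r), count_matches(x, 3, r))
    se <- feat_sampen(x, 2, r)
    if (!is.na(se)) expect_gte(se, 0)
  }
})

test_that("entropies agree with an independent reference implementation", {
  skip_if_not_installed("pracma")
  set.seed(27)
  x <- rnorm(100)
  r <- 0.2 * sd(x)
  expect_equal(feat_apen(x, 2, r),
               pracma::approx_entropy(x, edim = 2, r = r),
               tolerance = 1e-8)
  expect_equal(feat_sampen(x, 2, r),
               pracma::sample_entropy(x, edim = 2, r = r, tau = 1),
               tolerance = 1e-8)
})

test_that("record density is the observed fraction of expected samples", {
  expect_equal(feat_density((0:29) * 60), 1.0)
  expect_equal(feat_density((0:14) * 60), 0.5)
  expect_equal(feat_density(numeric(0)), 0)
})

test_that("a full window populates all 42 slots deterministically", {
  rec <- full_window_record(31)
  fv <- featurize_window(rec, window_at(0), cfg)
  expect_length(fv, 42)
  expect_named(fv, feature_names())
  expect_equal(sum(is.na(fv)), 0)
  expect_true(all(fv[paste0("density_", c("hr", "rr", "spo2"))] == 1))
  expect_true(all(fv[c("sd_hr", "sd_rr", "sd_spo2")] >= 0))
  expect_true(all(fv[paste0("aes_", c("hr", "rr", "spo2"))] >= 0))
  expect_identical(fv, featurize_window(rec, window_at(0), cfg))
})

test_that("features are invariant to row shuffling and time translation", {
  rec <- full_window_record(32)
  fv <- featurize_window(rec, window_at(0), cfg)
  # shuffle input rows: the constructor re-sorts, features unchanged
  shuf <- lapply(rec$channels, function(ch) ch[sample(nrow(ch)), ])
  fv2 <- featurize_window(vital_record("w1", shuf), window_at(0), cfg)
  expect_equal(fv2, fv)
  # translate the whole record (and window) by 97 minutes
  trans <- lapply(rec$channels, function(ch)
    data.frame(time_s = ch$time_s + 97 * 60, value = ch$value))
  fv3 <- featurize_window(vital_record("w1", trans), window_at(97 * 60), cfg)
  expect_equal(fv3, fv, tolerance = 1e-9)
})

test_that("an absent spo2 channel blanks exactly the spo2 slots", {
  rec <- full_window_record(33)
  rec$channels$spo2 <- NULL
  fv <- featurize_window(rec, window_at(0), cfg)
  spo2_slots <- grep("spo2", feature_names(), value = TRUE)
  expect_length(spo2_slots, 12)
  expect_true(all(is.na(fv[spo2_slots])))
  expect_equal(sum(is.na(fv)), length(spo2_slots))
})

test_that("last-5/10-min features reduce to full-window values on 5/10-min windows", {
  rec <- full_window_record(34)
  w5 <- window_at(25 * 60, 5)
  cfg5 <- pipeline_config(window_min = 5)
  fv <- featurize_window(rec, w5, cfg5)
  expect_equal(fv[["last_5min_mean_hr"]], fv[["mean_hr"]])
  expect_equal(fv[["last_5min_reg_hr"]], fv[["reg_hr"]])
  cfg10 <- pipeline_config(window_min = 10)
  fv10 <- featurize_window(rec, window_at(20 * 60, 10), cfg10)
  expect_equal(fv10[["last_10min_mean_rr"]], fv10[["mean_rr"]])
  expect_equal(fv10[["last_10min_reg_rr"]], fv10[["reg_rr"]])
})
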