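# one shared small planted-drift cohort + model for the trajectory tests
cfg <- pipeline_config(n_folds = 4, rng_seed = 11)
sim <- sim_config(n_case_subjects = 6, n_control_subjects = 6, rng_seed = 77)
co <- simulate_cohort(sim)
eps <- detect_episodes_cohort(co$records, cfg)
d0 <- suppressMessages(lagged_dataset(co$records, eps, lag_min = 0, cfg = cfg))
bundle <- crossval_train(d0$features, d0$labels, "random_forest", cfg)

test_that("records shorter than the window yield an empty trajectory", {
  rec <- hr_record(0:28, rnorm(29, 80, 2))
  tr <- rolling_risk(rec, bundle, cfg)
  expect_equal(nrow(tr), 0)
  expect_s3_class(tr, "risk_trajectory")
})

test_that("the first window_min minutes carry no risk and scores lie in [0,1]", {
  rec <- co$records[["N001"]]
  tr <- rolling_risk(rec, bundle, cfg, minutes = 25:40)
  expect_true(all(tr$minute >= cfg$window_min))
  expect_true(all(tr$risk[is.finite(tr$risk)] >= 0 &
                    tr$risk[is.finite(tr$risk)] <= 1))
})

test_that("rolling risk at a case window's end equals pooled window scoring", {
  w <- d0$features[d0$features$label == "case", ][1, ]
  rec <- co$records[[w$subject]]
  ext <- record_extent(rec, "hr")
  m <- round((w$t_end_s - ext[1]) / 60)
  tr <- rolling_risk(rec, bundle, cfg, minutes = m)
  direct <- predict(bundle, w)
  expect_equal(tr$risk, unname(direct), tolerance = 1e-12)
})

test_that("lag-0 reproduces the group-1 design; lags shift case windows back", {
  cases0 <- case_windows(eps, co$records, group = 1, lag_min = 0, cfg = cfg)
  expect_equal(d0$features$t_end_s[d0$features$label == "case"],
               cases0$t_end_s)
  onsets <- vapply(cases0$episode_ref, function(id)
    as.numeric(sub(".*@", "", id)), numeric(1))
  expect_equal(unname(cases0$t_end_s), unname(onsets))
  cases30 <- case_windows(eps, co$records, group = 1, lag_min = 30, cfg = cfg)
  expect_equal(unname(cases30$t_end_s), unname(onsets) - 1800)
  # growing the lag can only lose cases (windows run off the data)
  n_at_lag <- vapply(c(0, 10, 20, 30), function(l)
    nrow(suppressMessages(
      case_windows(eps, co$records, group = 1, lag_min = l, cfg = cfg))),
    numeric(1))
  expect_true(all(diff(n_at_lag) <= 0))
})

test_that("lift is the risk over the mean baseline risk, scale-free", {
  expect_equal(compute_lift(rep(0.3, 5), rep(0.3, 10)), rep(1, 5))
  expect_equal(compute_lift(0.5, c(0.1, 0.3)), 2.5)
  expect_true(all(is.na(compute_lift(c(0.2, 0.4), rep(1e-9, 5)))))
  set.seed(12)
  for (i in 1:10) {
    r <- runif(20); b <- runif(30); c_scale <- runif(1, 0.1, 10)
    expect_equal(compute_lift(c_scale * r, c_scale * b), compute_lift(r, b),
                 tolerance = 1e-12)
  }
})

test_that("lift trajectories exist for eligible subjects and rise pre-onset", {
  lifted <- list()
  for (s in names(co$records)[co$is_case]) {
    lt <- suppressMessages(
      lift_trajectory(co$records[[s]], bundle, eps, cfg))
    if (!is.null(lt)) lifted[[s]] <- lt
  }
  expect_gte(length(lifted), 2)
  for (lt in lifted) {
    expect_true(all(lt$minute >= -180 & lt$minute <= -1))
    expect_equal(lt$lift, lt$risk / attr(lt, "baseline"), tolerance = 1e-12)
  }
  # group-mean lift in the final 30 min exceeds the baseline level
  final <- vapply(lifted, function(lt)
    mean(lt$lift[lt$minute > -30], na.rm = TRUE), numeric(1))
  expect_gt(mean(final), 1)
})

test_that("subjects without the 3-h baseline are excluded from lift", {
  rec <- co$records[[which(co$is_case)[1]]]
  # truncate the record so the pre-onset history is too short
  onset <- min(eps$start_s[eps$subject == rec$subject_id])
  short <- lapply(rec$channels, function(ch)
    ch[ch$time_s > onset - 4 * 3600, , drop = FALSE])
  rec_short <- vital_record(rec$subject_id, short)
  expect_message(
    out <- lift_trajectory(rec_short, bundle, eps, cfg),
    "insufficient baseline")
  expect_null(out)
})

test_that("trajectory aggregation matches hand-computed averages", {
  t1 <- structure(data.frame(subject = "a", minute = 1:3, time_s = 1:3 * 60,
                             risk = c(0.2, 0.2, 0.2)),
                  class = c("risk_trajectory", "data.frame"))
  t2 <- t1; t2$subject <- "b"; t2$risk <- c(0.4, 0.4, 0.4)
  t3 <- t1; t3$subject <- "c"; t3$risk <- c(0.6, 0.3, NA)
  agg2 <- aggregate_trajectories(list(t1, t2), value = "risk")
  expect_equal(agg2$mean, rep(0.3, 3))
  agg_same <- aggregate_trajectories(list(t1, t1), value = "risk")
  expect_equal(agg_same$ci_lo, agg_same$ci_hi)   # zero-width band
  agg3 <- aggregate_trajectories(list(t1, t2, t3), value = "risk")
  expect_equal(agg3$mean, c(mean(c(0.2, 0.4, 0.6)), mean(c(0.2, 0.4, 0.3)),
                            mean(c(0.2, 0.4))))
  expect_equal(agg3$n, c(3, 3, 2))
})

test_that("risk stays flat on stationary records and rises before onsets", {
  slopes <- numeric(0)
  for (s in names(co$records)[!co$is_case][1:4]) {
    tr <- rolling_risk(co$records[[s]], bundle, cfg, minutes = 30:120)
    ok <- is.finite(tr$risk)
    slopes <- c(slopes, unname(coef(lm(tr$risk[ok] ~ tr$minute[ok]))[2]))
  }
  # no systematic trend across stationary subjects
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)) + 1e-3)

  rises <- numeric(0)
  for (s in names(co$records)[co$is_case]) {
    onset <- min(eps$start_s[eps$subject == s])
    ext <- record_extent(co$records[[s]], "hr")
    om <- round((onset - ext[1]) / 60)
    tr <- rolling_risk(co$records[[s]], bundle, cfg,
                       minutes = c((om - 209):(om - 180), (om - 29):om))
    late <- mean(tr$risk[tr$minute > om - 30], na.rm = TRUE)
    early <- mean(tr$risk[tr$minute <= om - 180], na.rm = TRUE)
    rises <- c(rises, late - early)
  }
  expect_gt(mean(rises), 0)
  expect_true(mean(rises > 0) >= 0.5)
})
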