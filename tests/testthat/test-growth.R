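test_that("noiseless metrics match the planted logistic parameters", {
  ## single-phase logistic: log-OD slope in the exponential window = r
  m1 <- growthMetrics(simulateGrowthCurve(lag_min = 0, max_rate_per_h = 0.4,
                                          single_phase = TRUE,
                                          t_max_min = 1500))
  expect_equal(m1$max_rate_per_h, 0.4, tolerance = 0.02)

  ## two-phase round trip: planted lag 200 recovered within 10 min
  m2 <- growthMetrics(simulateGrowthCurve(lag_min = 200,
                                          max_rate_per_h = 0.35,
                                          dip_time_min = 120, r1_per_h = 3))
  expect_equal(m2$lag_min, 200, tolerance = 10 / 200)
  expect_equal(m2$max_rate_per_h, 0.35, tolerance = 0.02)
  expect_true(m2$diauxic_survived)
  expect_false(is.na(m2$diauxic_shift_min))

  ## flat curve flags no growth
  flat <- data.frame(time_min = seq(0, 500, 10), od600 = 0.05)
  expect_true(growthMetrics(flat)$no_growth)

  ## non-survivor: OD stays at the dip level
  cv <- simulateGrowthCurve(survive_diauxic = FALSE, dip_time_min = 120,
                            r1_per_h = 3)
  expect_lte(max(cv$od600[cv$time_min > 160]),
             cv$od600[cv$time_min == 160] + 1e-9)
  m3 <- growthMetrics(cv)
  expect_false(m3$diauxic_survived)
})

test_that("metrics are invariant to uniform OD scaling and monotone in lag", {
  cv <- simulateGrowthCurve(lag_min = 300, max_rate_per_h = 0.3,
                            dip_time_min = 120, r1_per_h = 3)
  cv2 <- cv
  cv2$od600 <- cv2$od600 * 4.2
  a <- growthMetrics(cv)
  b <- growthMetrics(cv2)
  expect_equal(a$lag_min, b$lag_min, tolerance = 1e-8)
  expect_equal(a$max_rate_per_h, b$max_rate_per_h, tolerance = 1e-8)

  lags <- vapply(c(200, 300, 450, 700), function(L)
    growthMetrics(simulateGrowthCurve(lag_min = L, max_rate_per_h = 0.3,
                                      dip_time_min = 120,
                                      r1_per_h = 3))$lag_min, numeric(1))
  expect_true(all(diff(lags) > 0))
})

test_that("noisy two-phase round trips recover lag and rate", {
  lagE <- numeric(0); rateE <- numeric(0)
  for (s in 1:40) {
    cv <- simulateGrowthCurve(lag_min = 300 + 20 * (s %% 4),
                              max_rate_per_h = 0.3 + 0.02 * (s %% 3),
                              dip_time_min = 120, r1_per_h = 3,
                              noise_sd = 0.005, seed = s)
    tr <- attr(cv, "truth")
    m <- growthMetrics(cv)
    lagE <- c(lagE, m$lag_min / tr$lag_min - 1)
    rateE <- c(rateE, m$max_rate_per_h / tr$max_rate_per_h - 1)
  }
  expect_lt(mean(abs(lagE)), 0.10)
  expect_lt(mean(abs(rateE)), 0.05)
})

test_that("group assignment follows the screen's lag and survival rules", {
  wt <- list(lag_min = 100, diauxic_survived = TRUE)
  mk <- function(lag, surv = TRUE) list(lag_min = lag,
                                        diauxic_survived = surv)
  expect_equal(assignGroup(mk(115), wt, mild_severe_cutoff_min = 240), 1)
  expect_equal(assignGroup(mk(121), wt, mild_severe_cutoff_min = 240), 2)
  expect_equal(assignGroup(mk(700), wt, mild_severe_cutoff_min = 240), 3)
  expect_equal(assignGroup(mk(700, surv = FALSE), wt,
                           mild_severe_cutoff_min = 240), 4)
  expect_error(assignGroup(mk(700), list(lag_min = NA)), "input error")
})

test_that("late collection is scheduled at the first 90% WT-OD crossing", {
  cv <- data.frame(time_min = seq(0, 3000, 10))
  cv$od600 <- pmin(0.001 * cv$time_min / 2.4, 1.2)
  out <- scheduleLateCollection(cv, wt_od_24h = 1.0)
  expect_equal(out, cv$time_min[which(cv$od600 >= 0.9)[1]] / 60)
  ## never reached
  expect_true(is.na(scheduleLateCollection(
    data.frame(time_min = seq(0, 100, 10), od600 = 0.1), 1.0)))
  ## a WT-like curve reaches 90% of its own 24 h OD by 24 h
  wtc <- simulateGrowthCurve(lag_min = 200, max_rate_per_h = 0.35,
                             dip_time_min = 120, r1_per_h = 3)
  od24 <- wtc$od600[wtc$time_min == 1440]
  expect_lte(scheduleLateCollection(wtc, od24), 24)
})
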