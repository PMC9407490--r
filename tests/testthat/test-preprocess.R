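test_that("constant series yields no anomalies", {
  expect_length(detect_anomalies(rep(35, 400)), 0)
})

test_that("anomaly false-positive rate on AR(1) noise stays under 1%", {
  set.seed(21)
  rates <- replicate(10, {
    x <- as.numeric(arima.sim(list(ar = 0.6), 1500))
    length(detect_anomalies(x, window = 120, z_threshold = 4)) / 1500
  })
  expect_lt(mean(rates), 0.01)
})

test_that("anomaly clusters recover injected on/off transients", {
  hits <- 0
  for (s in 1:10) {
    ts <- simulate_subject(subject_sim_spec(length = 3000, seed = s))
    on <- 150; off <- 2880
    ts2 <- inject_wear_artifacts(ts, on, off, seed = s + 1000)
    an <- detect_anomalies(ts2)
    near_on <- any(abs(an - on) <= 30)
    near_off <- any(abs(an - off) <= 30)
    if (near_on && near_off) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("active-segment arithmetic follows the guard rule", {
  # two clusters; segment runs from after the on cluster to guard minutes
  # before the off cluster
  seg <- detect_active_segment(4000, c(10, 12, 14, 2900, 2903),
                               cluster_gap = 30, guard = 30)
  expect_equal(unname(seg["start"]), 15)
  expect_equal(unname(seg["end"]), 2870)
  expect_error(detect_active_segment(4000, c(10, 12, 14), guard = 30),
               "off cluster")
  expect_error(detect_active_segment(4000, c(3900, 3903), guard = 30),
               "on cluster")
})

test_that("recovered segments stay inside the true worn interval", {
  inside <- within30 <- 0
  for (s in 1:20) {
    ts <- simulate_subject(subject_sim_spec(length = 3000, seed = s))
    on <- 150; off <- 2880
    ts2 <- inject_wear_artifacts(ts, on, off, seed = s + 500)
    seg <- tryCatch(detect_active_segment(ts2, detect_anomalies(ts2)),
                    error = function(e) NULL)
    if (is.null(seg)) next
    if (seg["start"] >= on && seg["end"] <= off) inside <- inside + 1
    if (abs(seg["start"] - on) <= 30 && abs(seg["end"] - off) <= 30)
      within30 <- within30 + 1
  }
  expect_gte(inside, 19)
  expect_gte(within30, 19)
})

test_that("ADF test matches its reference implementation on a frozen series", {
  set.seed(42)
  x <- as.numeric(arima.sim(list(ar = 0.5), 500))
  # statsmodels.tsa.stattools.adfuller(x, maxlag = 7, autolag = None)
  expect_equal(adf_test(x, "c", lags = 7)$statistic, -7.272512, tolerance = 1e-5)
  expect_equal(adf_test(x, "ct", lags = 7)$statistic, -7.260514, tolerance = 1e-5)
})

test_that("ADF distinguishes white noise from a random walk", {
  set.seed(7)
  wn_reject <- mean(replicate(60, adf_test(rnorm(2000))$pvalue < 0.05))
  rw_accept <- mean(replicate(60, adf_test(cumsum(rnorm(2000)))$pvalue > 0.05))
  expect_gte(wn_reject, 0.99)
  expect_gte(rw_accept, 0.90)
  expect_error(adf_test(rep(1, 100)), "constant")
})

test_that("linear detrending removes a line exactly and is idempotent", {
  t <- 0:499
  res <- detrend_series(2 + 0.01 * t, "linear")
  expect_lt(max(abs(res$values)), 1e-9)
  x <- rnorm(300)
  once <- detrend_series(x, "linear")$values
  twice <- detrend_series(once, "linear")$values
  expect_lt(max(abs(once - twice)), 1e-9)
  expect_lt(abs(mean(once)), 1e-10)
})

test_that("cosinor fit recovers amplitude and leaves noise-level residuals", {
  set.seed(5)
  t <- 0:2799
  x <- 35 + 1.5 * cos(2 * pi * t / 1440 + 1) + rnorm(2800, sd = 0.05)
  res <- detrend_series(x, "cosinor")
  expect_lt(abs(res$amplitude - 1.5), 0.1)
  expect_lt(abs(res$series_sd - 0.05), 0.01)
  expect_lt(abs(mean(res$values)), 1e-10)
  expect_error(detrend_series(rnorm(50), "cosinor"), "100")
})

test_that("prepare_segment trims, detrends and records its choices", {
  ts <- simulate_subject(subject_sim_spec(length = 3000, seed = 11))
  ts2 <- inject_wear_artifacts(ts, 150, 2880, seed = 12)
  seg <- prepare_segment(ts2)
  expect_s3_class(seg, "analysis_segment")
  expect_true(seg$source_range[1] >= 150 && seg$source_range[2] <= 2880)
  expect_lt(seg$adf_pvalue, 0.05)
  expect_lt(abs(mean(seg$values)), 1e-8)
  expect_true(seg$detrend_method %in% c("linear", "cosinor"))
})

test_that("prepare_segment rejects unit-root input and short segments", {
  set.seed(3)
  rw <- new_series_for_test(35 + cumsum(rnorm(2800, sd = 0.05)))
  expect_error(prepare_segment(rw), "non-stationary")
  short <- simulate_subject(subject_sim_spec(length = 600, seed = 2))
  expect_error(prepare_segment(short, min_length = 1200), "floor")
})

test_that("strong circadian component forces the cosinor fallback", {
  # smooth noise plus a dominant 24-h cosine: the linear residuals keep the
  # cycle and fail the ADF gate, the cosinor residuals pass it
  found <- FALSE
  for (s in 1:10) {
    ts <- simulate_subject(subject_sim_spec(circadian_amplitude = 3,
                                            length = 2800, seed = s))
    seg <- tryCatch(prepare_segment(ts), error = function(e) NULL)
    if (!is.null(seg) && seg$detrend_method == "cosinor") { found <- TRUE; break }
  }
  expect_true(found)
})
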