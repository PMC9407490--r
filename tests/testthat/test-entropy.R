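test_that("perfectly regular alternation has zero sample entropy", {
  x <- rep(c(1, 2), 50)
  expect_equal(as.numeric(sample_entropy(x, m = 2, r = 0.1)), 0)
})

test_that("sample entropy reproduces the enumeration oracle on a worked example", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3)
  cnt <- sample_entropy_counts(x, m = 2, r = 1.0)
  expect_identical(c(cnt$A, cnt$B), c(1, 6))
  expect_equal(suppressWarnings(as.numeric(sample_entropy(x, 2, 1.0))),
               -log(1 / 6))
})

test_that("fast estimator equals brute-force pair counting exactly", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(40:200, 1)
    x <- rnorm(n)
    m <- sample(2:3, 1)
    r <- sample(c(0.10, 0.15, 0.20), 1) * sd(x)
    fast <- sample_entropy_counts(x, m, r)
    slow <- sampen_oracle(x, m, r)
    expect_identical(fast$A, as.numeric(slow$A))
    expect_identical(fast$B, as.numeric(slow$B))
  }
})

test_that("sample entropy is non-increasing in the tolerance", {
  set.seed(8)
  x <- rnorm(300)
  vals <- vapply(c(0.1, 0.2, 0.4, 0.8), function(r)
    as.numeric(sample_entropy(x, 2, r)), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("undefined sample entropy raises classed errors", {
  # widely separated values: no m-matches at tiny tolerance
  set.seed(2)
  x <- cumsum(runif(60, 1, 2))
  expect_error(sample_entropy(x, 2, 1e-6), class = "thermentropy_no_m_matches")
  expect_error(sample_entropy(rnorm(4), 2, 0.1), "too short")
  expect_warning(try(sample_entropy(rnorm(15), 2, 0.5), silent = TRUE),
                 "stability guideline")
})

test_that("sorted input has zero bubble entropy", {
  expect_equal(as.numeric(bubble_entropy(1:50, m = 3)), 0)
  expect_equal(as.numeric(bubble_entropy(seq(0.1, 5, by = 0.1), m = 5)), 0)
})

test_that("bubble entropy equals the swap-count enumeration oracle", {
  y <- c(2, 4, 1, 5, 3, 6, 2, 5, 1, 4)
  expect_equal(as.numeric(bubble_entropy(y, 2)), bubble_entropy_oracle(y, 2),
               tolerance = 1e-12)
  set.seed(33)
  for (rep in 1:20) {
    x <- rnorm(sample(20:60, 1))
    m <- sample(2:4, 1)
    expect_equal(as.numeric(bubble_entropy(x, m)), bubble_entropy_oracle(x, m),
                 tolerance = 1e-12)
  }
})

test_that("bubble entropy is invariant under positive affine transforms", {
  set.seed(12)
  for (rep in 1:20) {
    x <- rnorm(80)
    a <- runif(1, 0.1, 10)
    b <- runif(1, -5, 5)
    expect_identical(as.numeric(bubble_entropy(x, 3)),
                     as.numeric(bubble_entropy(a * x + b, 3)))
  }
})

test_that("swap-count Renyi entropies respect the combinatorial bound", {
  set.seed(4)
  for (m in 2:6) {
    x <- rnorm(500)
    h <- attributes(bubble_entropy(x, m))
    expect_lte(h$H_m, log(m * (m - 1) / 2 + 1))
    expect_lte(h$H_m1, log((m + 1) * m / 2 + 1))
  }
})

test_that("coarse-graining is the identity at scale 1", {
  x <- rnorm(500)
  expect_identical(coarse_grain(x, 1), x)
})

test_that("Butterworth coarse-graining attenuates the stopband and passes the passband", {
  t <- 0:4999
  hi <- sin(2 * pi * 0.4 * t)        # 0.4 cycles/min, far above cutoff 0.1
  lo <- sin(2 * pi * 0.01 * t)       # well inside the passband
  hi_f <- coarse_grain(hi, 5, decimate = FALSE)
  lo_f <- coarse_grain(lo, 5, decimate = FALSE)
  mid <- 1000:4000                   # avoid edge transients
  expect_lt(max(abs(hi_f[mid])), 0.02)
  expect_gt(max(abs(lo_f[mid])), 0.98)
  expect_equal(length(coarse_grain(rnorm(1000), 4)), 250)
})

test_that("refined multiscale refuses raw input and matches scale-1 definition", {
  expect_error(refined_multiscale(rnorm(500), "sampen"), "analysis_segment")
  set.seed(9)
  x <- rnorm(1200)
  seg <- segment_from_values(x)
  curve <- suppressWarnings(refined_multiscale(seg, "sampen", m = 2,
                                               r_frac = 0.15, tau_max = 5))
  direct <- as.numeric(sample_entropy(seg$values, 2, 0.15 * sd(seg$values)))
  expect_equal(curve$value[curve$scale == 1], direct)
  expect_equal(curve$scale, 1:5)
})

test_that("white-noise refined multiscale stays approximately scale-free", {
  set.seed(14)
  x <- rnorm(4000)
  curve <- suppressWarnings(
    refined_multiscale(segment_from_values(x), "sampen", m = 2,
                       r_frac = 0.15, tau_max = 10))
  v1 <- curve$value[curve$scale == 1]
  dev <- abs(curve$value[curve$defined] - v1)
  expect_lt(max(dev, na.rm = TRUE), 0.3)
})

test_that("control-group curves increase over scales on balance", {
  ts <- simulate_subject(subject_sim_spec(seed = 300))
  seg <- prepare_segment(ts)
  curve <- refined_multiscale(seg, "sampen")
  v <- curve$value[curve$defined]
  expect_gt(mean(diff(v) > 0), 0.5)
  expect_gt(v[length(v)], v[1])
})

test_that("quantization at logger resolution barely moves the entropy", {
  # series with SD comfortably above the 11-bit step
  set.seed(18)
  x <- as.numeric(arima.sim(list(ar = 0.9), 2000)) * 0.5
  xq <- round(x / 0.0625) * 0.0625
  h <- as.numeric(sample_entropy(x, 3, 0.15 * sd(x)))
  hq <- as.numeric(sample_entropy(xq, 3, 0.15 * sd(xq)))
  expect_lt(abs(h - hq), 0.1)
})

test_that("undefined scales are flagged rather than dropped", {
  set.seed(6)
  x <- cumsum(runif(1500, 0.5, 1))       # monotone: B > 0 impossible
  seg <- segment_from_values(x)
  curve <- suppressWarnings(refined_multiscale(seg, "sampen", tau_max = 4))
  expect_equal(nrow(curve), 4)
  expect_true(all(!curve$defined | is.finite(curve$value)))
})
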