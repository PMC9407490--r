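test_that("Cohen's d handles the canonical cases", {
  expect_equal(cohen_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohen_d(c(0, 2), c(2, 4)), -sqrt(2), tolerance = 1e-12)
  expect_equal(cohen_d(c(0, 2), c(2, 4)), -cohen_d(c(2, 4), c(0, 2)))
  expect_error(cohen_d(c(1, 1), c(1, 1)), "pooled SD")
  # invariance under a common affine transform
  set.seed(1)
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(cohen_d(a, b), cohen_d(3 * a + 2, 3 * b + 2), tolerance = 1e-12)
})

test_that("Welch t matches the closed-form computation", {
  set.seed(2)
  a <- rnorm(15); b <- rnorm(11, 1)
  wt <- welch_t(a, b)
  se <- sqrt(var(a) / 15 + var(b) / 11)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 15)^2 / 14 + (var(b) / 11)^2 / 10)
  expect_equal(wt$t, t_hand, tolerance = 1e-10)
  expect_equal(wt$df, df_hand, tolerance = 1e-10)
  expect_equal(wt$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
  expect_true(wt$ci_low < wt$mean_difference & wt$mean_difference < wt$ci_high)
  same <- welch_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("Welch type-I error is calibrated at the nominal level", {
  set.seed(3)
  n_rep <- 10000
  a <- matrix(rnorm(n_rep * 15), n_rep)
  b <- matrix(rnorm(n_rep * 11), n_rep)
  va <- apply(a, 1, var) / 15; vb <- apply(b, 1, var) / 11
  tt <- (rowMeans(a) - rowMeans(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / 14 + vb^2 / 10)
  p <- 2 * pt(-abs(tt), df)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
  # p-values approximately uniform under the null
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("effect curve flags scales and carries both statistics", {
  set.seed(4)
  cc <- cohort_curves(10, 8, effect_scales = 15:25, effect = 0.6, sd = 0.15)
  ec <- effect_curve(cc$curves, cc$labels)
  expect_equal(nrow(ec), 25)
  expect_true(all(c("d", "p", "ci_low", "ci_high", "significant") %in% names(ec)))
  expect_gt(mean(ec$d[ec$scale >= 15]), mean(ec$d[ec$scale < 15]))
  expect_equal(sign(ec$d), sign(ec$mean_difference))
})

test_that("null effect curves stay inside the false-positive budget", {
  set.seed(5)
  flagged <- replicate(20, {
    cc <- cohort_curves(15, 11, sd = 0.15)
    sum(effect_curve(cc$curves, cc$labels)$significant, na.rm = TRUE)
  })
  expect_lte(mean(flagged), 2)
})

test_that("analytic power behaves correctly at the boundaries", {
  expect_equal(power_two_sample_t(0, 10, 10, 0.05, "one_sided"), 0.05,
               tolerance = 1e-12)
  # monotone in |d| and in n
  ds <- seq(0, 2, by = 0.25)
  pw <- vapply(ds, power_two_sample_t, numeric(1), n1 = 10, n2 = 10)
  expect_true(all(diff(pw) > 0))
  ns <- c(4, 8, 16, 32)
  pw_n <- vapply(ns, function(n) power_two_sample_t(0.8, n, n), numeric(1))
  expect_true(all(diff(pw_n) > 0))
})

test_that("analytic power agrees with Monte-Carlo simulation", {
  set.seed(6)
  d <- 0.9; n1 <- 12; n2 <- 18; alpha <- 0.05
  n_rep <- 40000
  a <- matrix(rnorm(n_rep * n1, mean = d), n_rep)
  b <- matrix(rnorm(n_rep * n2), n_rep)
  sp <- sqrt(((n1 - 1) * apply(a, 1, var) + (n2 - 1) * apply(b, 1, var)) /
               (n1 + n2 - 2))
  tt <- (rowMeans(a) - rowMeans(b)) / (sp * sqrt(1 / n1 + 1 / n2))
  mc <- mean(tt > qt(1 - alpha, n1 + n2 - 2))
  expect_lt(abs(power_two_sample_t(d, n1, n2, alpha, "one_sided") - mc), 0.01)
})

test_that("Welch PSD satisfies Parseval and localizes a sinusoid", {
  set.seed(7)
  x <- rnorm(4096)
  psd <- welch_psd(x, segment_length = 512)
  expect_equal(sum(psd$power) / 512, var(x), tolerance = 0.1)
  t <- 0:4095
  s <- sin(2 * pi * 0.2 * t) + rnorm(4096, sd = 0.1)
  ps <- welch_psd(s, segment_length = 512)
  expect_equal(ps$frequency[which.max(ps$power)], 0.2, tolerance = 0.01)
})

test_that("band-power contrast detects a constructed spectral excess", {
  set.seed(8)
  base <- replicate(6, rnorm(2000), simplify = FALSE)
  plus <- lapply(base, function(x)
    x + 0.8 * sin(2 * pi * (seq_along(x)) / 5))    # 5-min period inside band
  bp <- band_power_contrast(base, plus, band_minutes = c(2.4, 9.1))
  expect_gt(bp$ratio, 1.3)
  ident <- band_power_contrast(base, base)
  expect_equal(ident$ratio, 1)
  expect_error(band_power_contrast(base, plus, band_minutes = c(1.2, 1.9)),
               "resolvable")
})

test_that("white-noise groups give near-unit band-power ratios", {
  set.seed(9)
  ratios <- replicate(20, {
    a <- replicate(5, rnorm(1500), simplify = FALSE)
    b <- replicate(5, rnorm(1500), simplify = FALSE)
    band_power_contrast(a, b)$ratio
  })
  expect_true(all(ratios > 0.8 & ratios < 1.25))
})
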