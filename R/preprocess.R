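#' Detect autoregressive anomalies in a temperature series
#'
#' Flags samples whose one-step-ahead prediction error under a rolling AR(1)
#' fit is an outlier: for each time point the AR(1) model (intercept + lag-1
#' slope) is fit by OLS on the preceding `window` samples, and the
#' standardized residual of the new sample is compared with `z_threshold`.
#' Sensor mounting/removal produces abrupt departures from body-temperature
#' autoregression and shows up as anomaly clusters near the on and off times.
#'
#' @param series A `temperature_series` tibble or numeric vector.
#' @param window Rolling-fit window length, samples (>= 10).
#' @param z_threshold Absolute standardized-residual threshold; the default 4
#'   keeps the false-positive rate under 1% on plain AR(1) input.
#' @return Integer vector of anomaly indices (1-based); may be empty.
#' @export
detect_anomalies <- function(series, window = 120, z_threshold = 4) {
  x <- series_values(series)
  n <- length(x)
  if (window < 10) abort("`window` must be at least 10 samples")
  if (n <= window) abort("series shorter than the rolling window")
  # rolling OLS of x_s on x_{s-1} over the preceding window, via cumulative
  # sums over the lag/lead pairs (x_j, x_{j+1})
  u <- x[-n]                       # lag
  v <- x[-1]                       # lead
  cs <- function(w) c(0, cumsum(w))
  Su <- cs(u); Sv <- cs(v); Suu <- cs(u^2); Svv <- cs(v^2); Suv <- cs(u * v)
  m <- window - 1                  # pairs fully inside each window
  t_idx <- seq(window + 1, n)
  hi <- t_idx - 2                  # last pair index in the window
  lo <- t_idx - window             # first pair index
  su <- Su[hi + 1] - Su[lo]; sv <- Sv[hi + 1] - Sv[lo]
  suu <- Suu[hi + 1] - Suu[lo]; svv <- Svv[hi + 1] - Svv[lo]
  suv <- Suv[hi + 1] - Suv[lo]
  vx <- (suu - su^2 / m) / (m - 1)
  cxy <- (suv - su * sv / m) / (m - 1)
  phi <- ifelse(vx < 1e-12, 0, cxy / vx)
  a <- sv / m - phi * su / m
  # residual variance of the window fit
  sse <- pmax(svv - sv^2 / m - phi * (suv - su * sv / m), 0)
  s <- sqrt(sse / (m - 1))
  s[vx < 1e-12] <- 0
  e <- x[t_idx] - (a + phi * x[t_idx - 1])
  z <- abs(e) / pmax(s, 1e-9)
  t_idx[is.finite(z) & z > z_threshold]
}

series_values <- function(series) {
  if (is.numeric(series)) return(as.numeric(series))
  if (!is.null(series[["temperature"]])) return(series$temperature)
  abort("expected a numeric vector or a temperature_series tibble")
}

# Split sorted anomaly indices into clusters with inter-anomaly gaps <= gap.
cluster_indices <- function(idx, gap) {
  if (length(idx) == 0) return(list())
  idx <- sort(idx)
  grp <- cumsum(c(1, diff(idx) > gap))
  unname(split(idx, grp))
}

#' Locate the worn (active) segment from anomaly clusters
#'
#' The active section runs from just after the rightmost anomaly of the
#' mounting ("on") cluster to `guard` minutes before the first anomaly of the
#' removal ("off") cluster.  The on cluster must lie in the first half of the
#' series and the off cluster in the second half.
#'
#' @param series A `temperature_series` or numeric vector (only its length is
#'   used).
#' @param anomalies Anomaly indices from [detect_anomalies()].
#' @param cluster_gap Maximum within-cluster gap between anomalies, minutes.
#' @param guard Safety margin before the off cluster, minutes.
#' @return Named integer vector `c(start, end)`, 1-based inclusive bounds.
#' @export
detect_active_segment <- function(series, anomalies, cluster_gap = 30,
                                  guard = 30) {
  n <- if (is.numeric(series) && length(series) == 1) series
       else length(series_values(series))
  cl <- cluster_indices(anomalies, cluster_gap)
  half <- n / 2
  on_cl <- Filter(function(c) max(c) <= half, cl)
  off_cl <- Filter(function(c) min(c) > half, cl)
  if (length(on_cl) == 0)
    abort("on cluster not found: trim the series start manually")
  if (length(off_cl) == 0)
    abort("off cluster not found: trim the series end manually")
  start <- max(on_cl[[1]]) + 1L
  end <- as.integer(min(off_cl[[length(off_cl)]]) - guard)
  if (start >= end)
    abort("active segment empty: anomaly clusters overlap after guarding")
  c(start = start, end = end)
}

# Dickey-Fuller t-statistic finite-sample quantiles (constant-only and
# constant+trend response regressions), interpolated over sample size and
# probability.  Values are the classic finite-sample tables used by standard
# ADF implementations.
.adf_table_n <- c(25, 50, 100, 250, 500, 1e5)
.adf_table_p <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
.adf_table_c <- rbind(
  c(-3.75, -3.58, -3.51, -3.46, -3.44, -3.43),
  c(-3.33, -3.22, -3.17, -3.14, -3.13, -3.12),
  c(-3.00, -2.93, -2.89, -2.88, -2.87, -2.86),
  c(-2.63, -2.60, -2.58, -2.57, -2.57, -2.57),
  c(-0.37, -0.40, -0.42, -0.42, -0.43, -0.44),
  c( 0.00, -0.03, -0.05, -0.06, -0.07, -0.07),
  c( 0.34,  0.29,  0.26,  0.24,  0.24,  0.23),
  c( 0.72,  0.66,  0.63,  0.62,  0.61,  0.60))
.adf_table_ct <- rbind(
  c(-4.38, -4.15, -4.04, -3.99, -3.98, -3.96),
  c(-3.95, -3.80, -3.73, -3.69, -3.68, -3.66),
  c(-3.60, -3.50, -3.45, -3.43, -3.42, -3.41),
  c(-3.24, -3.18, -3.15, -3.13, -3.13, -3.12),
  c(-1.14, -1.19, -1.22, -1.23, -1.24, -1.25),
  c(-0.80, -0.87, -0.90, -0.92, -0.93, -0.94),
  c(-0.50, -0.58, -0.62, -0.64, -0.65, -0.66),
  c(-0.15, -0.24, -0.28, -0.31, -0.32, -0.33))

#' Augmented Dickey-Fuller unit-root test
#'
#' OLS regression of the first difference on the lagged level, `lags` lagged
#' differences, and a constant (`regression = "c"`) or constant plus linear
#' trend (`"ct"`).  The t-statistic of the lagged-level coefficient is
#' converted to a p-value by two-way interpolation of the finite-sample
#' Dickey-Fuller tables; p-values beyond the tabulated range are clamped to
#' `[0.01, 0.99]`.  Low p-values reject the unit root, i.e. favour
#' stationarity.
#'
#' @param values Numeric series, length >= 50.
#' @param regression `"c"` (constant) or `"ct"` (constant + trend).
#' @param lags Number of lagged differences (default 5).  For 1-min
#'   physiological series the short-run dynamics the augmentation must
#'   absorb live within a few minutes; long Schwert-style lag lengths
#'   (`(n-1)^(1/3)` = 14 at n = 2800) sacrifice most of the test's power
#'   against smooth stationary alternatives.
#' @return List with `statistic`, `pvalue`, `lags`, `regression`.
#' @export
adf_test <- function(values, regression = c("c", "ct"), lags = 5) {
  regression <- match.arg(regression)
  x <- as.numeric(values)
  n <- length(x)
  if (n < 50) abort("ADF test needs at least 50 samples")
  if (sd(x) < 1e-12) abort("ADF test undefined for a constant series")
  k <- lags + 1
  dx <- diff(x)
  z <- embed(dx, k)          # columns: dx_t, dx_{t-1}, ..., dx_{t-lags}
  dy <- z[, 1]
  ylag <- x[k:(n - 1)]
  X <- if (lags > 0) cbind(ylag, z[, -1, drop = FALSE]) else cbind(ylag)
  if (regression == "ct") X <- cbind(X, trend = seq_along(dy))
  fit <- lm(dy ~ X)
  stat <- summary(fit)$coefficients["Xylag", "t value"]
  tab <- if (regression == "c") .adf_table_c else .adf_table_ct
  # quantile curve at this sample size, then invert stat -> probability
  qn <- apply(tab, 1, function(row) approx(.adf_table_n, row, n, rule = 2)$y)
  p <- approx(qn, .adf_table_p, stat, rule = 2)$y
  list(statistic = unname(stat), pvalue = unname(p),
       lags = lags, regression = regression)
}

#' Detrend a series linearly or by cosinor fit
#'
#' `linear` removes the OLS line in time; `cosinor` removes a least-squares
#' 24-hour cosine `M + A cos(2 pi t / period + phi)` (fit via its sin/cos
#' linearization), which eliminates the circadian rhythm while minimally
#' disturbing faster structure.  Residuals have mean zero by construction.
#'
#' @param values Numeric series.
#' @param method `"linear"` or `"cosinor"`.
#' @param period Cosinor period in minutes (24 h by default).
#' @return List with `values` (residuals), `method`, `series_sd`, and for
#'   cosinor the fitted `amplitude`, `acrophase` (radians) and `mesor`.
#' @export
detrend_series <- function(values, method = c("linear", "cosinor"),
                           period = 1440) {
  method <- match.arg(method)
  x <- as.numeric(values)
  n <- length(x)
  t <- seq_len(n) - 1
  if (method == "linear") {
    fit <- lm(x ~ t)
    res <- residuals(fit)
    out <- list(values = unname(res), method = method,
                series_sd = sd(res))
  } else {
    if (n < 100) abort("cosinor detrending needs at least 100 samples")
    cb <- cos(2 * pi * t / period)
    sb <- sin(2 * pi * t / period)
    fit <- tryCatch(lm(x ~ cb + sb),
                    error = function(e) abort("cosinor fit failed (singular design)"))
    beta <- coef(fit)
    res <- residuals(fit)
    out <- list(values = unname(res), method = method,
                series_sd = sd(res),
                mesor = unname(beta[1]),
                amplitude = sqrt(beta[2]^2 + beta[3]^2),
                acrophase = atan2(-beta[3], beta[2]))
  }
  out
}

new_analysis_segment <- function(values, source_range, detrend_method,
                                 adf_pvalue, subject_id = "subject",
                                 quantization_step = NA_real_) {
  structure(list(values = values,
                 source_range = source_range,
                 detrend_method = detrend_method,
                 adf_pvalue = adf_pvalue,
                 series_sd = sd(values),
                 subject_id = subject_id,
                 quantization_step = quantization_step),
            class = "analysis_segment")
}

#' @export
print.analysis_segment <- function(x, ...) {
  cat(sprintf(
    "<analysis_segment> %s: %d samples [%d, %d], detrend=%s, ADF p=%.3f, sd=%.3f\n",
    x$subject_id, length(x$values), x$source_range[1], x$source_range[2],
    x$detrend_method, x$adf_pvalue, x$series_sd))
  invisible(x)
}

#' Prepare a raw temperature series for entropy estimation
#'
#' Runs the fixed preprocessing order: detect autoregressive anomalies, trim
#' to the worn interval, detrend linearly and test stationarity with the
#' augmented Dickey-Fuller test; if the linear residuals fail the test, fall
#' back to cosinor detrending.  Series that remain non-stationary after both
#' methods, or whose trimmed length falls below the configured floor, are
#' rejected with a diagnostic error.  When no on/off anomaly clusters are
#' found (an artifact-free recording) the full series is used.
#'
#' @param series A `temperature_series` tibble.
#' @param window,z_threshold Anomaly-detector settings (see
#'   [detect_anomalies()]).
#' @param cluster_gap,guard Segmentation settings (see
#'   [detect_active_segment()]).
#' @param adf_alpha Stationarity threshold on the ADF p-value.
#' @param min_length Minimum admissible segment length, samples.
#' @return An `analysis_segment` (values are detrended, mean-zero).
#' @export
prepare_segment <- function(series, window = 120, z_threshold = 4,
                            cluster_gap = 30, guard = 30,
                            adf_alpha = 0.05, min_length = 1200) {
  x <- series_values(series)
  id <- attr(series, "subject_id") %||% "subject"
  seg_range <- tryCatch({
    an <- detect_anomalies(series, window = window, z_threshold = z_threshold)
    detect_active_segment(length(x), an, cluster_gap = cluster_gap,
                          guard = guard)
  }, error = function(e) c(start = 1L, end = length(x)))
  xr <- x[seq(seg_range[1], seg_range[2])]
  if (length(xr) < min_length)
    abort(sprintf("segment of %d samples for %s is below the %d-sample floor",
                  length(xr), id, min_length))
  for (method in c("linear", "cosinor")) {
    det <- detrend_series(xr, method)
    p <- adf_test(det$values)$pvalue
    if (p < adf_alpha) {
      return(new_analysis_segment(det$values, unname(seg_range), method, p,
                                  subject_id = id,
                                  quantization_step =
                                    attr(series, "quantization_step") %||% NA_real_))
    }
  }
  abort(sprintf(
    "series %s rejected: non-stationary after linear and cosinor detrending (ADF p >= %.2f)",
    id, adf_alpha))
}
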