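#' Specify a simulated temperature-logger subject
#'
#' Describes one subject's simulated 1-minute abdominal skin-temperature
#' recording: a circadian cosine riding on a baseline, short-range
#' autoregressive irregularity, an optional loss-of-complexity component, and
#' thermochron-style quantization.  Defaults emulate the summary statistics of
#' real logger recordings: median near 35.1 degC and a trimmed 95% range
#' (2.5th to 97.5th percentile, a proxy for circadian amplitude) near 3 degC,
#' recorded at 11-bit resolution (0.0625 degC steps) for roughly two days.
#'
#' The irregularity is a sum of three zero-mean Gaussian components spanning
#' the timescales the entropy analysis probes: a fast AR(1) component
#' (lag-1 coefficient `ar_coefficient`), a dominant medium component built
#' as a cascade of two identical AR(1) filters (a double-pole process whose
#' steep high-frequency rolloff mimics the smooth differentiable character
#' of vasomotor temperature fluctuations), and a slow mean-reverting AR(1)
#' drift.  Correlation times are `noise_timescales` minutes and variance
#' shares `noise_shares`.  This multi-timescale structure keeps the series
#' smoothly predictable at every coarse-graining scale, which is what makes
#' sample-entropy estimation stable on ~100-point decimated series.
#'
#' The `complexity_deficit` parameter injects the entropy signature
#' associated with pressure injury as a slowing of the medium (vasomotor)
#' band: its correlation time is stretched by `1 + complexity_deficit`,
#' making the band more sluggish and predictable while leaving its variance
#' untouched.  Total variance, and hence every amplitude
#' summary (median, IQR, trimmed range) and the entropy tolerance `r`, is
#' essentially unchanged; what changes is the predictability of the
#' mid-band fluctuations.  Short temporal scales are dominated by fast
#' power in both groups, so the entropy deficit emerges only after
#' coarse-graining past a few minutes, deepening toward the longest
#' scales.
#'
#' @param baseline_temp Mean skin temperature, degC.
#' @param circadian_amplitude Cosine amplitude of the 24-h rhythm, degC
#'   (half the peak-to-trough swing).
#' @param circadian_period Rhythm period in minutes; 1440 = 24 h.
#' @param ar_coefficient Lag-1 coefficient of the fast AR(1) component, in
#'   `[0, 1)`.
#' @param noise_sd Total marginal standard deviation of the irregularity
#'   (all three components), degC.
#' @param complexity_deficit Non-negative slowing of the medium band;
#'   0 = healthy control.
#' @param noise_timescales Correlation times (minutes) of the medium and slow
#'   components, named numeric of length 2.
#' @param noise_shares Variance shares of the fast, medium and slow
#'   components (summing to 1) before the deficit conversion.
#' @param length Number of 1-minute samples; at least 300.
#' @param quantization_step Logger resolution, degC.
#' @param seed Integer seed; fixing it makes the series reproducible
#'   bit-for-bit.
#'
#' @return A list of class `subject_sim_spec`.
#' @seealso [simulate_subject()], [cohort_sim_spec()]
#' @export
subject_sim_spec <- function(baseline_temp = 35.1,
                             circadian_amplitude = 1.5,
                             circadian_period = 1440,
                             ar_coefficient = 0.7,
                             noise_sd = 0.35,
                             complexity_deficit = 0,
                             noise_timescales = c(medium = 50, slow = 100),
                             noise_shares = c(fast = 0.05, medium = 0.80,
                                              slow = 0.15),
                             length = 2800,
                             quantization_step = 0.0625,
                             seed = NULL) {
  spec <- list(
    baseline_temp = baseline_temp,
    circadian_amplitude = circadian_amplitude,
    circadian_period = circadian_period,
    ar_coefficient = ar_coefficient,
    noise_sd = noise_sd,
    complexity_deficit = complexity_deficit,
    noise_timescales = noise_timescales,
    noise_shares = noise_shares,
    length = as.integer(length),
    quantization_step = quantization_step,
    seed = seed
  )
  validate_subject_sim_spec(spec)
  structure(spec, class = "subject_sim_spec")
}

validate_subject_sim_spec <- function(spec) {
  stop_field <- function(field, msg) {
    abort(sprintf("invalid subject_sim_spec field `%s`: %s", field, msg))
  }
  if (!is.numeric(spec$length) || spec$length < 300)
    stop_field("length", "must be >= 300 samples for stable entropy estimation")
  if (spec$quantization_step <= 0)
    stop_field("quantization_step", "must be > 0")
  if (spec$circadian_amplitude < 0)
    stop_field("circadian_amplitude", "must be >= 0")
  if (spec$ar_coefficient < 0 || spec$ar_coefficient >= 1)
    stop_field("ar_coefficient", "must lie in [0, 1)")
  if (spec$noise_sd < 0)
    stop_field("noise_sd", "must be >= 0")
  if (spec$complexity_deficit < 0)
    stop_field("complexity_deficit", "must be >= 0")
  if (length(spec$noise_timescales) != 2 || any(spec$noise_timescales <= 0))
    stop_field("noise_timescales", "must be 2 positive correlation times (minutes)")
  if (length(spec$noise_shares) != 3 || any(spec$noise_shares < 0) ||
      abs(sum(spec$noise_shares) - 1) > 1e-8)
    stop_field("noise_shares", "must be 3 non-negative shares summing to 1")
  if (spec$circadian_period <= 0)
    stop_field("circadian_period", "must be > 0 minutes")
  invisible(spec)
}

# Marginal-SD-normalized AR(1) path: stationary start, lag-1 coefficient phi.
ar1_path <- function(n, phi, marginal_sd) {
  if (marginal_sd == 0) return(numeric(n))
  innov_sd <- marginal_sd * sqrt(1 - phi^2)
  z <- rnorm(n, sd = innov_sd)
  if (phi == 0) return(z)
  x <- as.numeric(stats::filter(z, phi, method = "recursive",
                                init = rnorm(1, sd = marginal_sd)))
  x
}

# Cascade of two identical AR(1) filters (double pole at exp(-1/timescale)),
# normalized to the requested marginal SD via the closed-form variance of the
# cascaded process; a burn-in absorbs the zero initial state.
ar2_cascade_path <- function(n, timescale, marginal_sd, burn = 2000) {
  if (marginal_sd == 0) return(numeric(n))
  phi <- exp(-1 / timescale)
  v <- (1 + phi^2) / (1 - phi^2)^3   # var of cascaded unit-innovation process
  z <- stats::filter(stats::filter(rnorm(n + burn), phi, "recursive"),
                     phi, "recursive")
  marginal_sd * as.numeric(z)[-seq_len(burn)] / sqrt(v)
}

#' Simulate one subject's temperature series
#'
#' Generates `baseline + circadian cosine + multi-timescale AR noise`, then
#' quantizes to the logger resolution.  The circadian phase is drawn
#' uniformly per subject, so detrending cannot rely on a common phase.
#'
#' @param spec A [subject_sim_spec()].
#' @param subject_id Identifier carried in the output.
#'
#' @return A `temperature_series` tibble with columns `minute` (0-based
#'   elapsed minutes) and `temperature` (degC), and attributes
#'   `quantization_step`, `sampling_interval` (minutes) and `subject_id`.
#' @examples
#' ts <- simulate_subject(subject_sim_spec(length = 300, seed = 1))
#' range(ts$temperature)
#' @export
simulate_subject <- function(spec, subject_id = "sim") {
  if (!inherits(spec, "subject_sim_spec")) spec <- do.call(subject_sim_spec, spec)
  validate_subject_sim_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$length
  t <- seq_len(n) - 1
  phase <- runif(1, 0, 2 * pi)
  circ <- spec$circadian_amplitude * cos(2 * pi * t / spec$circadian_period + phase)
  shares <- spec$noise_shares
  # deficit: stretch the medium (vasomotor) correlation time
  stretch <- 1 + spec$complexity_deficit
  sds <- spec$noise_sd * sqrt(shares)
  noise <- ar1_path(n, spec$ar_coefficient, sds[1]) +
    ar2_cascade_path(n, spec$noise_timescales[1] * stretch, sds[2]) +
    ar1_path(n, exp(-1 / spec$noise_timescales[2]), sds[3])
  values <- spec$baseline_temp + circ + noise
  values <- quantize(values, spec$quantization_step)
  new_temperature_series(values,
                         subject_id = subject_id,
                         quantization_step = spec$quantization_step)
}

quantize <- function(x, step) round(x / step) * step

new_temperature_series <- function(values, subject_id = "subject",
                                   quantization_step = 0.0625,
                                   sampling_interval = 1) {
  out <- tibble(minute = seq_along(values) - 1, temperature = values)
  attr(out, "subject_id") <- subject_id
  attr(out, "quantization_step") <- quantization_step
  attr(out, "sampling_interval") <- sampling_interval
  class(out) <- c("temperature_series", class(out))
  out
}

#' Specify a two-group simulated cohort
#'
#' Pairs a control-subject template with an injury-subject template (the
#' latter normally carrying `complexity_deficit > 0`) and group sizes.
#' Defaults mirror the analysable-cohort composition of a nursing-facility
#' study arm: 15 controls and 11 pressure-injury cases, Braden scale scores
#' centred near 15.5 (control) and 14 (injury).
#'
#' @param n_control,n_injury Group sizes, each at least 2.
#' @param control_spec,injury_spec [subject_sim_spec()] templates (per-subject
#'   seeds are assigned by [simulate_cohort()]).
#' @param braden_mean_control,braden_mean_injury Group means of the Braden
#'   scale score (6-23; lower = higher risk).
#' @param braden_sd Within-group SD of the Braden score.
#' @param seed Integer seed governing all cohort-level randomness.
#'
#' @return A list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_control = 15, n_injury = 11,
                            control_spec = subject_sim_spec(),
                            injury_spec = subject_sim_spec(complexity_deficit = 2),
                            braden_mean_control = 15.5,
                            braden_mean_injury = 14,
                            braden_sd = 1.5,
                            seed = NULL) {
  if (n_control < 2 || n_injury < 2)
    abort("invalid cohort_sim_spec: need at least 2 subjects per group")
  validate_subject_sim_spec(control_spec)
  validate_subject_sim_spec(injury_spec)
  structure(list(n_control = as.integer(n_control),
                 n_injury = as.integer(n_injury),
                 control_spec = control_spec,
                 injury_spec = injury_spec,
                 braden_mean_control = braden_mean_control,
                 braden_mean_injury = braden_mean_injury,
                 braden_sd = braden_sd,
                 seed = seed),
            class = "cohort_sim_spec")
}

#' Simulate a two-group temperature-logger cohort
#'
#' Draws every subject from the appropriate group template with an
#' independent per-subject seed, attaches a Braden score and simple baseline
#' covariates, and returns one row per subject.
#'
#' @param spec A [cohort_sim_spec()].
#' @return A tibble with one row per subject: `subject_id`, `group`
#'   (factor control/injury), `braden`, `sex`, `bmi`, `heart_rate`,
#'   `dementia`, `vascular`, and a list-column `series` of
#'   `temperature_series` tibbles.
#' @examples
#' spec <- cohort_sim_spec(n_control = 3, n_injury = 2,
#'                         control_spec = subject_sim_spec(length = 400),
#'                         injury_spec = subject_sim_spec(length = 400,
#'                                                        complexity_deficit = 1),
#'                         seed = 7)
#' simulate_cohort(spec)
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_sim_spec"))
    abort("`spec` must be a cohort_sim_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_control + spec$n_injury
  group <- factor(rep(c("control", "injury"), c(spec$n_control, spec$n_injury)),
                  levels = c("control", "injury"))
  subject_seeds <- sample.int(.Machine$integer.max, n)
  braden_mu <- ifelse(group == "control",
                      spec$braden_mean_control, spec$braden_mean_injury)
  braden <- pmin(23, pmax(6, round(rnorm(n, braden_mu, spec$braden_sd))))
  covars <- tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = group,
    braden = braden,
    sex = factor(ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")),
    bmi = round(rnorm(n, 27, 5), 1),
    heart_rate = round(rnorm(n, 77, 10)),
    dementia = rbinom(n, 1, 0.15),
    vascular = rbinom(n, 1, 0.8)
  )
  tmpl <- list(control = spec$control_spec, injury = spec$injury_spec)
  covars$series <- pmap(list(as.character(group), subject_seeds, covars$subject_id),
                        function(g, s, id) {
                          sub <- tmpl[[g]]
                          sub$seed <- s %% .Machine$integer.max
                          simulate_subject(sub, subject_id = id)
                        })
  covars
}

#' Inject sensor on/off ambient-temperature artifacts
#'
#' Replaces the samples outside the worn interval `[on_index, off_index]`
#' (1-based, inclusive) with ambient-temperature segments: an AR-noise plateau
#' near `ambient_temp` with a linear 10-minute ramp into/out of body
#' temperature, producing the abrupt transients that autoregressive anomaly
#' detection keys on.  The interior of the series is untouched.
#'
#' @param series A `temperature_series` tibble.
#' @param on_index,off_index Worn interval bounds, `1 <= on < off <= length`.
#' @param ambient_temp Room temperature, degC.
#' @param ramp_minutes Length of the linear on/off transient.
#' @param seed Optional seed for the ambient noise.
#' @return The modified `temperature_series`.
#' @export
inject_wear_artifacts <- function(series, on_index, off_index,
                                  ambient_temp = 23, ramp_minutes = 10,
                                  seed = NULL) {
  n <- nrow(series)
  if (on_index < 1 || off_index > n || on_index >= off_index)
    abort("need 1 <= on_index < off_index <= length(series)")
  if (!is.null(seed)) set.seed(seed)
  x <- series$temperature
  body_on <- x[on_index]
  body_off <- x[off_index]
  step <- attr(series, "quantization_step") %||% 0.0625
  ambient_chunk <- function(len, join_temp, side) {
    if (len == 0) return(numeric(0))
    out <- ambient_temp + ar1_path(len, 0.8, 0.3)
    ramp <- min(ramp_minutes, len)
    if (side == "pre") {
      idx <- seq(len - ramp + 1, len)
      out[idx] <- out[idx] + (join_temp - ambient_temp) * seq_len(ramp) / ramp
    } else {
      idx <- seq_len(ramp)
      out[idx] <- out[idx] + (join_temp - ambient_temp) * rev(seq_len(ramp)) / ramp
    }
    out
  }
  if (on_index > 1)
    x[seq_len(on_index - 1)] <-
      ambient_chunk(on_index - 1, body_on, "pre")
  if (off_index < n)
    x[seq(off_index + 1, n)] <-
      ambient_chunk(n - off_index, body_off, "post")
  x <- quantize(x, step)
  x[seq(on_index, off_index)] <- series$temperature[seq(on_index, off_index)]
  series$temperature <- x
  series
}

`%||%` <- function(a, b) if (is.null(a)) b else a
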