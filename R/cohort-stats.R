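#' Cohen's d standardized mean difference
#'
#' `(mean(a) - mean(b)) / pooled SD`, with the pooled SD Bessel-corrected and
#' `(n - 1)`-weighted.  With `a` the control group and `b` the injury group,
#' a positive d means lower values with injury.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @return Cohen's d (unitless).
#' @export
cohen_d <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 values")
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) abort("zero pooled SD; effect size undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test of the difference in means (a - b) with
#' Welch-Satterthwaite degrees of freedom, two-sided p-value and 95%
#' confidence interval, as a one-row tibble.
#'
#' @inheritParams cohen_d
#' @param conf_level Confidence level of the interval.
#' @return One-row tibble: `mean_difference`, `t`, `df`, `p`, `ci_low`,
#'   `ci_high`.
#' @export
welch_t <- function(a, b, conf_level = 0.95) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) abort("each group needs at least 2 values")
  if (var(a) + var(b) <= 0) abort("degenerate variance in both groups")
  ht <- stats::t.test(a, b, var.equal = FALSE, conf.level = conf_level)
  tibble(mean_difference = unname(ht$estimate[1] - ht$estimate[2]),
         t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value,
         ci_low = ht$conf.int[1], ci_high = ht$conf.int[2])
}

#' Per-scale group contrast of entropy curves
#'
#' Cohen's d and a Welch t-test (control minus injury) at every temporal
#' scale.  No multiplicity correction is applied; the `significant` flag
#' simply marks unadjusted p < alpha, the convention for exploratory
#' per-scale screens where the emphasis is on effect sizes.
#'
#' @param curves Long `entropy_curve` tibble for one entropy kind.
#' @param labels Subject labels (see [optimize_scale_range()]).
#' @param alpha Flagging threshold on the unadjusted p-value.
#' @return An `effect_curve` tibble, one row per scale: `scale`, `n_control`,
#'   `n_injury`, `d`, `mean_difference`, `ci_low`, `ci_high`, `t`, `df`,
#'   `p`, `significant`.
#' @export
effect_curve <- function(curves, labels, alpha = 0.05) {
  labels <- as_label_frame(labels)
  kind <- unique(curves$kind)
  if (length(kind) != 1) abort("supply curves for a single entropy kind")
  df <- curves %>%
    filter(.data$defined) %>%
    left_join(labels, by = "subject_id")
  out <- df %>%
    group_by(.data$scale) %>%
    dplyr::group_map(function(g, key) {
      a <- g$value[g$group == "control"]
      b <- g$value[g$group == "injury"]
      if (length(a) < 2 || length(b) < 2) {
        return(tibble(scale = key$scale, n_control = length(a),
                      n_injury = length(b), d = NA_real_,
                      mean_difference = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, t = NA_real_, df = NA_real_,
                      p = NA_real_, significant = NA))
      }
      wt <- welch_t(a, b)
      tibble(scale = key$scale, n_control = length(a), n_injury = length(b),
             d = cohen_d(a, b)) %>%
        dplyr::bind_cols(wt) %>%
        mutate(significant = .data$p < alpha)
    }) %>%
    list_rbind() %>%
    mutate(kind = kind, .before = 1)
  class(out) <- c("effect_curve", class(out))
  out
}

#' Power of a two-sample t-test from the noncentral t distribution
#'
#' Exact analytic power for a two-sample t-test on standardized effect size
#' `d`: noncentrality `d * sqrt(n1 n2 / (n1 + n2))` with `n1 + n2 - 2`
#' degrees of freedom.  With `d = 0` the one-sided power equals `alpha`
#' exactly.
#'
#' @param d Standardized effect size (Cohen's d).
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Significance level.
#' @param tail `"one_sided"` or `"two_sided"`.
#' @return Power in `[0, 1]`.
#' @examples
#' power_two_sample_t(1.13, 6, 34, alpha = 0.05, tail = "one_sided")
#' @export
power_two_sample_t <- function(d, n1, n2, alpha = 0.05,
                               tail = c("one_sided", "two_sided")) {
  tail <- match.arg(tail)
  if (n1 < 2 || n2 < 2) abort("group sizes must be at least 2")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (tail == "one_sided") {
    1 - pt(qt(1 - alpha, df), df, ncp = ncp)
  } else {
    crit <- qt(1 - alpha / 2, df)
    (1 - pt(crit, df, ncp = ncp)) + pt(-crit, df, ncp = ncp)
  }
}

#' Welch-averaged power spectral density
#'
#' Mean modified periodogram over Hann-windowed, 50%-overlapping segments.
#' One-sided density normalized so that the integral over frequency equals
#' the series variance (Parseval).  Sampling rate is 1 per minute, so
#' frequency is in cycles/minute.
#'
#' @param x Numeric series (detrended).
#' @param segment_length Samples per segment.
#' @param overlap Fractional overlap between segments.
#' @return Tibble with `frequency` (cycles/min) and `power` (degC^2 x min).
#' @export
welch_psd <- function(x, segment_length = 512, overlap = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  seg <- min(segment_length, n)
  step <- max(1, floor(seg * (1 - overlap)))
  starts <- seq(1, n - seg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg) / (seg + 1)))  # Hann
  U <- sum(w^2)
  nf <- floor(seg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    xs <- x[s:(s + seg - 1)]
    xs <- (xs - mean(xs)) * w
    ps <- Mod(fft(xs))^2 / U
    acc <- acc + ps[seq_len(nf)]
  }
  p <- acc / length(starts)
  # one-sided: double interior bins (fs = 1 sample/min)
  if (seg %% 2 == 0) p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  else p[2:nf] <- 2 * p[2:nf]
  tibble(frequency = (seq_len(nf) - 1) / seg, power = p)
}

#' Band-power contrast between two groups of segments
#'
#' Welch PSD per subject, mean spectrum per group, and the ratio of
#' integrated power over a timescale band given in minutes (periods
#' `band_minutes[1]` to `band_minutes[2]`, i.e. frequencies
#' `1/band_minutes[2]` to `1/band_minutes[1]` cycles/min).
#'
#' @param segments_a,segments_b Lists of `analysis_segment`s (or numeric
#'   vectors); the ratio reported is b over a.
#' @param band_minutes Length-2 period band in minutes.
#' @param segment_length,overlap Welch settings.
#' @return List with `ratio` (band power b / band power a), `power_a`,
#'   `power_b`, and the band used.
#' @export
band_power_contrast <- function(segments_a, segments_b,
                                band_minutes = c(2.4, 9.1),
                                segment_length = 512, overlap = 0.5) {
  f_lo <- 1 / max(band_minutes)
  f_hi <- 1 / min(band_minutes)
  seg_values <- function(s) if (inherits(s, "analysis_segment")) s$values else as.numeric(s)
  nmin <- min(vapply(c(segments_a, segments_b),
                     function(s) length(seg_values(s)), numeric(1)))
  seg_len <- min(segment_length, nmin)
  if (f_lo < 1 / seg_len || f_hi > 0.5)
    abort("band outside resolvable frequencies for this segment length")
  band_power <- function(segments) {
    spectra <- map(segments, function(s)
      welch_psd(seg_values(s), segment_length = seg_len, overlap = overlap))
    pw <- rowMeans(vapply(spectra, function(s) s$power,
                          numeric(nrow(spectra[[1]]))))
    f <- spectra[[1]]$frequency
    keep <- f >= f_lo & f <= f_hi
    if (sum(keep) < 2) abort("band narrower than the frequency resolution")
    fk <- f[keep]; pk <- pw[keep]
    sum(diff(fk) * (pk[-1] + pk[-length(pk)]) / 2)
  }
  pa <- band_power(segments_a)
  pb <- band_power(segments_b)
  list(ratio = pb / pa, power_a = pa, power_b = pb,
       band_minutes = sort(band_minutes))
}
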