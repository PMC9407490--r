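#' Sample entropy
#'
#' The negative natural log of the conditional probability that epochs of
#' length `m` matching point-wise within tolerance `r` (Chebyshev distance)
#' also match at the next point: `-ln(A/B)`, where `B` counts matching
#' template pairs of length `m` and `A` those still matching at length
#' `m + 1`.  Self-matches are excluded; templates are taken at every start
#' for which the `m+1`-point extension exists.
#'
#' @param values Numeric series; lengths below `10 * m` draw a warning
#'   (estimates are unstable there), lengths below `m + 3` are errors.
#' @param m Embedding dimension (>= 1).
#' @param r Absolute match tolerance (> 0), same units as `values`.
#' @return Entropy in nats, with attributes `A` and `B` (the raw match
#'   counts).
#' @section Errors: throws a classed error when no template pair matches at
#'   length `m` (`thermentropy_no_m_matches`) or at length `m + 1`
#'   (`thermentropy_no_m1_matches`); entropy is undefined in either case.
#' @examples
#' sample_entropy(sin(1:200) + rnorm(200, sd = 0.1), m = 2, r = 0.2)
#' @export
sample_entropy <- function(values, m = 2, r) {
  x <- as.numeric(values)
  if (m < 1) abort("`m` must be a positive integer")
  if (r <= 0) abort("`r` must be positive")
  if (length(x) < m + 3)
    abort(sprintf("series of length %d too short for m=%d", length(x), m))
  if (length(x) < 10 * m)
    warn(sprintf("series of length %d below the stability guideline of %d for m=%d",
                 length(x), 10 * m, m))
  cnt <- sampen_counts(x, as.integer(m), r)
  if (cnt$B == 0)
    abort("no template pairs match at length m; entropy undefined",
          class = "thermentropy_no_m_matches")
  if (cnt$A == 0)
    abort("no template pairs match at length m+1; entropy undefined",
          class = "thermentropy_no_m1_matches")
  structure(-log(cnt$A / cnt$B), A = cnt$A, B = cnt$B)
}

#' Raw sample-entropy template-match counts
#'
#' Exposes the integer pair counts `A` (length `m + 1` matches) and `B`
#' (length `m` matches) underlying [sample_entropy()], mainly for
#' verification against direct pair enumeration.
#'
#' @inheritParams sample_entropy
#' @return List with numeric `A` and `B` (exact integers up to 2^53).
#' @export
sample_entropy_counts <- function(values, m = 2, r) {
  sampen_counts(as.numeric(values), as.integer(m), r)
}

#' Bubble entropy
#'
#' An ordinal, nearly parameter-free irregularity measure.  Every embedded
#' vector of length `k` is reduced to the number of bubble-sort swaps needed
#' to order it ascending; the order-2 Renyi entropy `H_k = -ln sum(p_i^2)` of
#' the swap-count distribution is computed at `k = m` and `k = m + 1`, and
#' the conditional difference is normalized:
#' `(H_{m+1} - H_m) / ln((m + 1) / m)`.  Because only the ordering of values
#' matters, the result is invariant under positive affine transforms of the
#' series.  Equal adjacent elements are never swapped, so heavily quantized
#' series are handled deterministically.
#'
#' @param values Numeric series, length >= `m + 2`.
#' @param m Embedding dimension (>= 2).
#' @return Normalized bubble entropy (unitless), with attributes `H_m` and
#'   `H_m1` (the two Renyi entropies in nats).
#' @export
bubble_entropy <- function(values, m = 3) {
  x <- as.numeric(values)
  if (m < 2) abort("`m` must be at least 2")
  if (length(x) < m + 2)
    abort("series too short: need at least m + 2 samples")
  h <- vapply(c(m, m + 1), function(k) {
    renyi2_swap_entropy(bubble_swap_counts(x, as.integer(k)))
  }, numeric(1))
  structure((h[2] - h[1]) / log((m + 1) / m), H_m = h[1], H_m1 = h[2])
}

# Order-2 Renyi entropy of the empirical swap-count distribution.
renyi2_swap_entropy <- function(counts) {
  if (length(counts) < 2)
    abort("fewer than 2 embedded vectors; bubble entropy undefined")
  p <- tabulate(counts + 1L) / length(counts)
  -log(sum(p^2))
}

#' Butterworth coarse-graining
#'
#' Maps a 1-minute series to temporal scale `tau` for refined multiscale
#' entropy: a zero-phase (forward-backward) 6th-order Butterworth low-pass at
#' cutoff `1 / (2 tau)` cycles per minute removes structure faster than the
#' target scale, then every `tau`-th sample is kept.  `tau = 1` is the
#' identity.
#'
#' @param values Numeric series.
#' @param tau Integer temporal scale, minutes (>= 1).
#' @param filter_order Butterworth order.
#' @param decimate Keep every `tau`-th sample (default); set `FALSE` to
#'   return the filtered, undecimated series.
#' @return The coarse-grained series.
#' @export
coarse_grain <- function(values, tau, filter_order = 6, decimate = TRUE) {
  x <- as.numeric(values)
  tau <- as.integer(tau)
  if (tau < 1) abort("`tau` must be >= 1")
  if (tau == 1) return(x)
  if (length(x) <= 3 * filter_order)
    abort("series too short for zero-phase filtering")
  # cutoff 1/(2 tau) cycles/min over a Nyquist of 0.5 cycles/min
  bf <- signal::butter(filter_order, 1 / tau, type = "low")
  xf <- signal::filtfilt(bf, x)
  if (decimate) xf[seq(1, length(xf), by = tau)] else xf
}

#' Refined multiscale entropy curve
#'
#' Computes sample or bubble entropy of an [prepare_segment()] output at
#' temporal scales `1..tau_max`.  At each scale the series is Butterworth
#' low-pass filtered (cutoff `1/(2 tau)`) and decimated; for sample entropy
#' the tolerance is re-derived at every scale as `r_frac` times the SD of the
#' filtered series, which counteracts the artificial entropy shrinkage that a
#' fixed tolerance produces at long scales.  Scales where the estimator is
#' undefined (no template matches, or too few points) are flagged rather than
#' dropped.
#'
#' Raw series are refused: trim, detrend and stationarity-test first with
#' [prepare_segment()].
#'
#' @param segment An `analysis_segment`.
#' @param kind `"sampen"` or `"bubben"`.
#' @param m Embedding dimension (default 3, the reporting configuration).
#' @param r_frac Tolerance as a fraction of the scale-wise SD (sample entropy
#'   only; default 0.15).
#' @param tau_max Largest scale, minutes.
#' @param filter_order Butterworth order.
#' @param r_from Recompute the tolerance from the `"filtered"`
#'   (pre-decimation, default) or `"decimated"` series.
#' @return An `entropy_curve` tibble: `subject_id`, `kind`, `m`, `r_frac`,
#'   `scale`, `value`, `defined`.
#' @export
refined_multiscale <- function(segment, kind = c("sampen", "bubben"),
                               m = 3, r_frac = 0.15, tau_max = 25,
                               filter_order = 6,
                               r_from = c("filtered", "decimated")) {
  kind <- match.arg(kind)
  r_from <- match.arg(r_from)
  if (!inherits(segment, "analysis_segment"))
    abort(paste("refined_multiscale() requires an analysis_segment;",
                "run prepare_segment() first (raw series are refused)"))
  x <- segment$values
  if (length(x) < 100 * tau_max)
    warn(sprintf("series length %d < 100 * tau_max; long-scale estimates may be unstable",
                 length(x)))
  rows <- map(seq_len(tau_max), function(tau) {
    xf <- coarse_grain(x, tau, filter_order, decimate = FALSE)
    xd <- if (tau == 1) xf else xf[seq(1, length(xf), by = tau)]
    val <- tryCatch({
      if (kind == "sampen") {
        r_abs <- r_frac * sd(if (r_from == "filtered") xf else xd)
        as.numeric(sample_entropy(xd, m = m, r = r_abs))
      } else {
        as.numeric(bubble_entropy(xd, m = m))
      }
    }, error = function(e) NA_real_)
    tibble(scale = tau, value = val, defined = is.finite(val))
  })
  rf <- if (kind == "sampen") r_frac else NA_real_
  out <- list_rbind(rows) %>%
    mutate(subject_id = segment$subject_id, kind = .env$kind, m = .env$m,
           r_frac = rf, .before = 1)
  class(out) <- c("entropy_curve", class(out))
  out
}

#' Multiscale entropy curves for a list of segments
#'
#' Maps [refined_multiscale()] over a list of `analysis_segment`s and binds
#' the per-subject curves into one long tibble.
#'
#' @param segments List of `analysis_segment`s.
#' @param ... Passed to [refined_multiscale()].
#' @return A long `entropy_curve` tibble.
#' @export
multiscale_entropy <- function(segments, ...) {
  out <- list_rbind(map(segments, refined_multiscale, ...))
  class(out) <- c("entropy_curve", class(out))
  out
}
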