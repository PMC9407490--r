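# Independent reference implementations used to validate the fast estimators.
# These stay deliberately naive: direct pair enumeration and literal
# bubble-sort counting, no shared code with the package internals.

# O(N^2) template-pair enumeration for sample entropy (Chebyshev distance,
# templates at every start that still has an (m+1)-th point).
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L
  B <- 0L
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  list(A = A, B = B)
}

# literal bubble sort, counting swaps (no swap on ties)
bubble_swaps_oracle <- function(v) {
  s <- 0L
  for (p in seq(length(v) - 1, 1)) {
    swapped <- FALSE
    for (k in 1:p) {
      if (v[k] > v[k + 1]) {
        tmp <- v[k]; v[k] <- v[k + 1]; v[k + 1] <- tmp
        s <- s + 1L
        swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  s
}

bubble_entropy_oracle <- function(x, m) {
  H <- vapply(c(m, m + 1), function(k) {
    sw <- vapply(1:(length(x) - k + 1),
                 function(i) bubble_swaps_oracle(x[i:(i + k - 1)]), integer(1))
    p <- as.numeric(table(sw)) / length(sw)
    -log(sum(p^2))
  }, numeric(1))
  (H[2] - H[1]) / log((m + 1) / m)
}

# closed-form OLS slope via the normal equations
ols_slope_oracle <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

# build an analysis_segment directly from values (for entropy-level tests
# that do not need the preprocessing pipeline)
segment_from_values <- function(values, id = "test") {
  thermentropy:::new_analysis_segment(values - mean(values), c(1L, length(values)),
                                      "linear", 0.01, subject_id = id)
}

# wrap raw values as a temperature_series tibble
new_series_for_test <- function(values, id = "test") {
  thermentropy:::new_temperature_series(values, subject_id = id)
}

# small entropy-curve tibble from explicit per-scale values
curve_from_values <- function(values, id = "s1", kind = "sampen") {
  out <- tibble::tibble(subject_id = id, kind = kind, m = 3,
                        r_frac = ifelse(kind == "sampen", 0.15, NA_real_),
                        scale = seq_along(values), value = values,
                        defined = is.finite(values))
  class(out) <- c("entropy_curve", class(out))
  out
}

# multi-subject curves with a group effect injected on chosen scales
cohort_curves <- function(n_control, n_injury, scales = 1:25,
                          effect_scales = integer(0), effect = 0, sd = 0.1,
                          kind = "sampen") {
  ids <- c(sprintf("C%02d", seq_len(n_control)),
           sprintf("I%02d", seq_len(n_injury)))
  grp <- rep(c("control", "injury"), c(n_control, n_injury))
  curves <- purrr::map2(ids, grp, function(id, g) {
    v <- 1 + 0.02 * scales + rnorm(length(scales), sd = sd)
    if (g == "injury") v[scales %in% effect_scales] <-
        v[scales %in% effect_scales] - effect
    curve_from_values(v, id, kind)
  })
  list(curves = dplyr::bind_rows(curves),
       labels = tibble::tibble(subject_id = ids, group = grp))
}
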