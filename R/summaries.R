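#' Default reporting windows for entropy-curve summaries
#'
#' The scale windows used for reporting: the sample-entropy scaling exponent
#' over 5-10 min (log-scale center 7.07 min), the bubble-entropy scaling
#' exponent over the full 1-25 min range (center 5.0 min), and the windowed
#' AUCs over 22-24 min (SampEn) and 21-23 min (BubbEn), which bracket the
#' scales of peak group contrast.
#'
#' @return A tibble with columns `kind`, `feature_kind`, `s1`, `s2`.
#' @export
default_summary_windows <- function() {
  tibble(kind = c("sampen", "bubben", "sampen", "bubben"),
         feature_kind = c("scaling_exponent", "scaling_exponent",
                          "requisite_auc", "requisite_auc"),
         s1 = c(5L, 1L, 22L, 21L),
         s2 = c(10L, 25L, 24L, 23L))
}

# Extract and validate one subject's defined curve values over [s1, s2].
curve_window_values <- function(curve, s1, s2) {
  if (length(unique(curve$subject_id)) != 1 || length(unique(curve$kind)) != 1)
    abort("expected a curve for a single subject and entropy kind")
  w <- curve[curve$scale >= s1 & curve$scale <= s2, ]
  scales <- seq(s1, s2)
  if (nrow(w) != length(scales) || !all(w$defined))
    abort(sprintf("curve undefined on some scale in [%d, %d]", s1, s2))
  w$value[order(w$scale)]
}

#' Scaling exponent of an entropy curve
#'
#' OLS slope of entropy against the centered natural log of the temporal
#' scale over the window `[s1, s2]`, i.e. the local slope of the
#' entropy-versus-ln(scale) curve evaluated at the window's geometric-mean
#' center.  The window must span at least five consecutive scales.
#'
#' @param curve An `entropy_curve` tibble for one subject and entropy kind.
#' @param s1,s2 Integer window bounds (inclusive), `s2 - s1 >= 4`.
#' @return One-row tibble: `subject_id`, `kind`, `feature_kind`, `s1`, `s2`,
#'   `center` (minutes, geometric mean), `value` (nats per ln-minute).
#' @export
scaling_exponent <- function(curve, s1, s2) {
  if (s2 - s1 < 4)
    abort("scaling-exponent window must span at least five consecutive scales")
  v <- curve_window_values(curve, s1, s2)
  lt <- log(seq(s1, s2))
  lt <- lt - mean(c(log(s1), log(s2)))
  slope <- sum((lt - mean(lt)) * (v - mean(v))) / sum((lt - mean(lt))^2)
  tibble(subject_id = curve$subject_id[1], kind = curve$kind[1],
         feature_kind = "scaling_exponent",
         s1 = as.integer(s1), s2 = as.integer(s2),
         center = exp((log(s1) + log(s2)) / 2), value = slope)
}

#' Windowed area under an entropy curve
#'
#' Trapezoidal integral of entropy over the integer scale grid between `s1`
#' and `s2` (at least three consecutive scales); a magnitude summary of the
#' curve over the scales of interest.
#'
#' @inheritParams scaling_exponent
#' @param s1,s2 Integer window bounds (inclusive), `s2 - s1 >= 2`.
#' @return One-row tibble as in [scaling_exponent()] (`value` in
#'   nats x minutes; `center` is the arithmetic midpoint).
#' @export
requisite_auc <- function(curve, s1, s2) {
  if (s2 - s1 < 2)
    abort("AUC window must span at least three consecutive scales")
  v <- curve_window_values(curve, s1, s2)
  auc <- sum((v[-length(v)] + v[-1]) / 2)
  tibble(subject_id = curve$subject_id[1], kind = curve$kind[1],
         feature_kind = "requisite_auc",
         s1 = as.integer(s1), s2 = as.integer(s2),
         center = (s1 + s2) / 2, value = auc)
}

#' Per-subject entropy-curve summary features
#'
#' Computes the scaling exponent and requisite AUC for every subject at the
#' given windows and returns them wide, one row per subject, with columns
#' named `<kind>_scaling_exp` and `<kind>_req_auc`.  A feature whose window
#' contains a flagged (undefined) scale for a subject is returned as `NA`
#' for that subject; downstream modelling excludes such subjects, mirroring
#' how unusable recordings are discarded from a real cohort.
#'
#' @param curves Long `entropy_curve` tibble (one or both entropy kinds).
#' @param windows Window table as from [default_summary_windows()].
#' @return A wide tibble of features, one row per subject.
#' @export
summarize_entropy <- function(curves, windows = default_summary_windows()) {
  feats <- purrr::pmap(windows, function(kind, feature_kind, s1, s2) {
    sub <- curves[curves$kind == kind, ]
    if (nrow(sub) == 0) return(NULL)
    fn <- if (feature_kind == "scaling_exponent") scaling_exponent else requisite_auc
    fk <- feature_kind
    sub %>%
      group_by(.data$subject_id) %>%
      dplyr::group_map(function(g, key) {
        tryCatch(fn(g %>% mutate(subject_id = key$subject_id), s1, s2),
                 error = function(e)
                   tibble(subject_id = key$subject_id, kind = g$kind[1],
                          feature_kind = fk, s1 = as.integer(s1),
                          s2 = as.integer(s2), center = NA_real_,
                          value = NA_real_))
      }) %>%
      list_rbind()
  }) %>% list_rbind()
  feats %>%
    mutate(feature = paste0(.data$kind, "_",
                            ifelse(.data$feature_kind == "scaling_exponent",
                                   "scaling_exp", "req_auc"))) %>%
    select("subject_id", "feature", "value") %>%
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
}

#' Effect-size-optimized scale-range search
#'
#' Exhaustively enumerates every scale window `[s1, s2]` spanning at least
#' `min_span` consecutive scales on which all subjects' curves are defined,
#' computes the per-subject summary feature on each window, and selects the
#' window maximizing Cohen's d between groups (control minus injury, so a
#' positive d means lower entropy with injury).  Ties are broken toward the
#' smallest `s1`, then the smallest `s2`.
#'
#' @param curves Long `entropy_curve` tibble for one entropy kind, several
#'   subjects on a shared scale grid.
#' @param labels Data frame with columns `subject_id` and `group`
#'   (control/injury), or a vector of groups named by subject id.
#' @param feature_kind `"scaling_exponent"` or `"requisite_auc"`.
#' @param min_span Minimum number of consecutive scales; defaults to 5 for
#'   the scaling exponent and 3 for the AUC.
#' @return A `range_search` list: `feature_kind`, `kind`, `best` (`s1`,
#'   `s2`), `best_effect_size`, and `window_table` (all admissible windows
#'   with their effect sizes).
#' @export
optimize_scale_range <- function(curves, labels,
                                 feature_kind = c("scaling_exponent",
                                                  "requisite_auc"),
                                 min_span = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (is.null(min_span))
    min_span <- if (feature_kind == "scaling_exponent") 5L else 3L
  kind <- unique(curves$kind)
  if (length(kind) != 1) abort("supply curves for a single entropy kind")
  labels <- as_label_frame(labels)
  if (min(table(labels$group)) < 2)
    abort("need at least 2 subjects per group")
  ids <- unique(curves$subject_id)
  scales <- sort(unique(curves$scale))
  # scale x subject matrix of curve values (NA where undefined)
  vm <- matrix(NA_real_, nrow = length(scales), ncol = length(ids),
               dimnames = list(scales, ids))
  for (i in seq_len(nrow(curves))) {
    if (curves$defined[i])
      vm[as.character(curves$scale[i]), curves$subject_id[i]] <- curves$value[i]
  }
  grp <- labels$group[match(ids, labels$subject_id)]
  rows <- list()
  for (a in seq_along(scales)) {
    for (b in seq_along(scales)) {
      s1 <- scales[a]; s2 <- scales[b]
      if (s2 - s1 < min_span - 1) next
      if (!all(scales[a:b] == seq(s1, s2))) next
      block <- vm[a:b, , drop = FALSE]
      if (anyNA(block)) next
      feat <- apply(block, 2, function(v) {
        if (feature_kind == "scaling_exponent") {
          lt <- log(seq(s1, s2))
          sum((lt - mean(lt)) * (v - mean(v))) / sum((lt - mean(lt))^2)
        } else {
          sum((v[-length(v)] + v[-1]) / 2)
        }
      })
      d <- cohen_d(feat[grp == "control"], feat[grp == "injury"])
      rows[[length(rows) + 1]] <- tibble(s1 = s1, s2 = s2, effect_size = d)
    }
  }
  if (length(rows) == 0) abort("no admissible scale window")
  wt <- list_rbind(rows) %>% arrange(.data$s1, .data$s2)
  best <- wt %>%
    arrange(dplyr::desc(.data$effect_size), .data$s1, .data$s2) %>%
    slice(1)
  structure(list(feature_kind = feature_kind, kind = kind,
                 best = c(s1 = best$s1, s2 = best$s2),
                 best_effect_size = best$effect_size,
                 window_table = wt),
            class = "range_search")
}

as_label_frame <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("subject_id", "group") %in% names(labels)))
    tibble(subject_id = as.character(labels$subject_id),
           group = as.character(labels$group))
  } else {
    tibble(subject_id = names(labels), group = as.character(labels))
  }
}

#' @export
print.range_search <- function(x, ...) {
  cat(sprintf("<range_search> %s %s: best window [%d, %d], Cohen's d = %.3f (%d windows searched)\n",
              x$kind, x$feature_kind, x$best["s1"], x$best["s2"],
              x$best_effect_size, nrow(x$window_table)))
  invisible(x)
}
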