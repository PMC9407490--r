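#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_ribbon geom_tile labs scale_x_continuous theme_minimal
#'   stat_summary facet_wrap scale_fill_viridis_c
#' @export
ggplot2::autoplot

#' Plot entropy curves by group
#'
#' Group mean curves with standard-error ribbons when labels are supplied,
#' otherwise one line per subject.
#'
#' @param object A long `entropy_curve` tibble.
#' @param labels Optional subject labels (see [optimize_scale_range()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.entropy_curve <- function(object, labels = NULL, ...) {
  df <- dplyr::filter(object, .data$defined)
  if (is.null(labels)) {
    p <- ggplot(df, aes(.data$scale, .data$value, group = .data$subject_id)) +
      geom_line(alpha = 0.4)
  } else {
    df <- left_join(df, as_label_frame(labels), by = "subject_id")
    sm <- df %>%
      group_by(.data$kind, .data$group, .data$scale) %>%
      summarise(mean = mean(.data$value),
                se = sd(.data$value) / sqrt(n()), .groups = "drop")
    p <- ggplot(sm, aes(.data$scale, .data$mean, colour = .data$group,
                        fill = .data$group)) +
      geom_ribbon(aes(ymin = .data$mean - .data$se,
                      ymax = .data$mean + .data$se),
                  alpha = 0.2, colour = NA) +
      geom_line()
  }
  p + facet_wrap(~kind, scales = "free_y") +
    labs(x = "temporal scale (min)", y = "entropy") +
    theme_minimal()
}

#' Plot a per-scale effect-size curve
#'
#' Cohen's d against temporal scale; scales with unadjusted p < 0.05 are
#' drawn as filled points.
#'
#' @param object An `effect_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effect_curve <- function(object, ...) {
  df <- dplyr::filter(object, is.finite(.data$d))
  ggplot(df, aes(.data$scale, .data$d)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_line() +
    geom_point(aes(shape = .data$significant), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                na.translate = FALSE) +
    facet_wrap(~kind) +
    labs(x = "temporal scale (min)", y = "Cohen's d (control - injury)",
         shape = "p < 0.05") +
    theme_minimal()
}

#' Plot the scale-range search surface
#'
#' Effect size of every admissible `[s1, s2]` window, with the selected
#' window marked.
#'
#' @param object A `range_search` from [optimize_scale_range()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.range_search <- function(object, ...) {
  ggplot(object$window_table, aes(.data$s1, .data$s2, fill = .data$effect_size)) +
    geom_tile() +
    geom_point(data = tibble(s1 = object$best["s1"], s2 = object$best["s2"]),
               aes(.data$s1, .data$s2), inherit.aes = FALSE, shape = 4, size = 3) +
    scale_fill_viridis_c(name = "Cohen's d") +
    labs(x = "window start s1 (min)", y = "window end s2 (min)",
         title = sprintf("%s %s window search", object$kind, object$feature_kind)) +
    theme_minimal()
}
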