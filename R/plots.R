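#' Diagnostic plot of EMG envelopes
#'
#' Line plot of one or more muscle envelopes over time, optionally with
#' stride boundaries overlaid, in the style of raw-trace figures used to
#' illustrate locomotor EMG.
#'
#' @param env Envelope tibble from [trial_envelopes()].
#' @param muscles Muscles to show.
#' @param onsets Optional onset tibble (vertical dashed lines).
#' @param xlim Optional time window (s).
#' @return A ggplot object.
#' @export
plot_envelopes <- function(env, muscles = GAIT_MUSCLES, onsets = NULL,
                           xlim = NULL) {
  long <- env |>
    select(all_of(c("time_s", muscles))) |>
    tidyr::pivot_longer(-"time_s", names_to = "muscle", values_to = "mv") |>
    mutate(muscle = factor(.data$muscle, levels = muscles))
  if (!is.null(xlim)) {
    long <- filter(long, .data$time_s >= xlim[1], .data$time_s <= xlim[2])
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$muscle), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "envelope (mV)") +
    ggplot2::theme_minimal()
  if (!is.null(onsets) && nrow(onsets) > 0) {
    on <- onsets
    if (!is.null(xlim)) on <- filter(on, .data$onset_s >= xlim[1], .data$onset_s <= xlim[2])
    p <- p + ggplot2::geom_vline(data = on,
                                 ggplot2::aes(xintercept = .data$onset_s),
                                 linetype = "dashed", linewidth = 0.2)
  }
  p
}

#' Cycle-averaged feature summaries by week
#'
#' Bar-and-error summary of a per-stride feature across weeks: subject
#' means are averaged per week with across-subject SD whiskers, the
#' presentation used for group-level adaptation summaries.
#'
#' @param features Long feature tibble.
#' @param feature Feature to summarize.
#' @return A ggplot object.
#' @export
plot_feature_by_week <- function(features, feature) {
  dat <- features |>
    filter(.data$feature == !!feature, !is.na(.data$value)) |>
    group_by(.data$subject, .data$week) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    group_by(.data$week) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              n = n(), .groups = "drop") |>
    mutate(week = factor(.data$week,
                         levels = intersect(GAIT_WEEKS, unique(.data$week))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$week, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a contrast table
#'
#' Dot-and-interval plot of contrast estimates with approximate 95%
#' intervals, colored by Bonferroni-corrected significance.
#'
#' @param object A `gait_contrasts` tibble.
#' @param alpha Significance level applied to the corrected p-values.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_contrasts <- function(object, alpha = 0.05, ...) {
  dat <- mutate(as_tibble(object),
                significant = .data$adj_p < alpha,
                lo = .data$estimate - 1.96 * .data$se,
                hi = .data$estimate + 1.96 * .data$se)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$label,
                                    color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.15) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "estimate", y = NULL, color = sprintf("adj p < %.2f", alpha)) +
    ggplot2::theme_minimal()
}

#' Plot model diagnostics
#'
#' Normal qq-plot of the residuals of a fitted mixed model, for the visual
#' check of the Gaussian-residual assumption.
#'
#' @param object A `gait_diagnostics` object from [export_diagnostics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_diagnostics <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$theoretical, y = .data$residual)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "theoretical quantile", y = "residual") +
    ggplot2::theme_minimal()
}
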