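#' Plot the trial-averaged normalized beta time course
#'
#' One line per channel (optionally a subset), with the cue at t = 0 and
#' the desynchronization / rebound search windows shaded.
#'
#' @param object A `beta_timecourse` object.
#' @param channels Optional character vector of channel labels to show.
#' @param erd_window,ers_window Shaded search windows in seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beta_timecourse <- function(object, channels = NULL,
                                     erd_window = c(0, 0.7),
                                     ers_window = c(0.7, 1.0), ...) {
  labs <- object$montage$label
  if (!is.null(channels)) {
    labs <- intersect(channels, labs)
    if (length(labs) == 0) stop("no matching channels", call. = FALSE)
  }
  idx <- match(labs, object$montage$label)
  avg <- apply(object$value[, idx, , drop = FALSE], c(2, 3), mean)
  df <- tibble::tibble(
    channel = rep(labs, each = length(object$times)),
    time = rep(object$times, length(labs)),
    value = as.numeric(t(avg))
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$value,
    colour = .data$channel
  )) +
    ggplot2::annotate("rect",
      xmin = erd_window[1], xmax = erd_window[2],
      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "steelblue"
    ) +
    ggplot2::annotate("rect",
      xmin = ers_window[1], xmax = ers_window[2],
      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "firebrick"
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time relative to cue (s)",
      y = "relative beta power change",
      title = "Trial-averaged beta modulation"
    )
}

#' Plot the montage with a personalized ROI highlighted
#'
#' Top-view scalp projection (x right, y front) of the electrode
#' positions; ROI members are filled, the peak electrode emphasized.
#'
#' @param montage Montage tibble.
#' @param roi Optional `personalized_roi` from [select_roi()].
#' @return A ggplot object.
#' @export
plot_montage <- function(montage, roi = NULL) {
  role <- if (is.null(roi)) {
    rep("other", nrow(montage))
  } else {
    dplyr::case_when(
      montage$label == roi$peak_electrode ~ "peak",
      montage$label %in% roi$members ~ "member",
      .default = "other"
    )
  }
  df <- dplyr::mutate(montage, role = role)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$x, y = .data$y,
    colour = .data$role
  )) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
      nudge_y = 0.06, size = 2.5, show.legend = FALSE
    ) +
    ggplot2::scale_colour_manual(values = c(
      peak = "firebrick", member = "steelblue", other = "grey60"
    )) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Electrode montage (top view)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot group modulation-depth distributions
#'
#' Boxplots with jittered points of a subject-level metric by group.
#'
#' @param data Data frame with one row per subject.
#' @param value Column name (string) of the metric (default
#'   `"modulation_depth"`).
#' @param group Column name (string) of the group factor (default
#'   `"group"`).
#' @return A ggplot object.
#' @export
plot_group_depths <- function(data, value = "modulation_depth",
                              group = "group") {
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data[[group]], y = .data[[value]],
    colour = .data[[group]]
  )) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(
      x = NULL, y = value,
      title = "Beta modulation depth by group"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot the cross-validated classifier report
#'
#' Metric means with percentile intervals over the repeated nested-CV
#' runs.
#'
#' @param object A `fatigue_cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fatigue_cv_report <- function(object, ...) {
  ggplot2::ggplot(object$metrics, ggplot2::aes(
    x = .data$metric, y = .data$mean
  )) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$conf_low, ymax = .data$conf_high
    )) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "value (mean and 95% interval over repeats)",
      title = "Nested-CV classification metrics"
    ) +
    ggplot2::theme_minimal()
}

#' Plot predictor selection frequencies
#'
#' Mean selection frequency per predictor with the retention cut-off
#' marked.
#'
#' @param report A `fatigue_cv_report`.
#' @param msf_threshold Cut-off line (default 0.5).
#' @return A ggplot object.
#' @export
plot_selection_frequency <- function(report, msf_threshold = 0.5) {
  df <- dplyr::arrange(report$selection, .data$msf)
  df$term <- factor(df$term, levels = df$term)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$msf, y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(
      xintercept = msf_threshold,
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "mean selection frequency", y = NULL,
      title = "Elastic-net stability selection"
    ) +
    ggplot2::theme_minimal()
}
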