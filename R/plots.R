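# ggplot2 figures for each result type.

#' Plot per-animal ICI cumulative distributions
#'
#' One empirical CDF step curve per animal, colored by group when available.
#'
#' @param ici Long data frame with `animal`, `interval` and optionally `group`.
#' @return A ggplot object.
#' @export
plot_ici_cdf <- function(ici) {
  if (!all(c("animal", "interval") %in% names(ici))) {
    abort_data("`ici` must have `animal` and `interval` columns.")
  }
  cdf <- ici %>%
    dplyr::group_by(dplyr::across(dplyr::any_of(c("animal", "group")))) %>%
    dplyr::arrange(.data$interval, .by_group = TRUE) %>%
    dplyr::mutate(cum_prob = dplyr::row_number() / dplyr::n()) %>%
    dplyr::ungroup()
  p <- ggplot2::ggplot(cdf, ggplot2::aes(.data$interval, .data$cum_prob,
                                         group = .data$animal))
  p <- if ("group" %in% names(cdf)) {
    p + ggplot2::geom_step(ggplot2::aes(color = .data$group), alpha = 0.7)
  } else {
    p + ggplot2::geom_step(alpha = 0.7)
  }
  p + ggplot2::labs(x = "Inter-breathing-cycle interval (s)",
                    y = "Cumulative probability")
}

#' @describeIn delta_matrix Heatmap of the pairwise |delta| distances.
#' @param object A `delta_matrix`.
#' @method autoplot delta_matrix
#' @export
autoplot.delta_matrix <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$animal_a, .data$animal_b,
                                     fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "|Cliff's δ|") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @describeIn cluster_animals Cosine-distance heatmap in dendrogram order
#'   with cluster assignments on the axis.
#' @param object A `cluster_result`.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  ord <- object$hclust$order
  ids <- object$labels$animal[ord]
  lab <- sprintf("%s [c%d]", ids, object$labels$cluster[ord])
  m <- object$cosine[ord, ord]
  long <- tibble(
    a = factor(rep(lab, times = length(lab)), levels = lab),
    b = factor(rep(lab, each = length(lab)), levels = lab),
    d = as.vector(m)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$a, .data$b, fill = .data$d)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "cosine dist.") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @describeIn fit_iv I/V points with the fitted relation and the reversal
#'   potential marked.
#' @param object A `df_estimate`.
#' @method autoplot df_estimate
#' @export
autoplot.df_estimate <- function(object, ...) {
  d <- object$data
  grid <- tibble(potential_mv = seq(min(d$potential_mv), max(d$potential_mv),
                                    length.out = 200))
  grid$fit <- stats::predict(object$fit, newdata = data.frame(v = grid$potential_mv))
  ggplot2::ggplot(d, ggplot2::aes(.data$potential_mv, .data$mean_current_pa)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit), color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$reversal_mv, linetype = 2,
                        color = "red3") +
    ggplot2::labs(x = "Imposed potential -Vp (mV)",
                  y = "Mean open-channel current (pA)",
                  subtitle = sprintf("DF_GABA = %.1f mV", object$df_gaba_mv))
}

#' Plot a normalized fEPSP slope time course
#'
#' Normalized slope against time with the early- and late-LTD analysis windows
#' shaded.
#'
#' @param series Data frame with `time_min` and `norm_slope` (or `slope`, then
#'   normalized with `baseline_window`).
#' @param early_window,late_window Analysis windows, minutes after washout.
#' @param baseline_window Baseline span for normalization if needed.
#' @return A ggplot object.
#' @export
plot_ltd <- function(series, early_window = c(20, 25), late_window = c(50, 55),
                     baseline_window = c(-15, -5)) {
  if (!"norm_slope" %in% names(series)) {
    series <- normalize_slopes(series, baseline_window = baseline_window)
  }
  shade <- tibble(
    xmin = c(early_window[1], late_window[1]),
    xmax = c(early_window[2], late_window[2]),
    window = c("early-LTD", "late-LTD")
  )
  ggplot2::ggplot(series, ggplot2::aes(.data$time_min, .data$norm_slope)) +
    ggplot2::geom_rect(data = shade, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$window), alpha = 0.2) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Time after drug washout (min)",
                  y = "fEPSP slope (% of baseline)", fill = NULL)
}

#' Plot a trace with detected events and bursts
#'
#' @param trace Data frame with `time`, `value`.
#' @param events Optional `event_train`; onsets are marked.
#' @param bursts Optional `burst_set`; burst epochs are shaded.
#' @return A ggplot object.
#' @export
plot_trace_events <- function(trace, events = NULL, bursts = NULL) {
  check_trace(trace)
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "Time (s)", y = "Current (pA)")
  if (!is.null(bursts) && nrow(bursts) > 0) {
    p <- p + ggplot2::geom_rect(
      data = bursts, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      fill = "orange", alpha = 0.2
    )
  }
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rug(data = events, sides = "t",
                               ggplot2::aes(x = .data$time), inherit.aes = FALSE)
  }
  p
}

#' @describeIn paired_correlation Cross-correlogram plot with the zero-lag
#'   Pearson coefficient annotated.
#' @param object A `paired_correlation`.
#' @method autoplot paired_correlation
#' @export
autoplot.paired_correlation <- function(object, ...) {
  ggplot2::ggplot(object$correlogram, ggplot2::aes(.data$lag, .data$correlation)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Lag (s)", y = "Cross-correlation",
                  subtitle = sprintf("zero-lag Pearson r = %.3f", object$r))
}
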