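#' Plot the inclination trace of a trial with detected drink events
#'
#' @param cond Conditioned recording (theta computed if absent).
#' @param events Optional macro-event table from [detect_macro_events()];
#'   detected on the fly when `NULL`.
#' @param cfg A [segmentation_config()], used when detecting.
#' @return A ggplot object.
#' @export
plot_inclination <- function(cond, events = NULL, cfg = segmentation_config()) {
  if (!"theta" %in% names(cond)) cond <- compute_inclination(cond)
  if (is.null(events)) events <- detect_macro_events(cond, cfg)
  p <- ggplot2::ggplot(as_tibble(cond), ggplot2::aes(x = .data$t, y = .data$theta)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = expression(theta ~ "(degrees)"),
                  title = "Container inclination") +
    ggplot2::theme_minimal()
  if (nrow(events) > 0) {
    shade <- tibble(xmin = cond$t[events$start],
                    xmax = cond$t[pmin(events$end, nrow(cond))])
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue")
  }
  p
}

#' Plot the micro-event partition of one drink
#'
#' Shows the cross-sectional angle over a macro-event with the lift, sip and
#' place phases shaded; the sip is the stretch where the angle is
#' stationary.
#'
#' @param alpha Cross-sectional angle over the macro-event (degrees).
#' @param partition One-row tibble from [partition_micro_events()].
#' @param rate Sampling rate, Hz.
#' @return A ggplot object.
#' @export
plot_micro_partition <- function(alpha, partition, rate = 20) {
  df <- tibble(t = seq_along(alpha) / rate, alpha = alpha)
  bands <- tibble(
    phase = factor(c("lift", "sip", "place"), levels = c("lift", "sip", "place")),
    xmin = c(partition$lift_start, partition$sip_start, partition$place_start) / rate,
    xmax = c(partition$lift_end, partition$sip_end, partition$place_end) / rate
  )
  bands <- bands[bands$xmax > bands$xmin, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$alpha)) +
    ggplot2::geom_rect(data = bands,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf, fill = .data$phase),
                       inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time within event (s)", y = expression(alpha ~ "(degrees)"),
                  fill = NULL, title = "Lift / sip / place partition") +
    ggplot2::theme_minimal()
}

#' Plot predictions against ground truth for a LOTO run
#'
#' @param object A [loto_evaluate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loto_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$truth, y = .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "ground truth", y = "prediction",
                  title = "Leave-one-trial-out predictions") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of per-trial MAPE for an evaluation
#'
#' @param object An [evaluation_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  ggplot2::ggplot(object$per_trial, ggplot2::aes(x = .data$mape)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "per-trial MAPE (%)", y = "trials",
                  title = sprintf("Per-trial error dispersion (sd %.2f%%)",
                                  object$mape_sd)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
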