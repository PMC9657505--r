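#' Plot a PTT series
#'
#' Per-beat PTT in milliseconds against time; beats flagged unusable are
#' drawn hollow.
#'
#' @param object A `ptt_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ptt_series
#' @export
autoplot.ptt_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beat_time_s,
                                   y = 1000 * .data$ptt_s,
                                   shape = .data$quality)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "usable") +
    ggplot2::labs(x = "time (s)", y = "PTT (ms)") +
    ggplot2::theme_minimal()
}

#' Plot the RR tachogram of a beat annotation
#'
#' @param object A `beat_annotation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot beat_annotation
#' @export
autoplot.beat_annotation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$rr_s), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_time_s, y = 1000 * .data$rr_s)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "RR interval (ms)") +
    ggplot2::theme_minimal()
}

#' Plot an intervention fit over its data
#'
#' @param object An `intervention_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot intervention_fit
#' @export
autoplot.intervention_fit <- function(object, ...) {
  df <- object$data
  tt <- seq(min(df$beat_time_s), max(df$beat_time_s), length.out = 500)
  ev <- vaso_event(object$t_on, object$t_off, object$delta,
                   object$tau_on, object$tau_recovery)
  curve <- tibble::tibble(t = tt,
                          y = object$baseline_ptt + vaso_response(tt, ev))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beat_time_s,
                                   y = 1000 * .data$ptt_s)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.5) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$t, y = 1000 * .data$y),
                       colour = "red") +
    ggplot2::labs(x = "time (s)", y = "PTT (ms)") +
    ggplot2::theme_minimal()
}

#' Plot a therapy session pressure/gas profile
#'
#' @param object A `session_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot session_profile
#' @export
autoplot.session_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_min,
                                    xmax = .data$end_min,
                                    ymin = 1, ymax = .data$pressure_ata,
                                    fill = .data$gas), alpha = 0.7) +
    ggplot2::labs(x = "treatment time (min)", y = "pressure (ATA)",
                  fill = "gas") +
    ggplot2::theme_minimal()
}

#' Plot a stretch of a recording's channels
#'
#' @param rec A [recording].
#' @param from,to Time window, seconds (default: whole recording).
#' @param channels Channel names to show.
#' @return A ggplot object.
#' @export
plot_recording <- function(rec, from = 0, to = NULL,
                           channels = c("ecg", "ppg_green")) {
  if (!inherits(rec, "recording")) stop_param("`rec` must be a recording.")
  n <- nrow(rec$frames)
  if (is.null(to)) to <- n / rec$sample_rate
  i0 <- max(1L, floor(from * rec$sample_rate) + 1L)
  i1 <- min(n, ceiling(to * rec$sample_rate))
  df <- rec$frames[i0:i1, channels, drop = FALSE]
  df$time_s <- (seq(i0, i1) - 1) / rec$sample_rate
  long <- tidyr::pivot_longer(df, dplyr::all_of(channels),
                              names_to = "channel", values_to = "counts")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$counts)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "counts") +
    ggplot2::theme_minimal()
}
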