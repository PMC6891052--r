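#' Plot a decoding distance matrix
#'
#' @param m Bands x bands distance matrix (e.g. one element of a
#'   `tone_decoding`, or the window-averaged matrix).
#' @param title Plot title.
#' @return A ggplot: presented band x reference band tile map (low distance =
#'   high similarity).
#' @export
plot_distance_matrix <- function(m, title = "Frequency-tuning matrix") {
  df <- tibble::tibble(
    row_band = rep(seq_len(nrow(m)), ncol(m)),
    col_band = rep(seq_len(ncol(m)), each = nrow(m)),
    distance = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$col_band, y = .data$row_band, fill = .data$distance
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(
      x = "reference band", y = "presented band", fill = "distance",
      title = title
    ) +
    ggplot2::theme_minimal()
}

#' Plot decoding-score time series per condition
#'
#' @param scores Tibble with `lag_ms`, `rho`, `condition` (e.g. from
#'   [decoding_scores()] rows bound across conditions, or
#'   `experiment_result$decoding$scores` averaged over subjects).
#' @return A ggplot of rho against lag.
#' @export
plot_decoding_scores <- function(scores) {
  df <- scores |>
    dplyr::group_by(.data$lag_ms, .data$condition) |>
    dplyr::summarise(rho = mean(.data$rho, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$lag_ms, y = .data$rho, color = .data$condition
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "lag relative to chord onset (ms)",
      y = "correlation with ideal matrix (rho)", color = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot a tuning-model fit
#'
#' Shows the pooled distance profile and the fitted gain/tuning curve.
#'
#' @param object A `tuning_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tuning_fit <- function(object, ...) {
  grid <- tibble::tibble(
    df = seq(0, max(object$profile$df), length.out = 200)
  )
  grid$z <- model_predict(object$g, object$sigma, object$c, grid$df)
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$df, y = .data$z)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_cells), alpha = 0.7) +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::scale_size_continuous(range = c(1, 3)) +
    ggplot2::labs(
      x = "relative tone frequency |band difference|",
      y = "distance (a.u.)", size = "cells",
      title = sprintf(
        "g = %.3g, sigma = %.3g, c = %.3g", object$g, object$sigma, object$c
      )
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot an encoding map
#'
#' @param object An `encoding_map`.
#' @param ... Unused.
#' @return A ggplot tile map of rho over channels and time.
#' @export
autoplot.encoding_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = .data$time_ms, y = .data$channel, fill = .data$rho
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "time (ms)", y = "channel", fill = "rho") +
    ggplot2::theme_minimal()
}

#' Plot phase-locking condition maps
#'
#' Channel-averaged PLV per condition over frequency and time.
#'
#' @param plv_by_condition Named list of [plv_map()] outputs.
#' @return A ggplot, faceted by condition.
#' @export
plot_plv <- function(plv_by_condition) {
  df <- purrr::imap_dfr(plv_by_condition, function(pm, cond) {
    avg <- colMeans(pm$plv, dims = 1) # freq x time, averaged over channels
    tibble::tibble(
      condition = cond,
      freq_hz = rep(pm$freqs_hz, length(pm$times_ms)),
      time_ms = rep(pm$times_ms, each = length(pm$freqs_hz)),
      plv = as.vector(avg)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_ms, y = .data$freq_hz, fill = .data$plv
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "time (ms)", y = "frequency (Hz)", fill = "PLV") +
    ggplot2::theme_minimal()
}
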