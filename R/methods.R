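#' Tidy a tuning-model fit
#'
#' @param x A `tuning_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `fixed`.
#' @export
tidy.tuning_fit <- function(x, ...) {
  tibble::tibble(
    term = c("g", "sigma", "c"),
    estimate = c(x$g, x$sigma, x$c),
    fixed = c("g", "sigma", "c") %in% x$fixed
  )
}

#' Glance at a tuning-model fit
#'
#' @param x A `tuning_fit`.
#' @param ... Unused.
#' @return One-row tibble with `rss`, `aic`, `n_points`, `n_free`,
#'   `converged`.
#' @export
glance.tuning_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, aic = x$aic, n_points = x$n_points,
    n_free = x$n_free, converged = x$converged
  )
}

#' Tidy a cluster-test result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return The cluster tibble (one row per cluster) with the cluster-forming
#'   threshold and permutation count as columns.
#' @export
tidy.cluster_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$threshold <- attr(x, "threshold")
  out$n_perm <- attr(x, "n_perm")
  out
}

#' Tidy a Bayesian model-selection result
#'
#' @param x A `bms_result`.
#' @param model_names Optional model labels.
#' @param ... Unused.
#' @return One row per model: `model`, `expected_p`, `exceedance_p`, `alpha`.
#' @export
tidy.bms_result <- function(x, model_names = NULL, ...) {
  tibble::tibble(
    model = model_names %||% paste0("m", seq_len(x$n_models)),
    expected_p = x$expected_p,
    exceedance_p = x$exceedance_p,
    alpha = x$alpha
  )
}

#' Tidy an encoding map into long format
#'
#' @param x An `encoding_map`.
#' @param ... Unused.
#' @return Long tibble: `channel`, `time_ms`, `rho`, `degenerate`.
#' @export
tidy.encoding_map <- function(x, ...) {
  nt <- ncol(x$rho)
  tibble::tibble(
    channel = rep(seq_len(nrow(x$rho)), nt),
    time_ms = rep(x$time_ms %||% seq_len(nt), each = nrow(x$rho)),
    rho = as.vector(x$rho),
    degenerate = as.vector(x$degenerate)
  )
}

#' Tidy a tone-decoding result into long format
#'
#' @param x A `tone_decoding`.
#' @param ... Unused.
#' @return Long tibble: `lag_ms`, `row_band`, `col_band`, `distance`.
#' @export
tidy.tone_decoding <- function(x, ...) {
  purrr::imap_dfr(x$matrices, function(m, i) {
    if (is.null(m)) {
      return(tibble::tibble())
    }
    tibble::tibble(
      lag_ms = x$lags_ms[i],
      row_band = rep(seq_len(nrow(m)), ncol(m)),
      col_band = rep(seq_len(ncol(m)), each = nrow(m)),
      distance = as.vector(m)
    )
  })
}
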