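#' Frequency-axis contrast vector
#'
#' The monotonic contrast assigns increasing values from the lowest to the
#' highest carrier; the quadratic contrast assigns the highest value to the
#' lowest and highest carriers and the lowest value to the middle carrier
#' (a centered square, symmetric V shape under ranking).
#'
#' @param kind `"monotonic"` or `"quadratic"`.
#' @param n_bands Number of frequency bands.
#' @return Numeric contrast vector of length `n_bands`.
#' @export
contrast_vector <- function(kind = c("monotonic", "quadratic"), n_bands = 15) {
  kind <- match.arg(kind)
  r <- seq_len(n_bands)
  switch(kind,
    monotonic = r,
    quadratic = (r - (n_bands + 1) / 2)^2
  )
}

#' Correlate per-band amplitudes with a frequency contrast
#'
#' Computes the Spearman rank correlation between the per-band mean amplitude
#' and the contrast vector, independently for every channel and time point.
#' Channel/time cells with zero amplitude variance across bands get a
#' coefficient of 0 and are flagged degenerate.
#'
#' @param band_means bands x channels x time array of mean amplitudes (one
#'   mean epoch per frequency band).
#' @param contrast Contrast vector of length `dim(band_means)[1]`, e.g. from
#'   [contrast_vector()].
#' @param time_ms Optional time axis for the result.
#' @return An object of class `encoding_map`: list with `rho` (channels x
#'   time), `degenerate` (logical, same shape), `time_ms`, `contrast_kind`.
#' @export
correlate_amplitude_frequency <- function(band_means, contrast,
                                          time_ms = NULL) {
  d <- dim(band_means)
  stopifnot(length(d) == 3, length(contrast) == d[1])
  flat <- matrix(band_means, nrow = d[1]) # bands x (chan*time)
  degen <- apply(flat, 2, function(v) stats::var(v) == 0)
  # Spearman = Pearson on ranks; rank the amplitude axis per cell
  ranks <- apply(flat, 2, rank)
  rc <- rank(contrast)
  rho <- suppressWarnings(as.vector(stats::cor(rc, ranks)))
  rho[degen] <- 0
  structure(
    list(
      rho = matrix(rho, d[2], d[3]),
      degenerate = matrix(degen, d[2], d[3]),
      time_ms = time_ms,
      contrast_kind = attr(contrast, "kind")
    ),
    class = "encoding_map"
  )
}

#' @export
print.encoding_map <- function(x, ...) {
  cat(sprintf(
    "<encoding_map> %d channels x %d time points, |rho| max %.3f\n",
    nrow(x$rho), ncol(x$rho), max(abs(x$rho))
  ))
  invisible(x)
}

#' Per-band mean tone-evoked epochs
#'
#' Averages tone-locked epochs per frequency band (optionally subsampling
#' tones per band for speed) and smooths them, producing the bands x channels
#' x time array that feeds [correlate_amplitude_frequency()].
#'
#' @param rec A (filtered) `meeg_recording`.
#' @param window_ms Epoch window around tone onset.
#' @param smooth_ms Moving-average smoothing window (ms).
#' @param n_bands Number of frequency bands.
#' @param max_per_band Cap on tones per band (subsampled deterministically);
#'   `Inf` for all.
#' @return List with `band_means` (bands x channels x time), `time_ms`,
#'   `n_per_band`.
#' @export
band_mean_epochs <- function(rec, window_ms = c(-200, 400), smooth_ms = 20,
                             n_bands = 15, max_per_band = 100) {
  stopifnot(inherits(rec, "meeg_recording"))
  tones <- rec$events[rec$events$event_kind == "tone", ]
  n_chan <- ncol(rec$data)
  time_ms <- round(window_ms[1]):round(window_ms[2])
  bm <- array(NA_real_, dim = c(n_bands, n_chan, length(time_ms)))
  n_per_band <- integer(n_bands)
  for (b in seq_len(n_bands)) {
    on <- tones$abs_onset_ms[tones$band == b]
    if (length(on) > max_per_band) {
      on <- on[round(seq(1, length(on), length.out = max_per_band))]
    }
    if (length(on) == 0) next
    ep <- epoch_events(rec, on, window_ms)
    n_per_band[b] <- dim(ep$data)[1]
    bm[b, , ] <- colMeans(ep$data, dims = 1)
  }
  if (any(n_per_band == 0)) {
    stop("no tones found for band(s): ",
      paste(which(n_per_band == 0), collapse = ", "),
      call. = FALSE
    )
  }
  list(
    band_means = smooth_epochs(bm, smooth_ms),
    time_ms = time_ms, n_per_band = n_per_band
  )
}
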