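#' Ledoit-Wolf shrinkage covariance
#'
#' Sample covariance (maximum-likelihood normalization) blended toward a
#' scaled identity with the analytically optimal weight, guaranteeing a
#' symmetric positive-definite estimate even for rank-deficient data.
#'
#' @param x Trials x features numeric matrix with at least 2 rows.
#' @return The shrunk covariance matrix; attribute `"shrinkage"` carries the
#'   shrinkage intensity in \[0, 1\].
#' @export
shrinkage_covariance <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2) stop("shrinkage covariance needs at least 2 trials", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  s <- crossprod(xc) / n
  m <- sum(diag(s)) / p
  target <- diag(m, p)
  d2 <- sum((s - target)^2)
  if (d2 <= 0) {
    out <- target
    attr(out, "shrinkage") <- 1
    return(out)
  }
  sq <- rowSums(xc^2)
  b2bar <- (sum(sq^2) - n * sum(s^2)) / n^2
  rho <- min(max(b2bar, 0), d2) / d2
  out <- rho * target + (1 - rho) * s
  attr(out, "shrinkage") <- rho
  out
}

#' Mahalanobis distance of a vector to a class mean
#'
#' @param x Feature vector.
#' @param mu Class mean vector.
#' @param cov Positive-definite covariance matrix.
#' @return `sqrt((x - mu)' cov^-1 (x - mu))`, a nonnegative scalar.
#' @export
mahalanobis_dist <- function(x, mu, cov) {
  delta <- as.numeric(x - mu)
  ch <- tryCatch(chol(cov), error = function(e) {
    stop("covariance is not positive definite", call. = FALSE)
  })
  z <- backsolve(ch, delta, transpose = TRUE)
  sqrt(sum(z^2))
}

#' Ideal tone-frequency distance matrix
#'
#' The reference pattern for perfect decoding: absolute carrier-frequency
#' differences in Hz between every pair of bands (zero diagonal, symmetric,
#' increasing away from the diagonal).
#'
#' @param grid A `frequency_grid`.
#' @return `n_bands` x `n_bands` numeric matrix.
#' @export
ideal_matrix <- function(grid = build_frequency_grid()) {
  f <- grid$carriers_hz
  abs(outer(f, f, "-"))
}

#' Decode tone frequency around chord onsets
#'
#' For each lag relative to chord onset, identifies the tone active at that
#' time point in each eligible trial (the tone whose onset-offset span
#' contains it; trials where the chord itself is playing are excluded),
#' extracts component amplitudes at each response-window offset after the lag
#' time point, and computes leave-one-out Mahalanobis distances (Ledoit-Wolf
#' shrinkage covariance from all training trials) from the held-out trial to
#' each band's training mean. Distances are minimized across window offsets
#' per band and averaged across test trials per presented band, giving one
#' bands x bands distance matrix per lag.
#'
#' Only chords preceded by the isochronous 1000 ms ISI enter the analysis.
#'
#' @param comp Samples x components matrix (basis-projected continuous data).
#' @param events The recording's event table (with `abs_onset_ms`).
#' @param lags_ms Lag grid relative to chord onset (default -500..500 ms in
#'   10 ms steps).
#' @param response_window_ms Offsets after the lag time point at which
#'   amplitudes are read (default 26..126 ms in 5 ms steps).
#' @param n_bands Number of frequency bands.
#' @param isi_ms Required preceding ISI.
#' @param include_targets Include target chords as reference events.
#' @param n_max_trials Optional cap on the number of reference chords
#'   (seeded subsampling), used to equalize sample counts across conditions;
#'   decoding quality depends on the trial count, so condition comparisons
#'   require matched counts.
#' @param subsample_seed Seed for the subsampling.
#' @return An object of class `tone_decoding`: list with `matrices` (list of
#'   bands x bands matrices, one per lag; `NULL` where no lag had usable
#'   trials), `lags_ms`, `n_trials` (per lag), `n_bands`.
#' @export
decode_tone_frequency <- function(comp, events,
                                  lags_ms = seq(-500, 500, by = 10),
                                  response_window_ms = seq(26, 126, by = 5),
                                  n_bands = 15, isi_ms = 1000,
                                  include_targets = FALSE,
                                  n_max_trials = NULL, subsample_seed = 1) {
  chords <- events[events$event_kind == "chord" &
    !is.na(events$preceding_isi_ms) &
    abs(events$preceding_isi_ms - isi_ms) <= 0.5, ]
  if (!include_targets) chords <- chords[chords$chord_kind == "short", ]
  if (nrow(chords) < 4) stop("too few eligible chords for decoding", call. = FALSE)
  if (!is.null(n_max_trials) && nrow(chords) > n_max_trials) {
    keep <- withr_seed(subsample_seed, sort(sample.int(nrow(chords), n_max_trials)))
    chords <- chords[keep, ]
  }
  tones <- events[events$event_kind == "tone", ]
  n_samp <- nrow(comp)
  k_off <- length(response_window_ms)
  mats <- vector("list", length(lags_ms))
  n_used <- integer(length(lags_ms))
  for (li in seq_along(lags_ms)) {
    lag <- lags_ms[li]
    tp <- chords$abs_onset_ms + lag
    band <- active_tone_band(tones, chords$trial, tp)
    feat_at <- round(tp)
    ok <- !is.na(band) & feat_at + min(response_window_ms) >= 1 &
      feat_at + max(response_window_ms) <= n_samp
    if (sum(ok) < 4 || length(unique(band[ok])) < 2) next
    idx <- which(ok)
    x <- array(0, dim = c(length(idx), ncol(comp), k_off))
    for (k in seq_len(k_off)) {
      x[, , k] <- comp[feat_at[idx] + response_window_ms[k], , drop = FALSE]
    }
    d <- cpp_loo_min_dist(x, as.integer(band[idx]), as.integer(n_bands))
    m <- matrix(NA_real_, n_bands, n_bands)
    for (b in unique(band[idx])) {
      m[b, ] <- colMeans(d[band[idx] == b, , drop = FALSE])
    }
    mats[[li]] <- m
    n_used[li] <- length(idx)
  }
  structure(
    list(
      matrices = mats, lags_ms = lags_ms, n_trials = n_used,
      n_bands = n_bands
    ),
    class = "tone_decoding"
  )
}

# band of the tone whose [onset, onset + duration) span contains each time
# point, within the matching trial; NA when none does (e.g. during the chord)
active_tone_band <- function(tones, trials, times_ms) {
  out <- rep(NA_integer_, length(times_ms))
  for (tr in unique(trials)) {
    sel <- which(trials == tr)
    tt <- tones[tones$trial == tr, ]
    if (nrow(tt) == 0) next
    pos <- findInterval(times_ms[sel], tt$abs_onset_ms)
    hit <- pos >= 1 &
      times_ms[sel] < tt$abs_onset_ms[pmax(pos, 1)] + tt$duration_ms[pmax(pos, 1)]
    out[sel[hit]] <- tt$band[pos[hit]]
  }
  out
}

#' Score a decoding matrix against the ideal matrix
#'
#' Spearman rank correlation over all retained (pairwise non-missing) cells.
#' A constant observed matrix scores 0 by convention (flagged degenerate).
#'
#' @param obs Observed bands x bands distance matrix.
#' @param ideal Ideal distance matrix of the same shape.
#' @return Scalar rho in \[-1, 1\]; attribute `"degenerate"` marks the
#'   zero-variance convention. Errors if fewer than 3 cell pairs remain.
#' @export
score_decoding <- function(obs, ideal) {
  stopifnot(all(dim(obs) == dim(ideal)))
  keep <- is.finite(obs) & is.finite(ideal)
  if (sum(keep) < 3) stop("fewer than 3 retained cell pairs", call. = FALSE)
  o <- obs[keep]
  if (stats::var(o) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  stats::cor(o, ideal[keep], method = "spearman")
}

#' Decoding-score time series for a tone decoding result
#'
#' @param dec A `tone_decoding`.
#' @param ideal Ideal distance matrix.
#' @return Tibble with `lag_ms`, `rho`, `n_trials` (NA rho where no matrix).
#' @export
decoding_scores <- function(dec, ideal = ideal_matrix()) {
  stopifnot(inherits(dec, "tone_decoding"))
  rho <- purrr::map_dbl(dec$matrices, function(m) {
    if (is.null(m)) {
      return(NA_real_)
    }
    as.numeric(score_decoding(m, ideal))
  })
  tibble::tibble(lag_ms = dec$lags_ms, rho = rho, n_trials = dec$n_trials)
}

#' Decode chord identity around chord onsets
#'
#' Identical scheme to tone decoding, with two classes (chord A vs B): per
#' time point and test trial, the Mahalanobis distance to the other-identity
#' training mean minus the distance to the same-identity training mean
#' (leave-one-out, shrinkage covariance, windowed minimum across response
#' offsets). Positive values indicate successful discrimination.
#'
#' @param comp Samples x components matrix.
#' @param events Event table with `abs_onset_ms`.
#' @param times_ms Time grid relative to chord onset (default -100..400 ms).
#' @param response_window_ms Offsets after each time point.
#' @param isi_ms Required preceding ISI.
#' @param n_max_trials,subsample_seed Optional seeded cap on the trial count,
#'   as in [decode_tone_frequency()].
#' @return Tibble with `time_ms`, `relative_distance`, `n_trials`.
#' @export
decode_chord <- function(comp, events, times_ms = seq(-100, 400, by = 10),
                         response_window_ms = seq(26, 126, by = 5),
                         isi_ms = 1000, n_max_trials = NULL,
                         subsample_seed = 1) {
  chords <- events[events$event_kind == "chord" &
    events$chord_kind == "short" &
    !is.na(events$preceding_isi_ms) &
    abs(events$preceding_isi_ms - isi_ms) <= 0.5, ]
  if (!is.null(n_max_trials) && nrow(chords) > n_max_trials) {
    keep <- withr_seed(subsample_seed, sort(sample.int(nrow(chords), n_max_trials)))
    chords <- chords[keep, ]
  }
  ids <- chords$chord_identity
  if (length(unique(ids)) < 2 || min(table(ids)) < 2) {
    stop("need at least 2 trials of each chord identity", call. = FALSE)
  }
  cls <- as.integer(factor(ids, levels = c("A", "B")))
  n_samp <- nrow(comp)
  k_off <- length(response_window_ms)
  out <- numeric(length(times_ms))
  n_used <- integer(length(times_ms))
  for (ti in seq_along(times_ms)) {
    feat_at <- round(chords$abs_onset_ms + times_ms[ti])
    ok <- feat_at + min(response_window_ms) >= 1 &
      feat_at + max(response_window_ms) <= n_samp
    if (sum(ok) < 4 || length(unique(cls[ok])) < 2) {
      out[ti] <- NA_real_
      next
    }
    idx <- which(ok)
    x <- array(0, dim = c(length(idx), ncol(comp), k_off))
    for (k in seq_len(k_off)) {
      x[, , k] <- comp[feat_at[idx] + response_window_ms[k], , drop = FALSE]
    }
    d <- cpp_loo_min_dist(x, cls[idx], 2L)
    same <- d[cbind(seq_along(idx), cls[idx])]
    other <- d[cbind(seq_along(idx), 3L - cls[idx])]
    out[ti] <- mean(other - same)
    n_used[ti] <- length(idx)
  }
  tibble::tibble(
    time_ms = times_ms, relative_distance = out,
    n_trials = n_used
  )
}
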