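#' Fixed-window Morlet transform
#'
#' Computes one complex coefficient per epoch, channel, frequency, and
#' requested time point by projecting the epoch onto a complex sinusoid
#' multiplied by a fixed-duration taper (default 2000 ms Hanning), giving
#' frequency-independent temporal resolution. Epochs must cover every
#' requested time point plus half the window on both sides.
#'
#' @param ep An `epoch_set` (time axis in ms at 1 kHz).
#' @param freqs_hz Analysis frequencies (default 0.5--5 Hz in 0.1 Hz steps).
#' @param times_ms Analysis time points relative to the epoch's zero (default
#'   -500..500 ms in 50 ms steps).
#' @param window_ms Fixed analysis window duration (ms).
#' @param taper `"hanning"` or `"none"` (rectangular).
#' @return An object of class `tf_map`: list with `coef` (epochs x channels x
#'   freqs x times complex array), `freqs_hz`, `times_ms`.
#' @export
morlet_transform <- function(ep, freqs_hz = seq(0.5, 5, by = 0.1),
                             times_ms = seq(-500, 500, by = 50),
                             window_ms = 2000,
                             taper = c("hanning", "none")) {
  stopifnot(inherits(ep, "epoch_set"))
  taper <- match.arg(taper)
  half <- window_ms / 2
  if (min(times_ms) - half < min(ep$time_ms) ||
    max(times_ms) + half > max(ep$time_ms)) {
    stop("epochs too short to cover every requested time +/- window/2",
      call. = FALSE
    )
  }
  d <- dim(ep$data)
  nt <- d[3]
  win_n <- round(window_ms) + 1L
  w <- if (taper == "hanning") {
    0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = win_n)))
  } else {
    rep(1, win_n)
  }
  w <- w / sum(w)
  # one real and one imaginary template per (freq, time), placed on the epoch
  # time axis; coefficients come from a single matrix product
  n_f <- length(freqs_hz)
  n_tp <- length(times_ms)
  t_re <- matrix(0, nt, n_f * n_tp)
  t_im <- matrix(0, nt, n_f * n_tp)
  for (j in seq_len(n_tp)) {
    at <- which(ep$time_ms == round(times_ms[j] - half))
    rows <- at + seq_len(win_n) - 1L
    trel <- (seq_len(win_n) - 1 - half) / 1000 # seconds, centered
    for (k in seq_len(n_f)) {
      col <- (j - 1L) * n_f + k
      phase <- 2 * pi * freqs_hz[k] * trel
      t_re[rows, col] <- w * cos(phase)
      t_im[rows, col] <- -w * sin(phase) # conjugate kernel
    }
  }
  flat <- matrix(aperm(ep$data, c(3, 1, 2)), nrow = nt) # time x (epoch*chan)
  cf <- complex(
    real = as.vector(crossprod(flat, t_re)),
    imaginary = as.vector(crossprod(flat, t_im))
  )
  # crossprod gives (epoch*chan) x (freq*time); reorder to ep x chan x f x t
  cf <- array(cf, dim = c(d[1], d[2], n_f, n_tp))
  structure(
    list(coef = cf, freqs_hz = freqs_hz, times_ms = times_ms),
    class = "tf_map"
  )
}

#' Phase-locking value of a set of phases
#'
#' `PLV = |mean over trials of exp(i * phase)|`, bounded in \[0, 1\]:
#' 1 for perfectly aligned phases, 0 for balanced opposition.
#'
#' @param phases Numeric vector of single-trial instantaneous phases
#'   (radians), length >= 2.
#' @return The PLV (scalar).
#' @export
compute_plv <- function(phases) {
  if (length(phases) < 2) stop("PLV needs at least 2 trials", call. = FALSE)
  if (!all(is.finite(phases))) stop("non-finite phases", call. = FALSE)
  Mod(mean(exp(1i * phases)))
}

#' PLV and power maps from a time-frequency decomposition
#'
#' @param tf A `tf_map` from [morlet_transform()].
#' @return List with `plv` and `power` (channels x freqs x times), `n_trials`,
#'   `freqs_hz`, `times_ms`.
#' @export
plv_map <- function(tf) {
  stopifnot(inherits(tf, "tf_map"))
  d <- dim(tf$coef)
  if (d[1] < 2) stop("PLV needs at least 2 trials", call. = FALSE)
  unit <- tf$coef / Mod(tf$coef)
  unit[!is.finite(unit)] <- 0 # zero-amplitude coefficients carry no phase
  plv <- Mod(colMeans(unit, dims = 1))
  pow <- colMeans(Mod(tf$coef)^2, dims = 1)
  list(
    plv = plv, power = pow, n_trials = d[1],
    freqs_hz = tf$freqs_hz, times_ms = tf$times_ms
  )
}

#' Select chords eligible for phase-locking analysis
#'
#' Retains chords that are both preceded and followed by the isochronous ISI
#' (1000 ms); each trial's first chord is excluded (it has no preceding
#' interval from which an expectation could form), as is each trial's last
#' chord (no following interval).
#'
#' @param block A `stimulus_block`.
#' @param isi_ms The isochronous interval (ms).
#' @param tol_ms Tolerance on the interval match.
#' @return Tibble of retained chord events (with `abs_onset_ms` if present in
#'   the block's recording events; otherwise block-relative onsets).
#' @export
select_plv_chords <- function(block, isi_ms = 1000, tol_ms = 0.5) {
  ev <- if (inherits(block, "stimulus_block")) block$events else block
  chords <- ev[ev$event_kind == "chord", ]
  chords <- chords |>
    dplyr::group_by(.data$trial) |>
    dplyr::mutate(following_isi_ms = dplyr::lead(.data$preceding_isi_ms)) |>
    dplyr::ungroup()
  keep <- !is.na(chords$preceding_isi_ms) & !is.na(chords$following_isi_ms) &
    abs(chords$preceding_isi_ms - isi_ms) <= tol_ms &
    abs(chords$following_isi_ms - isi_ms) <= tol_ms
  out <- chords[keep, ]
  if (nrow(out) == 0) warning("no chords satisfy the PLV selection", call. = FALSE)
  out
}
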