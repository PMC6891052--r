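#' Filter a continuous recording
#'
#' High-pass, notch (line frequency and harmonics up to the low-pass corner),
#' and low-pass filtering with fifth-order Butterworth designs applied
#' forward-backward (zero phase, effective order doubled). Output length
#' equals input length.
#'
#' @param rec A `meeg_recording`.
#' @param hp_hz High-pass corner (Hz); `NULL` to skip.
#' @param notch_hz Line frequency (Hz); harmonics up to `lp_hz` are notched;
#'   `NULL` to skip.
#' @param lp_hz Low-pass corner (Hz); `NULL` to skip.
#' @param notch_halfwidth_hz Half-width of each notch stop band.
#' @param order Butterworth order per pass.
#' @return The filtered `meeg_recording`.
#' @export
filter_continuous <- function(rec, hp_hz = 0.1, notch_hz = 50, lp_hz = 200,
                              notch_halfwidth_hz = 2, order = 5) {
  stopifnot(inherits(rec, "meeg_recording"))
  nyq <- rec$sr / 2
  for (f in c(hp_hz, lp_hz)) {
    if (!is.null(f) && f >= nyq) {
      stop("filter cutoff at or above the Nyquist frequency", call. = FALSE)
    }
  }
  filters <- list()
  if (!is.null(hp_hz)) {
    filters <- c(filters, list(signal::butter(order, hp_hz / nyq, "high")))
  }
  if (!is.null(notch_hz)) {
    top <- if (is.null(lp_hz)) nyq * 0.9 else lp_hz
    for (f0 in seq(notch_hz, top, by = notch_hz)) {
      band <- c(f0 - notch_halfwidth_hz, f0 + notch_halfwidth_hz) / nyq
      filters <- c(filters, list(signal::butter(order, band, "stop")))
    }
  }
  if (!is.null(lp_hz)) {
    filters <- c(filters, list(signal::butter(order, lp_hz / nyq, "low")))
  }
  rec$data <- zero_phase_filter(rec$data, filters)
  rec
}

# forward-backward (zero-phase) application of a cascade of IIR designs,
# realized in the frequency domain: the combined gain is the product of the
# squared magnitude responses |H(w)|^2, which is exactly the filtfilt
# response without edge transients. Columns are filtered together.
zero_phase_filter <- function(x, filters) {
  if (length(filters) == 0) {
    return(x)
  }
  one_col <- is.null(dim(x))
  if (one_col) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  nfft <- stats::nextn(n + 2000L) # zero padding limits circular wrap
  w <- 2 * pi * seq(0, nfft - 1) / nfft
  gain <- rep(1, nfft)
  for (flt in filters) {
    e <- exp(-1i * w)
    num <- outer(e, seq_along(flt$b) - 1, "^") %*% flt$b
    den <- outer(e, seq_along(flt$a) - 1, "^") %*% flt$a
    gain <- gain * as.vector(Mod(num / den))^2
  }
  mu <- colMeans(x) # demean so zero padding does not create a step edge
  xp <- rbind(sweep(x, 2, mu), matrix(0, nfft - n, ncol(x)))
  y <- Re(stats::mvfft(stats::mvfft(xp) * gain, inverse = TRUE)) / nfft
  y <- sweep(y[seq_len(n), , drop = FALSE], 2, mu * gain[1], "+")
  if (one_col) y <- y[, 1]
  y
}

#' Rereference EEG channels to their common average
#'
#' Subtracts the across-EEG-channel mean from every EEG channel at each
#' sample; magnetometer and gradiometer channels are untouched.
#'
#' @param rec A `meeg_recording` with at least two EEG-family channels.
#' @return The rereferenced `meeg_recording`.
#' @export
rereference_eeg <- function(rec) {
  stopifnot(inherits(rec, "meeg_recording"))
  idx <- which(rec$sensors$family == "eeg")
  if (length(idx) < 2) {
    stop("average rereferencing needs at least 2 EEG channels", call. = FALSE)
  }
  rec$data[, idx] <- rec$data[, idx] - rowMeans(rec$data[, idx, drop = FALSE])
  rec
}

#' Epoch a recording around event onsets
#'
#' Cuts fixed windows (1 ms resolution) around each event onset. Events whose
#' window exceeds the record bounds are dropped (with a message reporting the
#' count).
#'
#' @param rec A `meeg_recording` (or a plain samples x channels matrix plus
#'   `sr`).
#' @param onsets_ms Event onset times (ms, on the recording's absolute axis).
#' @param window_ms Two-element window `c(t0, t1)` in ms relative to onset.
#' @param labels Optional tibble/data.frame of per-event labels (one row per
#'   onset); retained rows follow the retained events.
#' @return An object of class `epoch_set`: list with `data` (epochs x channels
#'   x time array), `time_ms` (relative time axis), `labels` (tibble),
#'   `n_dropped`.
#' @export
epoch_events <- function(rec, onsets_ms, window_ms = c(-200, 400),
                         labels = NULL) {
  x <- if (inherits(rec, "meeg_recording")) rec$data else rec
  n <- nrow(x)
  t0 <- round(window_ms[1])
  t1 <- round(window_ms[2])
  time_ms <- t0:t1
  start <- round(onsets_ms) + t0 + 1L
  ok <- start >= 1L & (start + length(time_ms) - 1L) <= n
  if (sum(!ok) > 0) {
    message(sum(!ok), " event(s) dropped: window outside record bounds")
  }
  if (!any(ok)) stop("no events remain after bounds check", call. = FALSE)
  start <- start[ok]
  nt <- length(time_ms)
  rows <- outer(0:(nt - 1L), start, "+") # time x epochs sample indices
  slab <- x[as.vector(rows), , drop = FALSE] # (time*epochs) x channels
  ep <- aperm(array(slab, dim = c(nt, length(start), ncol(x))), c(2, 3, 1))
  if (!is.null(labels)) labels <- tibble::as_tibble(labels)[ok, , drop = FALSE]
  structure(
    list(
      data = ep, time_ms = time_ms, labels = labels,
      n_dropped = sum(!ok)
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples (%d..%d ms)\n",
    d[1], d[2], d[3], min(x$time_ms), max(x$time_ms)
  ))
  invisible(x)
}

#' Smooth epochs with a centered moving average
#'
#' The window shrinks (is truncated) at the epoch edges so the epoch length is
#' preserved.
#'
#' @param ep An `epoch_set` (or a numeric matrix/array with time as the last
#'   dimension).
#' @param window_ms Moving-average window length in ms (= samples at 1 kHz).
#' @return The smoothed object, same shape.
#' @export
smooth_epochs <- function(ep, window_ms = 20) {
  if (inherits(ep, "epoch_set")) {
    ep$data <- smooth_epochs(ep$data, window_ms)
    return(ep)
  }
  w <- round(window_ms)
  if (w < 1) stop("`window_ms` must span at least one sample", call. = FALSE)
  d <- dim(ep)
  nt <- d[length(d)]
  if (w > nt) stop("smoothing window longer than the epoch", call. = FALSE)
  m <- matrix(ep, ncol = nt) # rows: all leading dims, cols: time
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  lo <- pmax(seq_len(nt) - floor(w / 2) - 1L, 0L) # exclusive window start
  hi <- pmin(seq_len(nt) + ceiling(w / 2) - 1L, nt)
  sm <- (cs[, hi + 1L, drop = FALSE] - cs[, lo + 1L, drop = FALSE]) /
    rep(hi - lo, each = nrow(m))
  array(sm, dim = d)
}

#' Compute a per-family SVD component basis
#'
#' Each family's channels x time summary matrix (typically the grand-average
#' encoding-correlation map) is decomposed by singular value decomposition;
#' the smallest number of leading modes whose cumulative squared singular
#' values reach `var_target` is retained. Weights are orthonormal within
#' family.
#'
#' @param summaries Named list (by family) of channels x time matrices.
#' @param var_target Retained variance fraction (default 0.95).
#' @return An object of class `component_basis`: per family a list with
#'   `weights` (channels x modes), `n_modes`, `var_explained`, plus attribute
#'   `families`.
#' @export
compute_component_basis <- function(summaries, var_target = 0.95) {
  stopifnot(is.list(summaries), length(summaries) > 0)
  out <- purrr::imap(summaries, function(m, fam) {
    m <- as.matrix(m)
    if (!all(is.finite(m))) stop("non-finite values in summary matrix for ", fam,
      call. = FALSE
    )
    s <- svd(m)
    pow <- s$d^2
    if (sum(pow) == 0) stop("rank-0 summary matrix for family ", fam, call. = FALSE)
    cum <- cumsum(pow) / sum(pow)
    k <- which(cum >= var_target)[1]
    w <- s$u[, seq_len(k), drop = FALSE]
    # SVD sign convention: largest-magnitude loading positive per mode, so
    # summaries projected on bases from similar maps keep consistent signs
    for (j in seq_len(k)) {
      if (w[which.max(abs(w[, j])), j] < 0) w[, j] <- -w[, j]
    }
    list(
      weights = w,
      n_modes = k,
      var_explained = cum[k],
      var_spectrum = pow / sum(pow)
    )
  })
  structure(out, class = "component_basis")
}

#' @export
print.component_basis <- function(x, ...) {
  for (fam in names(x)) {
    cat(sprintf(
      "%s: %d modes (%.1f%% variance)\n", fam, x[[fam]]$n_modes,
      100 * x[[fam]]$var_explained
    ))
  }
  invisible(x)
}

#' Project data through a component basis
#'
#' Applies each family's weights to its channels and concatenates the
#' component axes across families.
#'
#' @param x An `epoch_set`, a `meeg_recording`, or a samples x channels
#'   matrix.
#' @param basis A `component_basis`.
#' @param families Character vector assigning each channel to a family
#'   (taken from the recording's sensors when `x` carries them).
#' @return Same class as `x`, with the channel axis replaced by concatenated
#'   components.
#' @export
apply_basis <- function(x, basis, families = NULL) {
  stopifnot(inherits(basis, "component_basis"))
  if (inherits(x, "meeg_recording")) {
    w <- basis_blockdiag(basis, x$sensors$family)
    x$data <- x$data %*% w
    x$sensors <- NULL
    x$component_families <- attr(w, "component_families")
    return(x)
  }
  if (inherits(x, "epoch_set")) {
    if (is.null(families)) stop("`families` required for epoch sets", call. = FALSE)
    w <- basis_blockdiag(basis, families)
    d <- dim(x$data)
    flat <- matrix(aperm(x$data, c(2, 1, 3)), nrow = d[2]) # chan x (epoch*time)
    proj <- t(w) %*% flat
    x$data <- aperm(array(proj, dim = c(ncol(w), d[1], d[3])), c(2, 1, 3))
    return(x)
  }
  w <- basis_blockdiag(basis, families)
  x %*% w
}

# channels x total-modes block weight matrix following the channel order
basis_blockdiag <- function(basis, families) {
  fams <- names(basis)
  miss <- setdiff(unique(families), fams)
  if (length(miss) > 0) {
    stop("no basis for channel family: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  total_modes <- sum(purrr::map_int(basis[unique(families)], "n_modes"))
  w <- matrix(0, length(families), total_modes)
  col0 <- 0L
  comp_fams <- character(0)
  for (fam in unique(families)) {
    idx <- which(families == fam)
    bw <- basis[[fam]]$weights
    if (nrow(bw) != length(idx)) {
      stop("channel count mismatch with basis for family ", fam, call. = FALSE)
    }
    w[idx, col0 + seq_len(ncol(bw))] <- bw
    comp_fams <- c(comp_fams, rep(fam, ncol(bw)))
    col0 <- col0 + ncol(bw)
  }
  attr(w, "component_families") <- comp_fams
  w
}
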