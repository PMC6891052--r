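#' Construct a synthetic sensor array
#'
#' Channels of three families (EEG-like, magnetometer-like, gradiometer-like)
#' are placed quasi-uniformly on a spherical cap using a Fibonacci lattice
#' with a small seeded jitter, so that every channel has at least one neighbor
#' under the default adjacency radius.
#'
#' @param n_eeg,n_mag,n_grad Channel counts per family (at least one > 0).
#' @param seed Integer seed for the jitter.
#' @param cap_fraction Fraction of the sphere covered by the cap.
#' @return A tibble of class `sensor_array` with columns `channel`, `family`,
#'   `x`, `y`, `z`.
#' @export
make_sensor_array <- function(n_eeg = 20, n_mag = 20, n_grad = 40, seed = 1,
                              cap_fraction = 0.45) {
  counts <- c(eeg = n_eeg, mag = n_mag, grad = n_grad)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("channel counts must be >= 0 with at least one positive", call. = FALSE)
  }
  n_total <- sum(counts)
  # one quasi-uniform lattice over the cap; families interleaved across it so
  # nearest-neighbor distances stay tightly clustered (every channel then has
  # a neighbor under the median-based adjacency radius)
  withr_seed(seed, {
    pos <- fibonacci_cap(n_total, cap_fraction)
    pos <- pos + matrix(stats::rnorm(3 * n_total, sd = 0.002), ncol = 3)
    fam <- sample(rep(names(counts), counts))
  })
  out <- tibble::tibble(
    channel = paste0(fam, "_", sprintf("%03d", seq_len(n_total))),
    family = fam, x = pos[, 1], y = pos[, 2], z = pos[, 3]
  )
  class(out) <- c("sensor_array", class(out))
  out
}

# n quasi-uniform points on the upper spherical cap of unit radius
fibonacci_cap <- function(n, cap_fraction) {
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * cap_fraction * i / n # z in (1 - 2*cap, 1)
  theta <- 2 * pi * i / golden
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Ground-truth parameters for the forward simulation
#'
#' Encodes the effect structure the analysis is designed to recover:
#' a tone-evoked response whose topography varies linearly with frequency
#' rank (monotonic frequency coding), chord-identity-specific topographies, a
#' 1 Hz component phase-locked to chord onsets in the rhythmic condition only
#' (equal amplitude, random phase per trial in the jittered condition), a
#' condition-dependent multiplicative gain envelope on the tone-evoked signal
#' as a function of lag to the upcoming chord, spatially mixed Gaussian noise,
#' and condition-dependent behavioral accuracy.
#'
#' @param tone_topography_slope Amplitude change per frequency rank (a.u./rank).
#' @param kernel_peak_ms,kernel_width_ms Latency and width of the tone-evoked
#'   response kernel (ms); default peak 76 ms.
#' @param chord_amplitude Amplitude of the chord-evoked component (a.u.).
#' @param chord_kernel_peak_ms Latency of the chord-evoked kernel peak (ms).
#' @param entrain_strength Named amplitudes (a.u.) of the 1 Hz component per
#'   condition; the component is phase-locked to chords only in the rhythmic
#'   condition.
#' @param entrain_freq_hz Frequency of the entrained component.
#' @param gain_boost Named multiplicative gain applied inside `boost_window_ms`
#'   per condition (1 = no boost); outside the window the gain is 1.
#' @param boost_window_ms Lag window (ms, relative to the upcoming chord
#'   onset) over which `gain_boost` applies.
#' @param noise_sd Standard deviation of the sensor noise (a.u.).
#' @param spatial_noise_mix Logical; mix the noise across channels with a
#'   random full-rank matrix.
#' @param accuracy Named per-condition probability of a correct target
#'   response.
#' @param rt_meanlog,rt_sdlog Lognormal reaction-time parameters (ms scale).
#' @param seed Seed fixing the random topography patterns and mixing matrix.
#' @return An object of class `ground_truth` (a list of the above).
#' @export
ground_truth <- function(tone_topography_slope = 0.25,
                         kernel_peak_ms = 76, kernel_width_ms = 60,
                         chord_amplitude = 0.5, chord_kernel_peak_ms = 120,
                         entrain_strength = c(rhythmic = 0.5, jittered = 0.5),
                         entrain_freq_hz = 1,
                         gain_boost = c(rhythmic = 1, jittered = 1),
                         boost_window_ms = c(-100, -80),
                         noise_sd = 1, spatial_noise_mix = TRUE,
                         accuracy = c(rhythmic = 0.72, jittered = 0.69),
                         rt_meanlog = log(700), rt_sdlog = 0.18,
                         seed = 99) {
  stopifnot(
    all(entrain_strength >= 0), all(gain_boost > 0), noise_sd >= 0,
    all(accuracy > 0 & accuracy < 1)
  )
  structure(
    list(
      tone_topography_slope = tone_topography_slope,
      kernel_peak_ms = kernel_peak_ms, kernel_width_ms = kernel_width_ms,
      chord_amplitude = chord_amplitude,
      chord_kernel_peak_ms = chord_kernel_peak_ms,
      entrain_strength = entrain_strength, entrain_freq_hz = entrain_freq_hz,
      gain_boost = gain_boost, boost_window_ms = boost_window_ms,
      noise_sd = noise_sd, spatial_noise_mix = spatial_noise_mix,
      accuracy = accuracy, rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
      seed = seed
    ),
    class = "ground_truth"
  )
}

# Hanning-shaped response kernel peaking at peak_ms, support 2*width_ms
response_kernel <- function(peak_ms, width_ms) {
  t <- seq(0, 2 * width_ms)
  k <- 0.5 * (1 - cos(pi * t / width_ms))
  k[t > 2 * width_ms] <- 0
  shift <- peak_ms - width_ms
  if (shift > 0) k <- c(numeric(shift), k)
  k
}

# fixed random unit channel patterns derived from the truth seed
truth_patterns <- function(truth, n_chan) {
  withr_seed(truth$seed, {
    unit <- function() {
      v <- stats::rnorm(n_chan)
      v / sqrt(sum(v^2))
    }
    base <- unit()
    slope_pat <- unit()
    chord_a <- unit()
    chord_b <- unit()
    entrain_pat <- unit()
    mix <- if (truth$spatial_noise_mix) {
      m <- matrix(stats::rnorm(n_chan^2, sd = 1 / sqrt(n_chan)), n_chan)
      diag(m) <- diag(m) + 0.5 # keep well conditioned
      m / sqrt(mean(m^2) * n_chan) * sqrt(1) # unit average output variance
    } else {
      diag(n_chan)
    }
  })
  list(
    base = base, slope = slope_pat, chord = list(A = chord_a, B = chord_b),
    entrain = entrain_pat, mix = mix
  )
}

#' Simulate a sensor-level recording for one stimulus block
#'
#' Forward model: each tone adds `kernel x topography(rank) x gain(lag)`,
#' each chord adds its identity topography under a chord kernel, a 1 Hz
#' component is added phase-locked to chord onsets (rhythmic) or with random
#' per-trial phase (jittered, equal power), and spatially mixed white Gaussian
#' noise is superimposed. Sampled at 1 kHz.
#'
#' @param block A `stimulus_block`.
#' @param sensors A `sensor_array`.
#' @param truth A `ground_truth`.
#' @param seed Integer seed for the noise and random phases.
#' @return An object of class `meeg_recording`: list with `data` (samples x
#'   channels matrix, a.u.), `sr` (1000), `sensors`, `events` (the block's
#'   event table with a per-block absolute time axis), `condition`, `block`.
#' @export
simulate_recording <- function(block, sensors, truth, seed = 1) {
  stopifnot(
    inherits(block, "stimulus_block"), inherits(sensors, "sensor_array"),
    inherits(truth, "ground_truth")
  )
  sr <- 1000
  ev <- block$events
  # lay trials end to end with a pause, as in rendering
  pause_ms <- 600
  tl <- ev |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(trial_end = max(.data$onset_ms + .data$duration_ms)) |>
    dplyr::arrange(.data$trial)
  offset <- c(0, cumsum(tl$trial_end + pause_ms))[seq_len(nrow(tl))]
  ev$abs_onset_ms <- ev$onset_ms + offset[match(ev$trial, tl$trial)]
  n_samp <- ceiling(max(ev$abs_onset_ms + ev$duration_ms)) + 500L
  n_chan <- nrow(sensors)
  pat <- truth_patterns(truth, n_chan)
  kern_tone <- response_kernel(truth$kernel_peak_ms, truth$kernel_width_ms)
  kern_chord <- truth$chord_amplitude *
    response_kernel(truth$chord_kernel_peak_ms, truth$kernel_width_ms)
  mid_rank <- (block$grid$n_bands + 1) / 2

  chords <- ev[ev$event_kind == "chord", ]
  tones <- ev[ev$event_kind == "tone", ]
  # lag of each tone to the next chord within its trial (negative before)
  next_chord <- rep(Inf, nrow(tones))
  for (tr in unique(tones$trial)) {
    sel <- which(tones$trial == tr)
    con <- sort(chords$abs_onset_ms[chords$trial == tr])
    if (length(con) == 0) next
    # first chord onset at or after the tone onset
    idx <- findInterval(tones$abs_onset_ms[sel] - 1e-9, con) + 1L
    next_chord[sel] <- c(con, Inf)[pmin(idx, length(con) + 1L)]
  }
  lag_ms <- tones$abs_onset_ms - next_chord
  gain <- ifelse(
    lag_ms >= truth$boost_window_ms[1] & lag_ms <= truth$boost_window_ms[2],
    truth$gain_boost[[block$condition]], 1
  )
  # the tone contribution is rank 2 in channel space: a common pattern plus a
  # rank-modulated pattern, each an impulse train convolved with the kernel
  at_tone <- round(tones$abs_onset_ms) + 1L
  imp_base <- accumulate_impulses(n_samp, at_tone, gain)
  imp_mod <- accumulate_impulses(
    n_samp, at_tone,
    gain * truth$tone_topography_slope * (tones$band - mid_rank)
  )
  at_chord <- round(chords$abs_onset_ms) + 1L
  imp_a <- accumulate_impulses(n_samp, at_chord[chords$chord_identity == "A"], 1)
  imp_b <- accumulate_impulses(n_samp, at_chord[chords$chord_identity == "B"], 1)
  profiles <- cbind(
    conv_kernel(imp_base, kern_tone),
    conv_kernel(imp_mod, kern_tone),
    conv_kernel(imp_a, kern_chord),
    conv_kernel(imp_b, kern_chord)
  )
  patterns <- rbind(pat$base, pat$slope, pat$chord$A, pat$chord$B)

  withr_seed(seed, {
    # 1 Hz component per trial: phase tied to chord onsets in the rhythmic
    # condition, random per trial otherwise (equal amplitude, hence equal power)
    amp <- truth$entrain_strength[[block$condition]]
    if (amp > 0) {
      osc <- numeric(n_samp)
      for (tr in tl$trial) {
        t0 <- offset[match(tr, tl$trial)]
        idx <- (round(t0) + 1L):min(
          round(t0 + tl$trial_end[match(tr, tl$trial)]), n_samp
        )
        first_chord <- min(chords$abs_onset_ms[chords$trial == tr])
        phase <- if (block$condition == "rhythmic") {
          -2 * pi * truth$entrain_freq_hz * first_chord / 1000
        } else {
          stats::runif(1, 0, 2 * pi)
        }
        osc[idx] <- amp * cos(2 * pi * truth$entrain_freq_hz * (idx - 1) / sr + phase)
      }
      profiles <- cbind(profiles, osc)
      patterns <- rbind(patterns, pat$entrain)
    }
    sig <- profiles %*% patterns
    if (truth$noise_sd > 0) {
      noise <- matrix(stats::rnorm(n_samp * n_chan, sd = truth$noise_sd), n_samp)
      sig <- sig + noise %*% pat$mix
    }
  })
  structure(
    list(
      data = sig, sr = sr, sensors = sensors, events = ev,
      condition = block$condition, block = block
    ),
    class = "meeg_recording"
  )
}

# weighted impulse train of length n (indices beyond n are dropped)
accumulate_impulses <- function(n, at, weights) {
  keep <- at >= 1L & at <= n
  imp <- numeric(n)
  if (any(keep)) {
    tab <- rowsum(rep(weights, length.out = length(at))[keep], at[keep])
    imp[as.integer(rownames(tab))] <- tab[, 1]
  }
  imp
}

# causal FIR convolution: y[t] = sum_j kernel[j] * x[t - j + 1]
conv_kernel <- function(x, kernel) {
  n <- length(x)
  if (all(x == 0) || all(kernel == 0)) {
    return(numeric(n))
  }
  y <- stats::filter(c(numeric(length(kernel) - 1), x), kernel,
    method = "convolution", sides = 1
  )
  as.numeric(y[length(kernel) - 1 + seq_len(n)])
}

#' @export
print.meeg_recording <- function(x, ...) {
  cat(sprintf(
    "<meeg_recording> %s, %d channels x %d samples (%.1f s at %d Hz)\n",
    x$condition, ncol(x$data), nrow(x$data), nrow(x$data) / x$sr, x$sr
  ))
  invisible(x)
}

#' Simulate behavioral responses to a block's targets
#'
#' Each target elicits a response that is correct with the condition's
#' ground-truth accuracy; errors pick the other identity. Reaction times are
#' drawn from a lognormal law.
#'
#' @param block A `stimulus_block`.
#' @param truth A `ground_truth`.
#' @param seed Integer seed.
#' @return A tibble with one row per target: `trial`, `condition`,
#'   `true_identity`, `chosen_identity`, `correct`, `rt_ms`,
#'   `preceding_isi_ms`.
#' @export
simulate_behavior <- function(block, truth, seed = 1) {
  stopifnot(inherits(block, "stimulus_block"), inherits(truth, "ground_truth"))
  targets <- block$events |>
    dplyr::filter(.data$event_kind == "chord", .data$chord_kind == "target")
  acc <- truth$accuracy[[block$condition]]
  withr_seed(seed, {
    correct <- stats::runif(nrow(targets)) < acc
    rt <- stats::rlnorm(nrow(targets), truth$rt_meanlog, truth$rt_sdlog)
  })
  tibble::tibble(
    trial = targets$trial,
    condition = block$condition,
    true_identity = targets$chord_identity,
    chosen_identity = ifelse(correct, targets$chord_identity,
      ifelse(targets$chord_identity == "A", "B", "A")
    ),
    correct = correct,
    rt_ms = rt,
    preceding_isi_ms = targets$preceding_isi_ms
  )
}
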