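#' Build a logarithmically spaced carrier-frequency grid
#'
#' The tone set spans a fixed number of octaves with a constant ratio between
#' consecutive carriers, as used for the pure-tone distractors (default: 15
#' carriers over two octaves, 460--1840 Hz).
#'
#' @param f_min_hz Lowest carrier frequency in Hz (> 0).
#' @param span_octaves Total span of the grid in octaves (> 0).
#' @param n_bands Number of carriers (>= 2).
#'
#' @return An object of class `frequency_grid`: a list with `carriers_hz`
#'   (strictly increasing numeric vector), `n_bands`, `f_min_hz`,
#'   `span_octaves`.
#' @examples
#' grid <- build_frequency_grid()
#' range(grid$carriers_hz)  # 460 1840
#' @export
build_frequency_grid <- function(f_min_hz = 460, span_octaves = 2, n_bands = 15) {
  if (!is.finite(f_min_hz) || f_min_hz <= 0) {
    stop("`f_min_hz` must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(span_octaves) || span_octaves <= 0) {
    stop("`span_octaves` must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(n_bands) || n_bands < 2 || n_bands != round(n_bands)) {
    stop("`n_bands` must be an integer >= 2", call. = FALSE)
  }
  carriers <- f_min_hz * 2^(span_octaves * (seq_len(n_bands) - 1) / (n_bands - 1))
  structure(
    list(
      carriers_hz = carriers,
      n_bands = as.integer(n_bands),
      f_min_hz = f_min_hz,
      span_octaves = span_octaves
    ),
    class = "frequency_grid"
  )
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf(
    "<frequency_grid> %d carriers, %.0f-%.0f Hz (%.2g octaves)\n",
    x$n_bands, min(x$carriers_hz), max(x$carriers_hz), x$span_octaves
  ))
  invisible(x)
}

#' Assign chord member frequencies and band classes
#'
#' Chords A and B share the same six member bands of the grid: two "common"
#' bands with identical amplitudes and four "discriminant" bands whose
#' amplitudes differ between A and B (two louder in A, two louder in B). The
#' two bands louder in A are never both above or both below the two bands
#' louder in B, so the chords cannot be told apart by overall pitch. The
#' remaining bands are classed "adjacent" (grid neighbors of a discriminant
#' band) or "distant".
#'
#' @param grid A `frequency_grid` with at least 8 bands.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @param amplitude_delta Relative amplitude difference of the discriminant
#'   tones (dimensionless), e.g. from [staircase_calibrate()].
#' @param common_amplitude Amplitude of the common tones relative to the mean
#'   discriminant amplitude (exposed as a parameter; default 1).
#'
#' @return A list with `chord_spec` (class `chord_spec`) and `band_classes`, a
#'   tibble with columns `band` and `class` in
#'   \{discriminant, adjacent, distant, common\}.
#' @export
assign_chord_frequencies <- function(grid, seed, amplitude_delta = 0.5,
                                     common_amplitude = 1) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (grid$n_bands < 8) stop("grid must have at least 8 bands", call. = FALSE)
  n <- grid$n_bands
  withr_seed(seed, {
    members <- sort(sample.int(n, 6))
    disc <- sort(sample(members, 4))
    common <- setdiff(members, disc)
    # valid interleaved splits of the sorted discriminant quadruple: the pair
    # louder in A must straddle the pair louder in B ({1,3}/{2,4} or {1,4}/{2,3})
    splits <- list(c(1, 3), c(1, 4), c(2, 3), c(2, 4))
    pick <- splits[[sample.int(4, 1)]]
    high_a <- disc[pick]
    high_b <- setdiff(disc, high_a)
  })
  cls <- rep("distant", n)
  adjacent <- setdiff(intersect(c(disc - 1, disc + 1), seq_len(n)), members)
  cls[adjacent] <- "adjacent"
  cls[disc] <- "discriminant"
  cls[common] <- "common"
  spec <- structure(
    list(
      member_band_indices = members,
      common = common,
      discriminant = disc,
      high_for_a = sort(high_a),
      high_for_b = sort(high_b),
      amplitude_delta = amplitude_delta,
      common_amplitude = common_amplitude
    ),
    class = "chord_spec"
  )
  list(
    chord_spec = spec,
    band_classes = tibble::tibble(band = seq_len(n), class = cls)
  )
}

#' Per-band chord amplitudes for one chord identity
#'
#' Discriminant bands take amplitude `1 + delta/2` when louder in the given
#' chord and `1 - delta/2` otherwise; common bands take `common_amplitude`.
#'
#' @param chord_spec A `chord_spec`.
#' @param identity `"A"` or `"B"`.
#' @return Named numeric vector over the six member bands.
#' @export
chord_amplitudes <- function(chord_spec, identity = c("A", "B")) {
  identity <- match.arg(identity)
  d <- chord_spec$amplitude_delta
  high <- if (identity == "A") chord_spec$high_for_a else chord_spec$high_for_b
  amp <- stats::setNames(numeric(6), chord_spec$member_band_indices)
  amp[as.character(chord_spec$common)] <- chord_spec$common_amplitude
  amp[as.character(chord_spec$discriminant)] <- 1 - d / 2
  amp[as.character(high)] <- 1 + d / 2
  amp
}

#' Generate one stimulus block
#'
#' A block is a sequence of trials; each trial presents 3--5 short chords
#' followed by one long target chord, with chord onsets separated by 1000 ms
#' in the rhythmic condition or by a 50/25/25 mixture (1000 ms / 570--908 ms /
#' 1092--1430 ms, allocated exactly by shuffled assignment) in the jittered
#' condition. Pure tones with random carriers and durations tile every
#' inter-chord interval (and a lead-in before the first chord) without gaps;
#' the last tone before a chord is truncated to close the interval exactly.
#' The number of short chords per trial is drawn balanced over \{3, 4, 5\} so
#' a block of `n_trials` divisible by 3 contains exactly `4 * n_trials` short
#' chords, matching the design count of 240 short chords per 60-trial block.
#'
#' @param condition `"rhythmic"` or `"jittered"`.
#' @param chord_spec A `chord_spec` from [assign_chord_frequencies()].
#' @param n_trials Number of trials (= targets) in the block.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @param grid The `frequency_grid` used for tone carriers.
#' @param params Design constants: list with `isi_ms` (rhythmic ISI),
#'   `jitter_early_ms`, `jitter_late_ms` (ranges), `durations_ms` (short
#'   chord/tone duration set), `target_duration_ms`, `lead_in_ms`,
#'   `tail_ms` (tone fill after target onset).
#'
#' @return An object of class `stimulus_block`: a list with `condition`,
#'   `n_trials`, `seed`, `chord_spec`, `grid`, and `events`, a tibble with one
#'   row per event (`trial`, `event_kind` in \{tone, chord\}, `onset_ms`,
#'   `duration_ms`, `band` (tones), `chord_identity`, `chord_kind` in
#'   \{short, target\}, `preceding_isi_ms`).
#' @export
generate_block <- function(condition = c("rhythmic", "jittered"), chord_spec,
                           n_trials = 60, seed = 1, grid = build_frequency_grid(),
                           params = block_params()) {
  condition <- match.arg(condition)
  stopifnot(inherits(chord_spec, "chord_spec"), inherits(grid, "frequency_grid"))
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  min_isi <- if (condition == "rhythmic") params$isi_ms else params$jitter_early_ms[1]
  if (min_isi <= max(params$target_duration_ms, max(params$durations_ms))) {
    stop("ISI shorter than the maximum chord duration: tone fill is infeasible",
      call. = FALSE
    )
  }
  withr_seed(seed, {
    n_short <- balanced_short_counts(n_trials)
    n_isi <- sum(n_short) # within-trial chord-to-chord intervals
    isis <- if (condition == "rhythmic") {
      rep(params$isi_ms, n_isi)
    } else {
      jittered_isis(n_isi, params)
    }
    isi_idx <- 0L
    trials <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      k <- n_short[tr]
      tr_isis <- isis[isi_idx + seq_len(k)]
      isi_idx <- isi_idx + k
      onsets <- params$lead_in_ms + c(0, cumsum(tr_isis))
      kinds <- c(rep("short", k), "target")
      durs <- c(sample(params$durations_ms, k, replace = TRUE),
                params$target_duration_ms)
      ids <- sample(c("A", "B"), k + 1L, replace = TRUE)
      chords <- tibble::tibble(
        trial = tr, event_kind = "chord", onset_ms = onsets,
        duration_ms = durs, band = NA_integer_, chord_identity = ids,
        chord_kind = kinds, preceding_isi_ms = c(NA_real_, tr_isis)
      )
      gaps <- tibble::tibble(
        from = c(0, onsets + durs),
        to = c(onsets, onsets[k + 1L] + params$tail_ms)
      )
      tones <- purrr::pmap_dfr(gaps, function(from, to) {
        fill_tones(from, to, params$durations_ms, grid$n_bands)
      })
      tones$trial <- tr
      trials[[tr]] <- dplyr::bind_rows(chords, tones)
    }
  })
  events <- dplyr::bind_rows(trials) |>
    dplyr::arrange(.data$trial, .data$onset_ms) |>
    dplyr::select(
      "trial", "event_kind", "onset_ms", "duration_ms", "band",
      "chord_identity", "chord_kind", "preceding_isi_ms"
    )
  structure(
    list(
      condition = condition, n_trials = as.integer(n_trials),
      seed = as.integer(seed), chord_spec = chord_spec, grid = grid,
      events = events, params = params
    ),
    class = "stimulus_block"
  )
}

#' Default block design constants
#'
#' @param isi_ms Rhythmic inter-chord onset interval (ms).
#' @param jitter_early_ms,jitter_late_ms Ranges for the early/late jittered
#'   intervals (ms).
#' @param durations_ms Short chord and tone duration set (ms).
#' @param target_duration_ms Target chord duration (ms).
#' @param lead_in_ms Tone fill before each trial's first chord (ms).
#' @param tail_ms Tone fill after target onset (ms).
#' @return A named list of design constants.
#' @export
block_params <- function(isi_ms = 1000, jitter_early_ms = c(570, 908),
                         jitter_late_ms = c(1092, 1430),
                         durations_ms = seq(23, 43, by = 5),
                         target_duration_ms = 165, lead_in_ms = 1000,
                         tail_ms = 715) {
  list(
    isi_ms = isi_ms, jitter_early_ms = jitter_early_ms,
    jitter_late_ms = jitter_late_ms, durations_ms = durations_ms,
    target_duration_ms = target_duration_ms, lead_in_ms = lead_in_ms,
    tail_ms = tail_ms
  )
}

#' @export
print.stimulus_block <- function(x, ...) {
  n_chord <- sum(x$events$event_kind == "chord")
  cat(sprintf(
    "<stimulus_block> %s, %d trials, %d chords, %d tones\n",
    x$condition, x$n_trials, n_chord, nrow(x$events) - n_chord
  ))
  invisible(x)
}

# balanced draw over {3,4,5}: equal counts of 3s and 5s so the block total is
# exactly 4 * n_trials whenever n_trials is divisible by 3
balanced_short_counts <- function(n_trials) {
  k <- floor(n_trials / 3)
  pool <- c(rep(3L, k), rep(5L, k), rep(4L, n_trials - 2L * k))
  sample(pool)
}

# exact 50/25/25 allocation by shuffled assignment; remainders (when n_isi is
# not divisible by 4) go to the 1000 ms class
jittered_isis <- function(n_isi, params) {
  n_early <- floor(n_isi / 4)
  n_late <- floor(n_isi / 4)
  n_iso <- n_isi - n_early - n_late
  vals <- c(
    rep(params$isi_ms, n_iso),
    stats::runif(n_early, params$jitter_early_ms[1], params$jitter_early_ms[2]),
    stats::runif(n_late, params$jitter_late_ms[1], params$jitter_late_ms[2])
  )
  sample(vals)
}

# tile [from, to) with tones; the last tone is truncated to close the gap
fill_tones <- function(from, to, durations_ms, n_bands) {
  gap <- to - from
  if (gap <= 0) {
    return(tibble::tibble(
      trial = integer(), event_kind = character(), onset_ms = numeric(),
      duration_ms = numeric(), band = integer(), chord_identity = character(),
      chord_kind = character(), preceding_isi_ms = numeric()
    ))
  }
  # draw enough durations to cover the gap, then truncate the last
  n_max <- ceiling(gap / min(durations_ms)) + 1L
  durs <- sample(durations_ms, n_max, replace = TRUE)
  ends <- cumsum(durs)
  n_use <- which(ends >= gap)[1]
  durs <- durs[seq_len(n_use)]
  durs[n_use] <- gap - if (n_use > 1) ends[n_use - 1] else 0
  keep <- durs > 0.5 # drop sub-millisecond slivers
  onsets <- from + c(0, cumsum(durs))[seq_len(n_use)]
  tibble::tibble(
    trial = NA_integer_, event_kind = "tone", onset_ms = onsets[keep],
    duration_ms = durs[keep],
    band = sample.int(n_bands, sum(keep), replace = TRUE),
    chord_identity = NA_character_, chord_kind = NA_character_,
    preceding_isi_ms = NA_real_
  )
}

#' Adaptive one-up-two-down staircase calibration
#'
#' Adjusts the discriminant-tone amplitude difference until the simulated
#' observer converges near the level where two consecutive correct responses
#' are as likely as not (p^2 = 0.5, i.e. ~70.7% correct). The step size is
#' halved at each reversal down to a floor of 1% amplitude. The returned level
#' is the mean of the final reversal points.
#'
#' @param observer Function mapping `amplitude_delta` to the probability of a
#'   correct response (monotone increasing).
#' @param n_trials Number of staircase trials.
#' @param seed Integer seed.
#' @param start Starting amplitude delta.
#' @param step Initial step size.
#' @param step_floor Smallest step size (1% amplitude by default).
#' @param bounds Allowed range for the delta.
#' @param n_final_reversals Number of final reversals averaged for the estimate.
#'
#' @return A list with `amplitude_delta` (the converged level), `n_reversals`,
#'   `track` (tibble: trial, delta, correct, reversal), and `converged`.
#'   Fewer than 4 reversals triggers a non-convergence warning and returns the
#'   best estimate.
#' @export
staircase_calibrate <- function(observer, n_trials = 400, seed = 1,
                                start = 0.6, step = 0.1, step_floor = 0.01,
                                bounds = c(0.001, 1), n_final_reversals = 40) {
  stopifnot(is.function(observer), n_trials >= 1)
  withr_seed(seed, {
    delta <- start
    cur_step <- step
    n_correct_run <- 0L
    last_dir <- 0L # -1 down (harder), +1 up (easier)
    deltas <- numeric(n_trials)
    corrects <- logical(n_trials)
    reversal <- logical(n_trials)
    reversal_levels <- numeric(0)
    for (i in seq_len(n_trials)) {
      deltas[i] <- delta
      p <- observer(delta)
      correct <- stats::runif(1) < p
      corrects[i] <- correct
      dir <- 0L
      if (correct) {
        n_correct_run <- n_correct_run + 1L
        if (n_correct_run >= 2L) {
          dir <- -1L
          n_correct_run <- 0L
        }
      } else {
        dir <- +1L
        n_correct_run <- 0L
      }
      if (dir != 0L) {
        if (last_dir != 0L && dir != last_dir) {
          reversal[i] <- TRUE
          reversal_levels <- c(reversal_levels, delta)
          cur_step <- max(cur_step / 2, step_floor)
        }
        last_dir <- dir
        delta <- min(max(delta + dir * cur_step, bounds[1]), bounds[2])
      }
    }
  })
  n_rev <- length(reversal_levels)
  if (n_rev < 4) {
    warning("staircase did not converge (fewer than 4 reversals); ",
      "returning best estimate",
      call. = FALSE
    )
    est <- if (n_rev > 0) mean(reversal_levels) else deltas[n_trials]
  } else {
    est <- mean(utils::tail(reversal_levels, n_final_reversals))
  }
  list(
    amplitude_delta = est,
    n_reversals = n_rev,
    converged = n_rev >= 4,
    track = tibble::tibble(
      trial = seq_len(n_trials), delta = deltas,
      correct = corrects, reversal = reversal
    )
  )
}

#' Logistic psychometric observer
#'
#' Convenience constructor for a two-alternative observer whose probability of
#' a correct response rises from chance (0.5) to `lapse`-limited ceiling as a
#' logistic function of the amplitude delta.
#'
#' @param threshold Delta at the logistic midpoint.
#' @param slope Logistic slope parameter (delta units).
#' @param lapse Lapse rate (ceiling is `1 - lapse`).
#' @return A function `delta -> P(correct)`.
#' @export
logistic_observer <- function(threshold = 0.3, slope = 0.15, lapse = 0.01) {
  function(delta) {
    0.5 + (0.5 - lapse) / (1 + exp(-(delta - threshold) / slope))
  }
}

#' Render a stimulus block as an audio waveform
#'
#' Tones are sinusoids at their carrier frequency; chords sum their six member
#' sinusoids with identity-dependent amplitudes. Every stimulus is tapered
#' with a 5 ms Hanning rise/fall and scaled so that its RMS over its duration
#' equals a common level (loudness equalization).
#'
#' @param block A `stimulus_block`.
#' @param sample_rate_hz Audio sample rate (default 48000).
#' @param taper_ms Rise/fall time of the Hanning taper.
#' @param rms_level Target RMS per stimulus.
#' @return Numeric waveform vector spanning the block (all trials laid out at
#'   their event onsets).
#' @export
render_audio <- function(block, sample_rate_hz = 48000, taper_ms = 5,
                         rms_level = 0.1) {
  stopifnot(inherits(block, "stimulus_block"))
  if (sample_rate_hz < 2 * max(block$grid$carriers_hz)) {
    stop("`sample_rate_hz` below the Nyquist limit for the highest carrier",
      call. = FALSE
    )
  }
  ev <- block$events
  if (nrow(ev) == 0) {
    return(numeric(0))
  }
  # lay trials end to end with a fixed inter-trial pause
  pause_ms <- 600
  ev <- ev |>
    dplyr::group_by(.data$trial) |>
    dplyr::mutate(trial_end = max(.data$onset_ms + .data$duration_ms)) |>
    dplyr::ungroup()
  trial_len <- ev |>
    dplyr::distinct(.data$trial, .data$trial_end) |>
    dplyr::arrange(.data$trial)
  offset <- c(0, cumsum(trial_len$trial_end + pause_ms))[seq_len(nrow(trial_len))]
  ev$abs_onset_ms <- ev$onset_ms + offset[match(ev$trial, trial_len$trial)]
  total_ms <- max(ev$abs_onset_ms + ev$duration_ms)
  wave <- numeric(ceiling(total_ms / 1000 * sample_rate_hz))
  carriers <- block$grid$carriers_hz
  for (i in seq_len(nrow(ev))) {
    n_samp <- round(ev$duration_ms[i] / 1000 * sample_rate_hz)
    if (n_samp < 2) next
    t <- (seq_len(n_samp) - 1) / sample_rate_hz
    if (ev$event_kind[i] == "tone") {
      s <- sin(2 * pi * carriers[ev$band[i]] * t)
    } else {
      amp <- chord_amplitudes(block$chord_spec, ev$chord_identity[i])
      f <- carriers[as.integer(names(amp))]
      s <- colSums(amp * t(sapply(f, function(fc) sin(2 * pi * fc * t))))
    }
    s <- s * hanning_taper(n_samp, taper_ms, sample_rate_hz)
    r <- sqrt(mean(s^2))
    if (r > 0) s <- s * rms_level / r
    at <- round(ev$abs_onset_ms[i] / 1000 * sample_rate_hz)
    wave[at + seq_len(n_samp)] <- wave[at + seq_len(n_samp)] + s
  }
  wave
}

# raised-cosine onset/offset ramps over taper_ms each side
hanning_taper <- function(n_samp, taper_ms, sample_rate_hz) {
  n_ramp <- min(round(taper_ms / 1000 * sample_rate_hz), floor(n_samp / 2))
  w <- rep(1, n_samp)
  if (n_ramp > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 0.5) / n_ramp))
    w[seq_len(n_ramp)] <- ramp
    w[n_samp + 1 - seq_len(n_ramp)] <- ramp
  }
  w
}

#' Export a block's event table as tab-separated values
#'
#' @param block A `stimulus_block`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_block_events <- function(block, path) {
  ev <- block$events |>
    dplyr::mutate(band_index_or_chord_id = dplyr::coalesce(
      as.character(.data$band), .data$chord_identity
    )) |>
    dplyr::select(
      "trial", "event_kind", "onset_ms", "duration_ms",
      "band_index_or_chord_id", "preceding_isi_ms"
    )
  utils::write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# run code with a local RNG seed without disturbing the caller's RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval(substitute(code), envir = parent.frame())
}
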