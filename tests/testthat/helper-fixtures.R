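# Small builders shared across the test files. Everything is generated in
# code; no stored fixtures.

tiny_grid <- function() build_frequency_grid()

tiny_chord_spec <- function(seed = 7) {
  assign_chord_frequencies(tiny_grid(), seed = seed)
}

tiny_sensors <- function(n_eeg = 4, n_mag = 4, n_grad = 8, seed = 1) {
  make_sensor_array(n_eeg, n_mag, n_grad, seed = seed)
}

# a bare recording object with known content, bypassing the forward model
manual_recording <- function(data, sensors = tiny_sensors(), events = NULL) {
  structure(
    list(
      data = data, sr = 1000, sensors = sensors,
      events = events, condition = "rhythmic", block = NULL
    ),
    class = "meeg_recording"
  )
}

# synthetic component series + event table with perfectly band-specific
# responses: one isolated tone per chord at exactly `target_lag` ms before the
# chord; the active band's pattern is emitted over the decoding response
# window, so decoding at that lag is clean (no overlapping responses)
band_coded_comp <- function(n_chords = 45, seed = 5, noise_sd = 0.02,
                            signal = 1, target_lag = -300, n_bands = 15) {
  set.seed(seed)
  isi <- 1000
  lead <- 1200
  onsets <- lead + isi * (seq_len(n_chords) - 1)
  chords <- tibble::tibble(
    trial = 1L, event_kind = "chord", abs_onset_ms = onsets,
    duration_ms = 30, band = NA_integer_, chord_identity =
      sample(c("A", "B"), n_chords, replace = TRUE),
    chord_kind = "short",
    preceding_isi_ms = c(NA, diff(onsets))
  )
  bands <- rep(seq_len(n_bands), length.out = n_chords)[sample(n_chords)]
  tone_on <- onsets + target_lag
  tones <- tibble::tibble(
    trial = 1L, event_kind = "tone", abs_onset_ms = tone_on,
    duration_ms = 40, band = bands,
    chord_identity = NA_character_, chord_kind = NA_character_,
    preceding_isi_ms = NA_real_
  )
  n_samp <- max(onsets) + 1200
  p <- n_bands
  # graded band code: neighboring bands share pattern overlap, so distances
  # grow smoothly with band separation as the ideal matrix expects
  patt <- sapply(seq_len(n_bands), function(b) {
    v <- dnorm(seq_len(p), mean = b, sd = 1.5)
    v / sqrt(sum(v^2))
  })
  comp <- matrix(rnorm(n_samp * p, sd = noise_sd), n_samp, p)
  for (i in seq_len(nrow(tones))) {
    rows <- tone_on[i] + 26:126
    comp[rows, ] <- comp[rows, ] +
      signal * rep(patt[, bands[i]], each = length(rows))
  }
  list(comp = comp, events = dplyr::bind_rows(chords, tones))
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
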