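test_that("frequency grid is log-spaced over the requested span", {
  g <- build_frequency_grid(460, 2, 15)
  expect_equal(g$carriers_hz[1], 460)
  expect_equal(max(g$carriers_hz), 1840, tolerance = 1e-9)
  ratios <- g$carriers_hz[-1] / g$carriers_hz[-15]
  expect_equal(ratios, rep(2^(2 / 14), 14), tolerance = 1e-9)
  expect_true(all(diff(g$carriers_hz) > 0))

  expect_equal(build_frequency_grid(100, 1, 2)$carriers_hz, c(100, 200))
  expect_error(build_frequency_grid(-1, 2, 15), "positive")
  expect_error(build_frequency_grid(460, 2, 1), "n_bands")
  expect_error(build_frequency_grid(Inf, 2, 15), "positive")
})

test_that("chord assignment satisfies the design constraints for many seeds", {
  g <- tiny_grid()
  for (seed in 1:150) {
    a <- assign_chord_frequencies(g, seed)
    cs <- a$chord_spec
    expect_length(cs$member_band_indices, 6)
    expect_length(cs$common, 2)
    expect_length(cs$discriminant, 4)
    expect_length(intersect(cs$common, cs$discriminant), 0)
    # pitch constraint: the pair louder in A straddles the pair louder in B
    expect_false(all(cs$high_for_a > max(cs$high_for_b)) ||
      all(cs$high_for_a < min(cs$high_for_b)))
    tab <- table(a$band_classes$class)
    expect_equal(unname(tab[["discriminant"]]), 4)
    expect_equal(unname(tab[["common"]]), 2)
    expect_equal(sum(tab), 15)
    expect_equal(sum(tab) - tab[["discriminant"]] - tab[["common"]], 9)
  }
  # deterministic given seed
  expect_identical(
    assign_chord_frequencies(g, 42),
    assign_chord_frequencies(g, 42)
  )
})

test_that("chord amplitudes reflect identity and delta", {
  a <- tiny_chord_spec()
  ampA <- chord_amplitudes(a$chord_spec, "A")
  ampB <- chord_amplitudes(a$chord_spec, "B")
  d <- a$chord_spec$amplitude_delta
  expect_equal(sort(names(ampA)), sort(as.character(a$chord_spec$member_band_indices)))
  common <- as.character(a$chord_spec$common)
  expect_equal(ampA[common], ampB[common])
  hi_a <- as.character(a$chord_spec$high_for_a)
  expect_equal(unname(ampA[hi_a]), rep(1 + d / 2, 2))
  expect_equal(unname(ampB[hi_a]), rep(1 - d / 2, 2))
})

test_that("rhythmic blocks have constant 1000 ms ISIs and jittered blocks the exact mixture", {
  a <- tiny_chord_spec()
  br <- generate_block("rhythmic", a$chord_spec, n_trials = 12, seed = 3)
  isis <- br$events$preceding_isi_ms[br$events$event_kind == "chord"]
  isis <- isis[!is.na(isis)]
  expect_true(all(isis == 1000))

  bj <- generate_block("jittered", a$chord_spec, n_trials = 12, seed = 3)
  ji <- bj$events$preceding_isi_ms[bj$events$event_kind == "chord"]
  ji <- ji[!is.na(ji)]
  expect_equal(mean(ji == 1000), 0.5)
  expect_equal(mean(ji >= 570 & ji <= 908), 0.25)
  expect_equal(mean(ji >= 1092 & ji <= 1430), 0.25)
})

test_that("trials contain 3-5 short chords and one 165 ms target", {
  a <- tiny_chord_spec()
  b <- generate_block("rhythmic", a$chord_spec, n_trials = 9, seed = 11)
  ch <- b$events[b$events$event_kind == "chord", ]
  per_trial <- split(ch, ch$trial)
  for (tr in per_trial) {
    expect_equal(sum(tr$chord_kind == "target"), 1)
    expect_true(tr$chord_kind[nrow(tr)] == "target")
    expect_equal(tr$duration_ms[tr$chord_kind == "target"], 165)
    n_short <- sum(tr$chord_kind == "short")
    expect_true(n_short >= 3 && n_short <= 5)
    expect_true(all(tr$duration_ms[tr$chord_kind == "short"] %in% seq(23, 43, 5)))
  }
  # a 60-trial block carries the design count of 240 short chords
  b60 <- generate_block("rhythmic", a$chord_spec, n_trials = 60, seed = 2)
  expect_equal(sum(b60$events$chord_kind == "short", na.rm = TRUE), 240)
})

test_that("tone fill tiles every inter-chord interval without gaps or overlaps", {
  a <- tiny_chord_spec()
  for (cond in c("rhythmic", "jittered")) {
    b <- generate_block(cond, a$chord_spec, n_trials = 6, seed = 9)
    ok <- b$events |>
      dplyr::group_by(trial) |>
      dplyr::arrange(onset_ms, .by_group = TRUE) |>
      dplyr::summarise(
        gapless = all(abs(
          diff(onset_ms) - duration_ms[-dplyr::n()]
        ) < 0.51) # sub-ms slivers may be dropped at interval ends
      )
    expect_true(all(ok$gapless))
  }
})

test_that("block generation is bit-reproducible under a fixed seed", {
  a <- tiny_chord_spec()
  b1 <- generate_block("jittered", a$chord_spec, n_trials = 5, seed = 123)
  b2 <- generate_block("jittered", a$chord_spec, n_trials = 5, seed = 123)
  expect_identical(b1$events, b2$events)
  b3 <- generate_block("jittered", a$chord_spec, n_trials = 5, seed = 124)
  expect_false(identical(b1$events, b3$events))
})

test_that("infeasible ISI parameters are rejected", {
  a <- tiny_chord_spec()
  p <- block_params(isi_ms = 100)
  expect_error(
    generate_block("rhythmic", a$chord_spec, n_trials = 2, seed = 1, params = p),
    "infeasible"
  )
})

test_that("the staircase converges near the one-up-two-down fixed point", {
  obs <- logistic_observer()
  s <- staircase_calibrate(obs, n_trials = 400, seed = 5)
  expect_true(s$converged)
  # accuracy at the converged level is close to sqrt(0.5) = 70.7%
  expect_gt(obs(s$amplitude_delta), 0.64)
  expect_lt(obs(s$amplitude_delta), 0.77)
  # deterministic given seed
  s2 <- staircase_calibrate(obs, n_trials = 400, seed = 5)
  expect_identical(s$amplitude_delta, s2$amplitude_delta)
})

test_that("a ceiling observer drives the staircase to the lower bound", {
  s <- suppressWarnings(staircase_calibrate(function(d) 1,
    n_trials = 300, seed = 1, bounds = c(0.001, 1)
  ))
  expect_lt(s$amplitude_delta, 0.05)
  expect_equal(min(s$track$delta), 0.001)
})

test_that("too few reversals triggers a non-convergence warning", {
  expect_warning(
    staircase_calibrate(function(d) 1, n_trials = 5, seed = 1),
    "did not converge"
  )
})

test_that("rendered audio has correct sample counts, taper, and loudness equalization", {
  # single 33 ms 460 Hz tone at 48 kHz: 1584 samples, 240-sample ramps
  g <- tiny_grid()
  a <- tiny_chord_spec()
  events <- tibble::tibble(
    trial = 1L, event_kind = "tone", onset_ms = 0, duration_ms = 33,
    band = 1L, chord_identity = NA_character_, chord_kind = NA_character_,
    preceding_isi_ms = NA_real_
  )
  blk <- structure(
    list(
      condition = "rhythmic", n_trials = 1L, seed = 1L,
      chord_spec = a$chord_spec, grid = g, events = events,
      params = block_params()
    ),
    class = "stimulus_block"
  )
  w <- render_audio(blk, 48000)
  expect_equal(length(w), 1584)
  # ramps: amplitude grows over the first 240 samples and shrinks over the last
  expect_lt(max(abs(w[1:60])), max(abs(w[100:240])))
  expect_lt(max(abs(w[(1584 - 59):1584])), max(abs(w[(1584 - 240):(1584 - 100)])))

  # loudness equalization: two equal-duration tones at different carriers
  # have equal RMS within 1%
  events2 <- dplyr::bind_rows(events, dplyr::mutate(events, band = 15L, onset_ms = 33))
  blk$events <- events2
  w2 <- render_audio(blk, 48000)
  r1 <- sqrt(mean(w2[1:1584]^2))
  r2 <- sqrt(mean(w2[1585:3168]^2))
  expect_equal(r1, r2, tolerance = 0.01)

  # empty block
  blk$events <- events[0, ]
  expect_length(render_audio(blk, 48000), 0)
  # aliasing guard
  blk$events <- events
  expect_error(render_audio(blk, 3000), "Nyquist")
})

test_that("block event tables export as tab-separated text", {
  a <- tiny_chord_spec()
  b <- generate_block("rhythmic", a$chord_spec, n_trials = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_block_events(b, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(b$events))
  expect_true(all(c("trial", "event_kind", "onset_ms") %in% names(back)))
})
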