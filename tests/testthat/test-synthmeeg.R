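test_that("sensor arrays have the requested families and are reproducible", {
  s <- make_sensor_array(10, 10, 20, seed = 3)
  expect_equal(nrow(s), 40)
  expect_equal(as.integer(table(s$family)[c("eeg", "mag", "grad")]), c(10, 10, 20))
  expect_false(any(duplicated(s$channel)))
  expect_identical(s, make_sensor_array(10, 10, 20, seed = 3))
  expect_error(make_sensor_array(0, 0, 0), "at least one")
})

test_that("every channel has a neighbor under the default adjacency radius", {
  for (seed in 1:5) {
    s <- make_sensor_array(8, 8, 16, seed = seed)
    adj <- channel_adjacency(s)
    # brute-force check against pairwise distances
    pos <- as.matrix(s[, c("x", "y", "z")])
    d <- as.matrix(dist(pos))
    diag(d) <- Inf
    radius <- 1.3 * median(apply(d, 1, min))
    expect_identical(unname(adj), unname(d <= radius & row(d) != col(d)))
    expect_true(all(rowSums(adj) >= 1))
  }
})

test_that("the noiseless forward model adds kernel x topography at each tone", {
  sens <- tiny_sensors()
  truth <- ground_truth(
    noise_sd = 0, entrain_strength = c(rhythmic = 0, jittered = 0),
    spatial_noise_mix = FALSE
  )
  # one isolated tone, one chord far away
  events <- tibble::tibble(
    trial = 1L,
    event_kind = c("tone", "chord"),
    onset_ms = c(500, 5000),
    duration_ms = c(33, 30),
    band = c(4L, NA),
    chord_identity = c(NA, "A"),
    chord_kind = c(NA, "short"),
    preceding_isi_ms = NA_real_
  )
  g <- tiny_grid()
  a <- tiny_chord_spec()
  blk <- structure(
    list(
      condition = "rhythmic", n_trials = 1L, seed = 1L,
      chord_spec = a$chord_spec, grid = g, events = events,
      params = block_params()
    ),
    class = "stimulus_block"
  )
  rec <- simulate_recording(blk, sens, truth, seed = 1)
  pat <- rhythmgain:::truth_patterns(truth, nrow(sens))
  kern <- rhythmgain:::response_kernel(truth$kernel_peak_ms, truth$kernel_width_ms)
  topo <- pat$base + truth$tone_topography_slope * (4 - 8) * pat$slope
  seg <- rec$data[500 + seq_along(kern), ]
  expect_equal(seg, outer(kern, topo), tolerance = 1e-12)
  # additivity: doubling the noise leaves the noiseless component unchanged
  truth2 <- ground_truth(
    noise_sd = 2, entrain_strength = c(rhythmic = 0, jittered = 0),
    spatial_noise_mix = FALSE
  )
  rec2 <- simulate_recording(blk, sens, truth2, seed = 1)
  noise2 <- rec2$data[500 + seq_along(kern), ] - outer(kern, topo)
  truth1 <- ground_truth(
    noise_sd = 1, entrain_strength = c(rhythmic = 0, jittered = 0),
    spatial_noise_mix = FALSE
  )
  rec1 <- simulate_recording(blk, sens, truth1, seed = 1)
  noise1 <- rec1$data[500 + seq_along(kern), ] - outer(kern, topo)
  expect_equal(noise2, 2 * noise1, tolerance = 1e-10)
})

test_that("the gain envelope multiplies tone responses inside the boost window", {
  sens <- tiny_sensors()
  g <- tiny_grid()
  a <- tiny_chord_spec()
  # tone onset at lag -90 from the chord: inside the default [-100, -80] window
  events <- tibble::tibble(
    trial = 1L,
    event_kind = c("tone", "chord"),
    onset_ms = c(910, 1000),
    duration_ms = c(33, 30),
    band = c(8L, NA),
    chord_identity = c(NA, "A"),
    chord_kind = c(NA, "short"),
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
  mk <- function(boost) {
    truth <- ground_truth(
      noise_sd = 0, entrain_strength = c(rhythmic = 0, jittered = 0),
      chord_amplitude = 0, spatial_noise_mix = FALSE,
      gain_boost = c(rhythmic = boost, jittered = 1)
    )
    simulate_recording(blk, sens, truth, seed = 1)$data[920, ]
  }
  expect_equal(mk(3), 3 * mk(1), tolerance = 1e-12)
})

test_that("simulated recordings are reproducible and condition-tagged", {
  sens <- tiny_sensors()
  a <- tiny_chord_spec()
  blk <- generate_block("jittered", a$chord_spec, n_trials = 2, seed = 5)
  truth <- ground_truth()
  r1 <- simulate_recording(blk, sens, truth, seed = 9)
  r2 <- simulate_recording(blk, sens, truth, seed = 9)
  expect_identical(r1$data, r2$data)
  expect_equal(r1$sr, 1000)
  expect_equal(r1$condition, "jittered")
  expect_true(all(is.finite(r1$data)))
})

test_that("simulated behavior matches the ground-truth accuracy", {
  a <- tiny_chord_spec()
  blk <- generate_block("rhythmic", a$chord_spec, n_trials = 30, seed = 2)
  t1 <- ground_truth(accuracy = c(rhythmic = 0.999, jittered = 0.5))
  resp <- simulate_behavior(blk, t1, seed = 3)
  expect_equal(nrow(resp), 30)
  expect_true(all(resp$correct))
  expect_true(all(resp$chosen_identity == resp$true_identity))
  expect_true(all(resp$rt_ms > 0))

  # chance-level accuracy gives d' near 0 over many targets
  blk2 <- generate_block("jittered", a$chord_spec, n_trials = 60, seed = 4)
  t2 <- ground_truth(accuracy = c(rhythmic = 0.5, jittered = 0.5))
  ds <- sapply(1:20, function(s) {
    r <- simulate_behavior(blk2, t2, seed = s)
    signal_detection(r$true_identity, r$chosen_identity)$dprime
  })
  expect_lt(abs(mean(ds)), 0.15)
})

test_that("1 Hz power matches across conditions when entrain amplitudes are equal", {
  # phase alignment differs between conditions, power does not
  sens <- tiny_sensors(2, 2, 2)
  a <- tiny_chord_spec()
  truth <- ground_truth(
    noise_sd = 0.1, entrain_strength = c(rhythmic = 0.5, jittered = 0.5),
    chord_amplitude = 0, tone_topography_slope = 0, spatial_noise_mix = FALSE
  )
  pow <- sapply(c("rhythmic", "jittered"), function(cond) {
    ps <- sapply(1:4, function(s) {
      blk <- generate_block(cond, a$chord_spec, n_trials = 4, seed = s)
      rec <- simulate_recording(blk, sens, truth, seed = 100 + s)
      sel <- select_plv_chords(rec$events)
      ep <- suppressMessages(
        epoch_events(rec, sel$abs_onset_ms, c(-1100, 1100))
      )
      tf <- morlet_transform(ep, freqs_hz = 1, times_ms = 0)
      mean(Mod(tf$coef)^2)
    })
    mean(ps)
  })
  expect_equal(unname(pow[1]), unname(pow[2]), tolerance = 0.15)
})
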