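test_that("continuous filtering removes DC, keeps the passband, and notches line noise", {
  n <- 10000
  t <- (1:n) / 1000
  sens <- tiny_sensors(2, 1, 1)
  x <- cbind(5, sin(2 * pi * 10 * t), sin(2 * pi * 50 * t), rnorm(n))
  rec <- manual_recording(x, sens)
  out <- filter_continuous(rec)$data
  expect_equal(nrow(out), n)
  # DC channel suppressed
  expect_lt(max(abs(out[, 1])), 1e-6)
  # 10 Hz passband preserved within 5% (interior samples)
  expect_equal(max(abs(out[3000:7000, 2])), 1, tolerance = 0.05)
  # 50 Hz attenuated by at least 20 dB
  atten <- 20 * log10(sd(out[3000:7000, 3]) / sd(x[3000:7000, 3]))
  expect_lt(atten, -20)
  expect_error(filter_continuous(rec, lp_hz = 600), "Nyquist")
})

test_that("zero-phase filtering introduces no group delay", {
  n <- 8000
  set.seed(2)
  # bandlimited input
  src <- manual_recording(matrix(rnorm(n), ncol = 1), tiny_sensors(2, 1, 1))
  x <- filter_continuous(src, hp_hz = NULL, notch_hz = NULL, lp_hz = 30)$data[, 1]
  y <- filter_continuous(
    manual_recording(matrix(x, ncol = 1), tiny_sensors(2, 1, 1))
  )$data[, 1]
  cc <- ccf(x, y, lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("average rereferencing zeroes the EEG mean and leaves MEG untouched", {
  set.seed(1)
  sens <- tiny_sensors(4, 2, 2)
  x <- matrix(rnorm(100 * 8), 100, 8)
  rec <- manual_recording(x, sens)
  out <- rereference_eeg(rec)
  eeg <- which(sens$family == "eeg")
  expect_lt(max(abs(rowMeans(out$data[, eeg]))), 1e-12)
  expect_identical(out$data[, -eeg], x[, -eeg])

  # identical eeg signals become zero; (x, -x) pairs are unchanged
  x2 <- x
  x2[, eeg] <- x[, eeg[1]]
  expect_lt(max(abs(rereference_eeg(manual_recording(x2, sens))$data[, eeg])), 1e-12)
  x3 <- x
  x3[, eeg] <- cbind(x[, 1], -x[, 1], x[, 2], -x[, 2])
  expect_equal(rereference_eeg(manual_recording(x3, sens))$data, x3)

  sens1 <- tiny_sensors(0, 2, 2)
  expect_error(
    rereference_eeg(manual_recording(x[, 1:4], sens1)),
    "at least 2 EEG"
  )
})

test_that("epoching cuts the requested windows and drops out-of-bounds events", {
  x <- matrix(0, 1000, 2)
  x[501, 1] <- 1 # impulse at 500 ms
  ep <- epoch_events(x, 500, c(-200, 400))
  expect_equal(dim(ep$data), c(1, 2, 601))
  expect_equal(ep$time_ms, -200:400)
  expect_equal(ep$data[1, 1, ], c(rep(0, 200), 1, rep(0, 400)))

  expect_message(
    ep2 <- epoch_events(x, c(10, 500), c(-200, 400)),
    "dropped"
  )
  expect_equal(dim(ep2$data)[1], 1)
  expect_equal(ep2$n_dropped, 1)
  expect_error(
    suppressMessages(epoch_events(x, 10, c(-200, 400))),
    "no events"
  )
})

test_that("moving-average smoothing has the boxcar impulse response with truncated edges", {
  ep <- array(0, dim = c(1, 1, 101))
  ep[1, 1, 51] <- 1
  sm <- smooth_epochs(ep, 20)
  expect_equal(sum(sm[1, 1, ] > 0), 20)
  expect_equal(max(sm), 1 / 20, tolerance = 1e-12)

  cst <- array(3, dim = c(2, 2, 50))
  expect_equal(smooth_epochs(cst, 20), cst)

  # white-noise variance is reduced by about the window length (interior)
  set.seed(3)
  wn <- array(rnorm(4 * 3 * 5000), dim = c(4, 3, 5000))
  smn <- smooth_epochs(wn, 20)
  ratio <- var(as.vector(smn[, , 100:4900])) / var(as.vector(wn))
  expect_equal(ratio, 1 / 20, tolerance = 0.15)

  expect_error(smooth_epochs(array(0, c(1, 1, 10)), 20), "longer")
})

test_that("the component basis keeps the smallest mode set reaching the variance target", {
  # rank-1 input: one mode, all the variance
  u <- rnorm(12)
  v <- rnorm(300)
  b1 <- compute_component_basis(list(eeg = outer(u, v)))
  expect_equal(b1$eeg$n_modes, 1)
  expect_equal(b1$eeg$var_explained, 1, tolerance = 1e-12)

  # random input: target reached, and minimally so
  set.seed(4)
  m <- matrix(rnorm(12 * 300), 12)
  b <- compute_component_basis(list(eeg = m), var_target = 0.95)
  k <- b$eeg$n_modes
  cum <- cumsum(b$eeg$var_spectrum)
  expect_gte(cum[k], 0.95)
  if (k > 1) expect_lt(cum[k - 1], 0.95)
  # weights orthonormal
  w <- b$eeg$weights
  expect_equal(crossprod(w), diag(ncol(w)), tolerance = 1e-12)

  expect_error(compute_component_basis(list(eeg = matrix(0, 3, 5))), "rank-0")
})

test_that("basis projection preserves variance when all modes are kept", {
  set.seed(5)
  sens <- tiny_sensors(4, 4, 4)
  x <- matrix(rnorm(500 * 12), 500, 12)
  maps <- lapply(split(seq_len(12), sens$family), function(idx) {
    matrix(rnorm(length(idx) * 50), length(idx))
  })
  basis_full <- compute_component_basis(maps, var_target = 1)
  rec <- manual_recording(x, sens)
  proj <- apply_basis(rec, basis_full)
  expect_equal(sum(proj$data^2), sum(x^2), tolerance = 1e-9)

  # epoch-space projection agrees with continuous projection
  ep <- suppressMessages(epoch_events(rec, c(100, 300), c(-50, 50)))
  pe <- apply_basis(ep, basis_full, families = sens$family)
  expect_equal(
    pe$data[1, , ],
    t(proj$data[100 + (-50:50) + 1, ]),
    tolerance = 1e-12
  )
  # channel mismatch is an error
  expect_error(apply_basis(x[, 1:5], basis_full, families = sens$family[1:5]))
})
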