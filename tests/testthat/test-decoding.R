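test_that("shrinkage covariance matches an independently coded Ledoit-Wolf oracle", {
  # reference implementation written directly from the closed-form intensity
  lw_oracle <- function(x) {
    n <- nrow(x)
    p <- ncol(x)
    xc <- sweep(x, 2, colMeans(x))
    s <- t(xc) %*% xc / n
    m <- mean(diag(s))
    d2 <- sum((s - m * diag(p))^2)
    b2bar <- 0
    for (k in seq_len(n)) {
      b2bar <- b2bar + sum((tcrossprod(xc[k, ]) - s)^2)
    }
    b2 <- min(b2bar / n^2, d2)
    (b2 / d2) * m * diag(p) + (1 - b2 / d2) * s
  }
  set.seed(20)
  for (i in 1:25) {
    x <- matrix(rnorm(50 * 10), 50, 10)
    expect_equal(shrinkage_covariance(x), lw_oracle(x),
      tolerance = 1e-10, ignore_attr = TRUE
    )
  }
  # rank-1 trials still give a nonsingular estimate
  x1 <- outer(rnorm(20), rnorm(6))
  s1 <- shrinkage_covariance(x1)
  expect_no_error(chol(s1))
  expect_true(attr(s1, "shrinkage") > 0)
  expect_error(shrinkage_covariance(matrix(1, 1, 3)), "at least 2")
})

test_that("Mahalanobis distances match explicit-inverse computation", {
  expect_equal(mahalanobis_dist(c(1, 0), c(0, 0), diag(2)), 1)
  expect_equal(mahalanobis_dist(c(2, 0), c(0, 0), diag(c(4, 1))), 1)
  set.seed(21)
  for (i in 1:100) {
    p <- 5
    a <- matrix(rnorm(p * p), p)
    cov <- crossprod(a) + diag(p)
    x <- rnorm(p)
    mu <- rnorm(p)
    direct <- sqrt(drop(t(x - mu) %*% solve(cov) %*% (x - mu)))
    expect_equal(mahalanobis_dist(x, mu, cov), direct, tolerance = 1e-8)
  }
  expect_equal(mahalanobis_dist(1:3, 1:3, diag(3)), 0)
})

test_that("the LOO decoding kernel equals a plain R reference implementation", {
  set.seed(22)
  n <- 18
  p <- 5
  K <- 3
  C <- 4
  X <- array(rnorm(n * p * K), c(n, p, K))
  lab <- c(1:4, sample(1:C, n - 4, replace = TRUE)) # every class present
  D <- rhythmgain:::cpp_loo_min_dist(X, as.integer(lab), as.integer(C))
  ref <- matrix(Inf, n, C)
  for (k in 1:K) {
    for (i in 1:n) {
      Xtr <- X[-i, , k]
      S <- shrinkage_covariance(Xtr)
      for (cc in 1:C) {
        rows <- which(lab[-i] == cc)
        if (length(rows) == 0) {
          ref[i, cc] <- NaN
          next
        }
        mu <- colMeans(Xtr[rows, , drop = FALSE])
        d <- mahalanobis_dist(X[i, , k], mu, S)
        if (d < ref[i, cc]) ref[i, cc] <- d
      }
    }
  }
  expect_equal(D, ref, tolerance = 1e-10)
})

test_that("the ideal matrix is symmetric with zero diagonal and growing off-diagonals", {
  im <- ideal_matrix()
  expect_equal(dim(im), c(15, 15))
  expect_equal(diag(im), rep(0, 15))
  expect_equal(im, t(im))
  for (r in 1:15) {
    right <- im[r, r:15]
    expect_true(all(diff(right) > 0) || length(right) == 1)
  }
})

test_that("decoding scores hit the trivial endpoints and the degenerate convention", {
  im <- ideal_matrix()
  expect_equal(as.numeric(score_decoding(im, im)), 1)
  expect_equal(as.numeric(score_decoding(-im, im)), -1)
  s0 <- score_decoding(matrix(1, 15, 15), im)
  expect_equal(as.numeric(s0), 0)
  expect_true(attr(s0, "degenerate"))
  few <- matrix(NA, 15, 15)
  few[1, 1:2] <- 1
  expect_error(score_decoding(few, im), "3 retained")
})

test_that("band-coded components decode with diagonal minima and near-perfect score", {
  bc <- band_coded_comp()
  dec <- decode_tone_frequency(bc$comp, bc$events,
    lags_ms = -300,
    response_window_ms = seq(26, 126, by = 10)
  )
  expect_s3_class(dec, "tone_decoding")
  m <- dec$matrices[[1]]
  present <- which(rowSums(is.finite(m)) > 0)
  expect_gt(length(present), 10)
  for (r in present) {
    expect_equal(which.min(m[r, ]), r)
  }
  expect_gt(as.numeric(score_decoding(m, ideal_matrix())), 0.5)
  # lag grid arithmetic: the default spans 101 lags
  expect_length(seq(-500, 500, by = 10), 101)
})

test_that("shuffled band labels destroy the decoding score", {
  bc <- band_coded_comp()
  set.seed(23)
  scores <- replicate(15, {
    ev <- bc$events
    tone_rows <- ev$event_kind == "tone"
    ev$band[tone_rows] <- sample(ev$band[tone_rows])
    m <- decode_tone_frequency(bc$comp, ev,
      lags_ms = -300,
      response_window_ms = seq(26, 126, by = 20)
    )$matrices[[1]]
    as.numeric(score_decoding(m, ideal_matrix()))
  })
  expect_lt(abs(mean(scores)), 0.15)
})

test_that("trial subsampling for decoding is seeded and caps the count", {
  bc <- band_coded_comp()
  d1 <- decode_tone_frequency(bc$comp, bc$events,
    lags_ms = -300, response_window_ms = c(26, 76),
    n_max_trials = 20, subsample_seed = 4
  )
  d2 <- decode_tone_frequency(bc$comp, bc$events,
    lags_ms = -300, response_window_ms = c(26, 76),
    n_max_trials = 20, subsample_seed = 4
  )
  expect_identical(d1$matrices, d2$matrices)
  expect_lte(max(d1$n_trials), 20)
})

test_that("chord decoding separates distinct identity patterns but not identical ones", {
  set.seed(24)
  n_ch <- 30
  onsets <- 700 + 1000 * (seq_len(n_ch) - 1)
  ids <- rep(c("A", "B"), length.out = n_ch)
  events <- tibble::tibble(
    trial = 1L, event_kind = "chord", abs_onset_ms = onsets, duration_ms = 30,
    band = NA_integer_, chord_identity = ids, chord_kind = "short",
    preceding_isi_ms = c(NA, diff(onsets))
  )
  n_samp <- max(onsets) + 900
  p <- 6
  mk_comp <- function(distinct) {
    comp <- matrix(rnorm(n_samp * p, sd = 0.3), n_samp, p)
    patt <- list(A = c(1, rep(0, p - 1)), B = c(rep(0, p - 1), 1))
    for (i in seq_len(n_ch)) {
      rows <- onsets[i] + 100 + seq_len(60)
      add <- 3 * (if (distinct) patt[[ids[i]]] else patt$A)
      comp[rows, ] <- comp[rows, ] + rep(add, each = 60)
    }
    comp
  }
  cd <- decode_chord(mk_comp(TRUE), events,
    times_ms = seq(-100, 400, by = 50),
    response_window_ms = seq(26, 126, by = 20)
  )
  expect_equal(cd$time_ms, seq(-100, 400, by = 50))
  # strongest separation near the injected 100-160 ms response
  peak <- cd$time_ms[which.max(cd$relative_distance)]
  expect_true(peak >= 0 && peak <= 150)
  expect_gt(max(cd$relative_distance, na.rm = TRUE), 0.3)

  cd0 <- decode_chord(mk_comp(FALSE), events,
    times_ms = seq(-100, 400, by = 100),
    response_window_ms = seq(26, 126, by = 20)
  )
  expect_lt(max(abs(cd0$relative_distance), na.rm = TRUE), 0.15)

  one_id <- dplyr::mutate(events, chord_identity = "A")
  expect_error(
    decode_chord(mk_comp(TRUE), one_id),
    "each chord identity"
  )
})

test_that("decoding score rises monotonically with the response strength", {
  score_at <- function(amp) {
    bc <- band_coded_comp(n_chords = 30, seed = 42, noise_sd = 1, signal = amp)
    m <- decode_tone_frequency(bc$comp, bc$events,
      lags_ms = -300, response_window_ms = seq(26, 126, by = 20)
    )$matrices[[1]]
    as.numeric(score_decoding(m, ideal_matrix()))
  }
  s <- sapply(c(0.05, 0.6, 3), score_at)
  expect_true(all(diff(s) > 0))
})
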