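test_that("the 1-D cluster test finds injected effects and nothing in silence", {
  expect_equal(nrow(cluster_test_1d(matrix(0, 10, 50) + 1e-14)), 0)

  set.seed(40)
  x <- matrix(rnorm(20 * 100), 20)
  x[, 40:60] <- x[, 40:60] + 2 # Cohen's d = 2 boxcar
  ct <- cluster_test_1d(x, n_perm = 500, seed = 1)
  expect_gt(nrow(ct), 0)
  best <- ct[which.max(abs(ct$mass)), ]
  expect_lt(best$p, 0.05)
  expect_true(best$start <= 60 && best$end >= 40)

  expect_error(cluster_test_1d(x, n_perm = 50), "at least 100")
  expect_error(cluster_test_1d(x[1:3, ]), "at least 5")
})

test_that("cluster permutation p-values are bounded away from zero and reproducible", {
  set.seed(41)
  x <- matrix(rnorm(20 * 60), 20)
  x[, 10:20] <- x[, 10:20] + 3
  c1 <- cluster_test_1d(x, n_perm = 300, seed = 7)
  c2 <- cluster_test_1d(x, n_perm = 300, seed = 7)
  expect_identical(tidy(c1), tidy(c2))
  expect_true(all(c1$p >= 1 / 300))
  # full enumeration for small samples
  xe <- matrix(rnorm(6 * 30), 6)
  ce <- cluster_test_1d(xe, seed = 1)
  expect_equal(attr(ce, "n_perm"), 64)
})

test_that("channel/time-frequency clusters respect the adjacency structure", {
  set.seed(42)
  n <- 12
  dims <- c(4, 5, 6) # channels x freqs x times
  base <- array(rnorm(n * prod(dims), sd = 0.3), dim = c(n, dims))
  # effect on channels 1-2 (adjacent), freq 2-3, time 2-4
  eff <- base
  eff[, 1:2, 2:3, 2:4] <- eff[, 1:2, 2:3, 2:4] + 2
  adj <- matrix(FALSE, 4, 4)
  adj[1, 2] <- adj[2, 1] <- TRUE
  ct <- cluster_test_chan_tf(eff, adj, n_perm = 300, seed = 2)
  expect_gt(nrow(ct), 0)
  best <- ct$cells[[which.max(abs(ct$mass))]]
  injected <- expand.grid(channel = 1:2, freq = 2:3, time = 2:4)
  hit <- merge(as.data.frame(best), injected)
  expect_gte(nrow(hit), 0.5 * nrow(injected))
  expect_lt(min(ct$p), 0.05)

  # with no adjacency edges, clusters never span channels
  ct0 <- cluster_test_chan_tf(eff, matrix(FALSE, 4, 4), n_perm = 300, seed = 3)
  for (cl in ct0$cells) {
    expect_equal(length(unique(cl[, "channel"])), 1)
  }
})

test_that("the repeated-measures ANOVA matches hand-computed sums of squares", {
  set.seed(43)
  n <- 10
  vals <- array(rnorm(n * 2 * 4), dim = c(n, 2, 4))
  out <- rm_anova_2x4(vals)
  expect_equal(out$effect, c("a", "b", "a:b"))
  expect_equal(out$df1, c(1, 3, 3))
  expect_equal(out$df2, c(n - 1, 3 * (n - 1), 3 * (n - 1)))

  # oracle: classical within-subject partitioning computed from scratch
  grand <- mean(vals)
  mean_s <- apply(vals, 1, mean)
  mean_a <- apply(vals, 2, mean)
  mean_b <- apply(vals, 3, mean)
  mean_sa <- apply(vals, c(1, 2), mean)
  mean_sb <- apply(vals, c(1, 3), mean)
  mean_ab <- apply(vals, c(2, 3), mean)
  ss_a <- n * 4 * sum((mean_a - grand)^2)
  ss_b <- n * 2 * sum((mean_b - grand)^2)
  ss_sa <- 4 * sum(sweep(sweep(mean_sa, 1, mean_s), 2, mean_a - grand)^2)
  ss_sb <- 2 * sum(sweep(sweep(mean_sb, 1, mean_s), 2, mean_b - grand)^2)
  f_a <- (ss_a / 1) / (ss_sa / (n - 1))
  f_b <- (ss_b / 3) / (ss_sb / (3 * (n - 1)))
  expect_equal(out$F[1], f_a, tolerance = 1e-8)
  expect_equal(out$F[2], f_b, tolerance = 1e-8)

  # adding pure subject constants changes no effect statistic
  shifted <- vals + array(rep(rnorm(n, sd = 5), 8), dim = c(n, 2, 4))
  outs <- rm_anova_2x4(shifted)
  expect_equal(outs$F, out$F, tolerance = 1e-8)

  # crossed interaction dominates
  ivals <- array(rnorm(n * 2 * 4, sd = 0.2), dim = c(n, 2, 4))
  ivals[, 1, ] <- sweep(ivals[, 1, ], 2, c(1, -1, 1, -1), "+")
  ivals[, 2, ] <- sweep(ivals[, 2, ], 2, c(-1, 1, -1, 1), "+")
  outi <- rm_anova_2x4(ivals)
  expect_equal(which.max(outi$F), 3)
  expect_lt(outi$p[3], 0.01)

  vals_na <- vals
  vals_na[1, 1, 1] <- NA
  expect_error(rm_anova_2x4(vals_na), "missing")
})

test_that("paired t tests match the textbook formula and handle degeneracy", {
  a <- c(5.1, 4.8, 6.0, 5.5, 4.9)
  b <- c(4.7, 4.9, 5.2, 5.0, 4.6)
  out <- paired_ttest(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(out$t, t_hand, tolerance = 1e-10)
  expect_equal(out$df, 4)
  expect_equal(out$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-10)

  same <- paired_ttest(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  shifted <- paired_ttest(a + 1, a)
  expect_equal(shifted$t, Inf)
  expect_equal(shifted$p, 0)

  nearly <- paired_ttest(a + 1 + rnorm(5, sd = 1e-6), a)
  expect_gt(nearly$t, 1e4)
  expect_lt(nearly$p, 1e-10)
})

test_that("influence-aware correlation excludes gross outliers by Cook's distance", {
  x <- 1:10
  out <- correlate_with_influence(x, x)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(correlate_with_influence(x, -x)$r, -1, tolerance = 1e-12)

  set.seed(44)
  x2 <- seq(-1, 1, length.out = 20)
  y2 <- x2 + rnorm(20, sd = 0.02)
  y2[20] <- -3 # gross outlier
  res <- correlate_with_influence(x2, y2)
  expect_true(20 %in% res$excluded)
  expect_gt(abs(res$r_excluded), abs(res$r))
  expect_gt(res$r_excluded, 0.99)

  expect_error(correlate_with_influence(rep(1, 5), 1:5), "zero variance")
})

test_that("the type-I rate of the 1-D cluster test stays near nominal (quick check)", {
  # small version of the calibration; the full 500-run version lives in the
  # acceptance suite
  set.seed(45)
  hits <- replicate(60, {
    x <- matrix(rnorm(20 * 60), 20)
    ct <- cluster_test_1d(x, n_perm = 300, seed = sample.int(1e6, 1))
    nrow(ct) > 0 && any(ct$p < 0.05)
  })
  expect_lt(mean(hits), 0.17)
})

test_that("the Bonferroni helper divides alpha", {
  expect_equal(bonferroni_alpha(0.05, 3), 0.05 / 3)
})
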