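#' One-dimensional cluster-based permutation test
#'
#' One-sample (or paired-difference) t statistics are computed per time
#' point; contiguous runs of same-sign statistics exceeding the two-tailed
#' critical value at `alpha_cluster` form clusters whose mass is the summed t.
#' The null distribution of the maximal absolute cluster mass is obtained by
#' sign-flipping subject series: full enumeration of all `2^n` flips when
#' `n <= 12`, otherwise Monte-Carlo flips (including the observed labeling,
#' so p >= 1/(n_perm + 1)).
#'
#' @param data Subjects x time matrix (paired designs pass the difference).
#' @param alpha_cluster Cluster-forming alpha (two-tailed).
#' @param n_perm Number of Monte-Carlo permutations (>= 100).
#' @param seed Integer seed.
#' @return An object of class `cluster_result`: tibble of clusters (`start`,
#'   `end` indices, `mass`, `p`) plus attributes `threshold`, `n_perm`,
#'   `t_obs`.
#' @export
cluster_test_1d <- function(data, alpha_cluster = 0.05, n_perm = 1000,
                            seed = 1) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 5) stop("need at least 5 subjects", call. = FALSE)
  if (n_perm < 100) stop("`n_perm` must be at least 100", call. = FALSE)
  thr <- stats::qt(1 - alpha_cluster / 2, df = n - 1)
  ssq <- colSums(data^2)
  t_from_signs <- function(s_mat) {
    # rows of s_mat are sign vectors; t_j from the flipped column means,
    # using sum x^2 invariance under sign flips
    m <- s_mat %*% data / n
    v <- sweep(-n * m^2, 2, ssq, "+") / (n - 1)
    m / sqrt(pmax(v, .Machine$double.eps) / n)
  }
  t_obs <- as.vector(t_from_signs(matrix(1, 1, n)))
  obs <- find_clusters_1d(t_obs, thr)
  s_mat <- if (n <= 12) {
    all_sign_flips(n)
  } else {
    withr_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm))
  }
  t_perm <- t_from_signs(s_mat)
  max_mass <- apply(t_perm, 1, function(tv) max_cluster_mass_1d(tv, thr))
  if (!(n <= 12)) max_mass[1] <- max(abs(obs$mass), 0) # include observed
  p <- purrr::map_dbl(obs$mass, function(m) mean(max_mass >= abs(m)))
  out <- tibble::tibble(
    start = obs$start, end = obs$end, mass = obs$mass, p = p
  )
  structure(out,
    class = c("cluster_result", class(out)),
    threshold = thr, n_perm = nrow(s_mat), t_obs = t_obs
  )
}

all_sign_flips <- function(n) {
  g <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(g) <- NULL
  g
}

find_clusters_1d <- function(tv, thr) {
  lab <- sign(tv) * (abs(tv) > thr)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  list(
    start = starts[keep], end = ends[keep],
    mass = purrr::map2_dbl(starts[keep], ends[keep], function(s, e) {
      sum(tv[s:e])
    })
  )
}

max_cluster_mass_1d <- function(tv, thr) {
  cl <- find_clusters_1d(tv, thr)
  if (length(cl$mass) == 0) 0 else max(abs(cl$mass))
}

#' Channel adjacency graph from sensor positions
#'
#' Neighbors are channels within `radius_factor` times the median
#' nearest-neighbor distance (array-agnostic default).
#'
#' @param sensors A `sensor_array` (or tibble with x, y, z).
#' @param radius_factor Multiplier on the median nearest-neighbor distance.
#' @return Logical channels x channels adjacency matrix (FALSE diagonal).
#' @export
channel_adjacency <- function(sensors, radius_factor = 1.3) {
  pos <- as.matrix(sensors[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  radius <- radius_factor * stats::median(apply(d, 1, min))
  adj <- d <= radius
  diag(adj) <- FALSE
  adj
}

#' Channel x time-frequency cluster-based permutation test
#'
#' As [cluster_test_1d()], over subjects x channel x frequency x time arrays:
#' clusters connect suprathreshold cells that are adjacent in frequency or
#' time within a channel, or lie at the same time-frequency cell in
#' neighboring channels. Channels without neighbors form singleton-channel
#' clusters.
#'
#' @param data Subjects x channels x freqs x times array (paired designs pass
#'   the difference).
#' @param adjacency Channels x channels logical matrix from
#'   [channel_adjacency()].
#' @param alpha_cluster,n_perm,seed As in [cluster_test_1d()].
#' @return A `cluster_result` tibble with `cells` (list of member cell
#'   indices, rows of (channel, freq, time)), `mass`, `p`.
#' @export
cluster_test_chan_tf <- function(data, adjacency, alpha_cluster = 0.05,
                                 n_perm = 1000, seed = 1) {
  d <- dim(data)
  stopifnot(length(d) == 4)
  n <- d[1]
  if (n < 5) stop("need at least 5 subjects", call. = FALSE)
  if (n_perm < 100) stop("`n_perm` must be at least 100", call. = FALSE)
  if (nrow(adjacency) != d[2]) {
    stop("adjacency must cover all channels", call. = FALSE)
  }
  thr <- stats::qt(1 - alpha_cluster / 2, df = n - 1)
  flat <- matrix(data, nrow = n) # subjects x (chan*freq*time)
  ssq <- colSums(flat^2)
  t_from_signs <- function(s_mat) {
    m <- s_mat %*% flat / n
    v <- sweep(-n * m^2, 2, ssq, "+") / (n - 1)
    m / sqrt(pmax(v, .Machine$double.eps) / n)
  }
  t_obs <- as.vector(t_from_signs(matrix(1, 1, n)))
  obs <- find_clusters_ctf(t_obs, thr, d[2:4], adjacency)
  s_mat <- if (n <= 12) {
    all_sign_flips(n)
  } else {
    withr_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm))
  }
  t_perm <- t_from_signs(s_mat)
  max_mass <- apply(t_perm, 1, function(tv) {
    cl <- find_clusters_ctf(tv, thr, d[2:4], adjacency)
    if (length(cl$mass) == 0) 0 else max(abs(cl$mass))
  })
  if (!(n <= 12) && length(obs$mass) > 0) {
    max_mass[1] <- max(abs(obs$mass))
  }
  p <- purrr::map_dbl(obs$mass, function(m) mean(max_mass >= abs(m)))
  out <- tibble::tibble(cells = obs$cells, mass = obs$mass, p = p)
  structure(out,
    class = c("cluster_result", class(out)),
    threshold = thr, n_perm = nrow(s_mat), dims = d[2:4]
  )
}

# connected components of suprathreshold same-sign cells under the
# channel/freq/time adjacency, via union-find
find_clusters_ctf <- function(tv, thr, dims, adjacency) {
  lab <- sign(tv) * (abs(tv) > thr)
  idx <- which(lab != 0)
  if (length(idx) == 0) {
    return(list(cells = list(), mass = numeric(0)))
  }
  nc <- dims[1]
  nf <- dims[2]
  nt <- dims[3]
  # cell index -> (chan, freq, time); array order chan fastest
  ch <- (idx - 1L) %% nc + 1L
  fr <- ((idx - 1L) %/% nc) %% nf + 1L
  ti <- (idx - 1L) %/% (nc * nf) + 1L
  pos <- integer(nc * nf * nt)
  pos[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  neighbor_link <- function(delta, valid) {
    other <- idx + delta
    ok <- valid & other >= 1L & other <= length(pos)
    ok[ok] <- pos[other[ok]] > 0L
    w <- which(ok)
    w <- w[lab[other[w]] == lab[idx[w]]]
    for (i in w) unite(i, pos[other[i]])
  }
  neighbor_link(-nc, fr > 1L) # freq - 1
  neighbor_link(+nc, fr < nf) # freq + 1
  neighbor_link(-nc * nf, ti > 1L) # time - 1
  neighbor_link(+nc * nf, ti < nt) # time + 1
  nb <- which(adjacency, arr.ind = TRUE)
  if (nrow(nb) > 0) {
    for (r in seq_len(nrow(nb))) {
      delta <- nb[r, 2] - nb[r, 1]
      neighbor_link(delta, ch == nb[r, 1])
    }
  }
  root <- purrr::map_int(seq_along(idx), find)
  groups <- split(seq_along(idx), root)
  list(
    cells = purrr::map(groups, function(g) {
      cbind(channel = ch[g], freq = fr[g], time = ti[g])
    }),
    mass = purrr::map_dbl(groups, function(g) sum(tv[idx[g]]))
  )
}

#' Two-by-four repeated-measures ANOVA
#'
#' Within-subject F tests for the two main effects and their interaction in a
#' complete 2 x 4 design (e.g. temporal expectation x frequency class), via
#' per-effect error strata.
#'
#' @param values Subjects x 2 x 4 numeric array, or a long tibble with
#'   columns `subject`, `a` (2 levels), `b` (4 levels), `value`.
#' @return Tibble with `effect` (`a`, `b`, `a:b`), `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2x4 <- function(values) {
  if (is.array(values) && length(dim(values)) == 3) {
    d <- dim(values)
    stopifnot(d[2] == 2, d[3] == 4)
    long <- expand.grid(
      subject = seq_len(d[1]), a = seq_len(2), b = seq_len(4)
    )
    long$value <- as.vector(values)
  } else {
    long <- as.data.frame(values)
    stopifnot(all(c("subject", "a", "b", "value") %in% names(long)))
  }
  if (anyNA(long$value)) stop("missing cells in the design", call. = FALSE)
  long$subject <- factor(long$subject)
  long$a <- factor(long$a)
  long$b <- factor(long$b)
  if (nlevels(long$subject) < 3) stop("need at least 3 subjects", call. = FALSE)
  if (nlevels(long$a) != 2 || nlevels(long$b) != 4 ||
    nrow(long) != nlevels(long$subject) * 8) {
    stop("design must be complete 2 x 4 within-subject", call. = FALSE)
  }
  fit <- stats::aov(value ~ a * b + Error(subject / (a * b)), data = long)
  sm <- summary(fit)
  pull_eff <- function(stratum, row) {
    tab <- sm[[stratum]][[1]]
    i <- which(trimws(rownames(tab)) == row)[1]
    tibble::tibble(
      effect = row, F = tab[i, "F value"], df1 = tab[i, "Df"],
      df2 = tab[nrow(tab), "Df"], p = tab[i, "Pr(>F)"]
    )
  }
  dplyr::bind_rows(
    pull_eff("Error: subject:a", "a"),
    pull_eff("Error: subject:b", "b"),
    pull_eff("Error: subject:a:b", "a:b")
  )
}

#' Pearson correlation with Cook's-distance influence handling
#'
#' z-scores both inputs, computes the Pearson correlation and p-value, then
#' recomputes after excluding points whose Cook's distance (from the y-on-x
#' regression) exceeds the mean Cook's distance.
#'
#' @param x,y Per-subject values (length >= 4).
#' @return List with `r`, `p`, `r_excluded`, `p_excluded`, `excluded` (point
#'   indices).
#' @export
correlate_with_influence <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance input: correlation undefined", call. = FALSE)
  }
  zx <- as.vector(scale(x))
  zy <- as.vector(scale(y))
  ct <- stats::cor.test(zx, zy)
  cd <- stats::cooks.distance(stats::lm(zy ~ zx))
  excl <- which(cd > mean(cd))
  keep <- setdiff(seq_along(zx), excl)
  ct2 <- if (length(keep) >= 4 && stats::var(zx[keep]) > 0 &&
    stats::var(zy[keep]) > 0) {
    stats::cor.test(zx[keep], zy[keep])
  } else {
    NULL
  }
  list(
    r = unname(ct$estimate), p = ct$p.value,
    r_excluded = if (is.null(ct2)) NA_real_ else unname(ct2$estimate),
    p_excluded = if (is.null(ct2)) NA_real_ else ct2$p.value,
    excluded = excl
  )
}

#' Paired t test
#'
#' Standard paired t on the per-subject differences, two-tailed. Zero-variance
#' differences return an infinite-t sentinel (sign of the mean difference)
#' with p = 0 for a nonzero mean and t = 0, p = 1 when all differences are 0.
#'
#' @param a,b Per-subject values, equal lengths >= 2.
#' @return Tibble with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::var(d) == 0) {
    md <- mean(d)
    return(tibble::tibble(
      t = if (md == 0) 0 else Inf * sign(md),
      df = length(d) - 1,
      p = if (md == 0) 1 else 0,
      mean_diff = md
    ))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean_diff = unname(tt$estimate)
  )
}

#' Bonferroni-adjusted alpha helper
#'
#' @param alpha Family-wise alpha.
#' @param m Number of tests.
#' @return The per-test alpha `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) alpha / m
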