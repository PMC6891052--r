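#' Gain/tuning model prediction
#'
#' Distance profile over the relative-frequency axis (band-index difference):
#' `Z(df) = c + g * exp(-df^2 / (2 sigma^2))`. The gain `g` scales the depth
#' of the profile at the diagonal (more negative = better overall decoding),
#' `sigma` is the tuning width in band-index units, and `c` the constant
#' offset.
#'
#' @param g Gain (a.u.).
#' @param sigma Tuning width (> 0, band-index units).
#' @param c Constant offset (a.u.).
#' @param df Absolute band-index differences (>= 0).
#' @return Predicted distances, same length as `df`.
#' @export
model_predict <- function(g, sigma, c, df) {
  if (!is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be positive", call. = FALSE)
  }
  c + g * exp(-df^2 / (2 * sigma^2))
}

#' Symmetrized distance profile of a decoding matrix
#'
#' Pools matrix cells by absolute band-index difference `|row - col|`
#' (optionally over a subset of rows), averaging finite cells; the pooled
#' count per difference is kept as a weight.
#'
#' @param obs Bands x bands distance matrix.
#' @param rows Row subset (default all).
#' @return Tibble with `df`, `z` (mean distance), `n_cells`.
#' @export
distance_profile <- function(obs, rows = seq_len(nrow(obs))) {
  n <- ncol(obs)
  df_mat <- abs(outer(rows, seq_len(n), "-"))
  vals <- obs[rows, , drop = FALSE]
  keep <- is.finite(vals)
  tibble::tibble(df = as.vector(df_mat)[keep], z = vals[keep]) |>
    dplyr::group_by(.data$df) |>
    dplyr::summarise(z = mean(.data$z), n_cells = dplyr::n()) |>
    dplyr::arrange(.data$df)
}

#' Fit the gain/tuning model to a decoding matrix
#'
#' Robust (iteratively reweighted, bisquare) least squares on the symmetrized
#' profile `Z(df)`, with cells pooled by `|row - col|` and weighted by pooled
#' cell counts. Any subset of the parameters can be fixed at anchor values
#' (typically from the fit to the grand-average matrix).
#'
#' @param obs Bands x bands distance matrix, or a profile tibble from
#'   [distance_profile()].
#' @param fixed Character vector naming parameters held fixed (subset of
#'   `c("g", "sigma", "c")`).
#' @param anchors Named list of anchor values used for fixed parameters and
#'   as starting points for free ones.
#' @param rows Row subset for class-specific fits.
#' @param tuning_constant Bisquare tuning constant.
#' @param max_iter,tol IRLS iteration cap and relative-change tolerance.
#' @return An object of class `tuning_fit`: list with `g`, `sigma`, `c`,
#'   `fixed`, `rss`, `n_points`, `aic`, `converged`, `profile`.
#' @export
fit_tuning_model <- function(obs, fixed = character(0),
                             anchors = list(g = -1, sigma = 2, c = NULL),
                             rows = NULL, tuning_constant = 4.685,
                             max_iter = 200, tol = 1e-8) {
  prof <- if (is.matrix(obs)) {
    distance_profile(obs, rows %||% seq_len(nrow(obs)))
  } else {
    obs
  }
  stopifnot(all(c("df", "z") %in% names(prof)))
  if (is.null(prof$n_cells)) prof$n_cells <- 1
  if (length(fixed) > 0) {
    fixed <- sort(unique(match.arg(fixed, c("g", "sigma", "c"),
      several.ok = TRUE
    )))
  }
  free <- setdiff(c("g", "sigma", "c"), fixed)
  if (nrow(prof) < length(free)) {
    stop("fewer profile points than free parameters", call. = FALSE)
  }
  if (is.null(anchors$c)) anchors$c <- max(prof$z)
  if (is.null(anchors$g)) anchors$g <- min(prof$z) - max(prof$z)
  if (is.null(anchors$sigma)) anchors$sigma <- 2
  pars <- c(g = anchors$g, sigma = anchors$sigma, c = anchors$c)

  if (length(free) == 0) {
    res <- prof$z - model_predict(pars["g"], pars["sigma"], pars["c"], prof$df)
    fit <- list(pars = pars, rss = sum(prof$n_cells * res^2), converged = TRUE)
  } else {
    fit <- irls_fit(prof, pars, free, tuning_constant, max_iter, tol)
  }
  k <- length(free)
  n <- nrow(prof)
  aic <- aic_rss(fit$rss, n, k)
  structure(
    list(
      g = unname(fit$pars["g"]), sigma = unname(fit$pars["sigma"]),
      c = unname(fit$pars["c"]), fixed = fixed, rss = fit$rss,
      n_points = n, n_free = k, aic = aic, converged = fit$converged,
      profile = prof
    ),
    class = "tuning_fit"
  )
}

# bisquare IRLS around a weighted Gauss-Newton step (nlsLM)
irls_fit <- function(prof, pars, free, tuning_constant, max_iter, tol) {
  sigma_min <- 0.5 # half a band: sharper profiles are unresolvable on the grid
  zrange <- max(prof$z) - min(prof$z)
  if (zrange <= 0) zrange <- max(abs(prof$z), 1)
  # box constraints keep the profile fit on the data scale even when the
  # bisquare weights temporarily concentrate on few points
  lower <- c(g = -10 * zrange, sigma = sigma_min, c = min(prof$z) - 5 * zrange)
  upper <- c(g = 10 * zrange, sigma = 1e6, c = max(prof$z) + 5 * zrange)
  predict_free <- function(theta) {
    p <- pars
    p[free] <- theta
    model_predict(p["g"], max(p["sigma"], sigma_min), p["c"], prof$df)
  }
  theta <- pmin(pmax(pars[free], lower[free]), upper[free])
  w_robust <- rep(1, nrow(prof))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # breakdown guard: never fit on fewer points than parameters + 2
    if (sum(w_robust > 0.05) < length(free) + 2) w_robust <- rep(1, nrow(prof))
    w <- w_robust * prof$n_cells
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = theta,
        fn = function(th) sqrt(w) * (prof$z - predict_free(th)),
        lower = lower[free], upper = upper[free],
        control = minpack.lm::nls.lm.control(maxiter = 100)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) break
    new_theta <- stats::coef(fit)
    res <- prof$z - predict_free(new_theta)
    scale <- stats::median(abs(res[prof$n_cells > 0])) / 0.6745
    scale <- max(scale, 1e-3 * zrange) # scale floor avoids weight collapse
    if (!is.finite(scale) || max(abs(res)) < 1e-10 * zrange) {
      theta <- new_theta
      converged <- TRUE
      break
    }
    u <- res / (tuning_constant * scale)
    w_new <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    delta <- max(abs(new_theta - theta) / pmax(abs(theta), 1e-12))
    theta <- new_theta
    w_robust <- w_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max_iter > 0) {
    warning("robust fit did not converge; returning best iterate", call. = FALSE)
  }
  pars[free] <- theta
  res <- prof$z - model_predict(pars["g"], pars["sigma"], pars["c"], prof$df)
  list(pars = pars, rss = sum(prof$n_cells * res^2), converged = converged)
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf(
    "<tuning_fit> g = %.4g, sigma = %.4g, c = %.4g (fixed: %s), AIC = %.4g\n",
    x$g, x$sigma, x$c,
    if (length(x$fixed)) paste(x$fixed, collapse = ",") else "none", x$aic
  ))
  invisible(x)
}

#' AIC from a residual sum of squares
#'
#' Gaussian-residual approximation `AIC = n log(RSS/n) + 2k`. An exact fit
#' (RSS = 0) returns `-Inf` with an `exact_fit` attribute.
#'
#' @param rss Residual sum of squares.
#' @param n Number of data points.
#' @param k Number of free parameters.
#' @return The AIC value.
#' @export
aic_rss <- function(rss, n, k) {
  if (n <= k) stop("need more points than free parameters", call. = FALSE)
  if (rss <= 0) {
    out <- -Inf
    attr(out, "exact_fit") <- TRUE
    return(out)
  }
  n * log(rss / n) + 2 * k
}

#' The seven-model space of the gain/tuning analysis
#'
#' The full model plus six reduced models in which every proper nonempty
#' subset of \{g, sigma, c\} stays free (equivalently, each combination of
#' parameters can be fixed to its grand-average anchor), excluding the
#' all-fixed case.
#'
#' @return Tibble with `model` (name), `free` (list of free parameter names),
#'   `n_free`.
#' @export
tuning_model_space <- function() {
  pars <- c("g", "sigma", "c")
  subsets <- purrr::map(seq_len(2^3 - 1), function(i) {
    pars[as.logical(bitwAnd(i, c(1L, 2L, 4L)))]
  })
  tibble::tibble(
    model = purrr::map_chr(subsets, paste, collapse = "+"),
    free = subsets,
    n_free = lengths(subsets)
  ) |> dplyr::arrange(dplyr::desc(.data$n_free), .data$model)
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet scheme over per-subject log model evidence
#' approximations: iteratively updates posterior model assignment
#' probabilities and Dirichlet counts, then estimates exceedance
#' probabilities by Monte-Carlo sampling of the posterior Dirichlet.
#'
#' @param log_evidence Subjects x models matrix (e.g. `-AIC/2`).
#' @param alpha0 Dirichlet prior count per model.
#' @param n_samples Monte-Carlo samples for exceedance probabilities.
#' @param seed Seed for the Monte-Carlo step.
#' @param max_iter,tol Iteration control.
#' @return An object of class `bms_result`: list with `expected_p` (p(m|y)),
#'   `exceedance_p`, `alpha` (posterior Dirichlet), `assignment` (subjects x
#'   models posterior), `n_subjects`, `n_models`.
#' @export
bayesian_model_selection <- function(log_evidence, alpha0 = 1,
                                     n_samples = 1e5, seed = 1,
                                     max_iter = 500, tol = 1e-8) {
  le <- as.matrix(log_evidence)
  if (nrow(le) < 2 || ncol(le) < 2) {
    stop("need at least 2 subjects and 2 models", call. = FALSE)
  }
  if (!all(is.finite(le))) stop("non-finite log evidence", call. = FALSE)
  n_sub <- nrow(le)
  n_mod <- ncol(le)
  alpha <- rep(alpha0, n_mod)
  for (it in seq_len(max_iter)) {
    lu <- sweep(le, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lu <- lu - apply(lu, 1, max)
    g <- exp(lu)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  withr_seed(seed, {
    draws <- matrix(stats::rgamma(n_samples * n_mod, shape = rep(alpha, each = n_samples)),
      nrow = n_samples
    )
    winner <- max.col(draws, ties.method = "first")
    xp <- tabulate(winner, nbins = n_mod) / n_samples
  })
  structure(
    list(
      expected_p = alpha / sum(alpha),
      exceedance_p = xp,
      alpha = alpha,
      assignment = g,
      n_subjects = n_sub,
      n_models = n_mod
    ),
    class = "bms_result"
  )
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>\n  expected p(m|y):", sprintf("%.3f", x$expected_p), "\n")
  cat("  exceedance p:   ", sprintf("%.3f", x$exceedance_p), "\n")
  invisible(x)
}

#' Fit the full gain/tuning model per frequency class
#'
#' Fits the full three-parameter model separately to the matrix rows of each
#' band class (discriminant, adjacent, distant, common).
#'
#' @param obs Bands x bands distance matrix.
#' @param band_classes Tibble with `band`, `class` (from
#'   [assign_chord_frequencies()]).
#' @param ... Passed to [fit_tuning_model()].
#' @return Named list of `tuning_fit` objects (classes with no usable rows
#'   are skipped with a warning).
#' @export
fit_by_frequency_class <- function(obs, band_classes, ...) {
  classes <- c("discriminant", "adjacent", "distant", "common")
  out <- list()
  for (cl in classes) {
    rows <- band_classes$band[band_classes$class == cl]
    rows <- rows[rows %in% which(rowSums(is.finite(obs)) > 0)]
    if (length(rows) < 1) {
      warning("no usable rows for class ", cl, "; skipped", call. = FALSE)
      next
    }
    out[[cl]] <- fit_tuning_model(obs, rows = rows, ...)
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
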