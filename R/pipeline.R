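#' Derive a stage seed from the master seed
#'
#' Counter-based split: deterministic, stage-independent streams below 2^31.
#'
#' @param master Master seed (integer).
#' @param subject Subject counter (0 for group-level stages).
#' @param stage Stage counter.
#' @return An integer seed.
#' @export
seed_for <- function(master, subject = 0, stage = 0) {
  m <- 2147483647
  as.integer((master %% m) * 48271 %% m + subject * 97561 + stage * 7919) %% m + 1L
}

#' Experiment configuration
#'
#' Bundles the design constants, ground-truth parameters, and analysis
#' settings of a simulated experiment. The defaults are a desk-scale version
#' of the study design: the full design (22 subjects, 60 trials per block,
#' 10 ms lag grid, 0.1 Hz phase-locking grid) is obtained by overriding the
#' corresponding entries.
#'
#' @param master_seed Master seed; all stage seeds derive from it.
#' @param n_subjects Number of virtual subjects.
#' @param n_blocks Named counts of blocks per condition (3 rhythmic / 6
#'   jittered in the study design).
#' @param n_trials Trials per block.
#' @param sensors Named channel counts (`n_eeg`, `n_mag`, `n_grad`).
#' @param truth Arguments passed to [ground_truth()].
#' @param lags_ms Tone-decoding lag grid.
#' @param response_window_ms Decoding response window offsets.
#' @param chord_times_ms Chord-decoding time grid.
#' @param plv_freqs_hz,plv_times_ms Phase-locking analysis grids.
#' @param n_perm Cluster permutations.
#' @param alpha Cluster-level alpha.
#' @param var_target Retained variance for the component basis.
#' @param enc_window_ms,smooth_ms,max_per_band Encoding epoch window,
#'   smoothing, and per-band tone cap for the basis maps.
#' @param sig_window_ms Lag window over which distance matrices are averaged
#'   for the gain/tuning fits.
#' @param equalize_fraction Both conditions' eligible decoding chords are
#'   subsampled to this fraction of the common minimum, so that the two
#'   analysis sets have equal size and equal selection randomness.
#' @param filters High-pass, notch, and low-pass settings passed to
#'   [filter_continuous()]; set an entry to `NULL` to skip that stage (the
#'   forward model contains no line noise, so desk-scale runs may skip the
#'   notch).
#' @return A list of class `run_config`.
#' @export
run_config <- function(master_seed = 1, n_subjects = 8,
                       n_blocks = c(rhythmic = 1, jittered = 2),
                       n_trials = 12,
                       sensors = c(n_eeg = 20, n_mag = 20, n_grad = 40),
                       truth = list(),
                       lags_ms = seq(-500, 500, by = 20),
                       response_window_ms = seq(26, 126, by = 5),
                       chord_times_ms = seq(-100, 400, by = 20),
                       plv_freqs_hz = seq(0.5, 5, by = 0.5),
                       plv_times_ms = seq(-500, 500, by = 100),
                       n_perm = 500, alpha = 0.05, var_target = 0.95,
                       enc_window_ms = c(-200, 400), smooth_ms = 20,
                       max_per_band = 60,
                       sig_window_ms = c(-100, -80),
                       equalize_fraction = 0.8,
                       filters = list(hp_hz = 0.1, notch_hz = 50,
                                      lp_hz = 200)) {
  cfg <- list(
    master_seed = master_seed, n_subjects = n_subjects, n_blocks = n_blocks,
    n_trials = n_trials, sensors = sensors, truth = truth, lags_ms = lags_ms,
    response_window_ms = response_window_ms, chord_times_ms = chord_times_ms,
    plv_freqs_hz = plv_freqs_hz, plv_times_ms = plv_times_ms,
    n_perm = n_perm, alpha = alpha, var_target = var_target,
    enc_window_ms = enc_window_ms, smooth_ms = smooth_ms,
    max_per_band = max_per_band, sig_window_ms = sig_window_ms,
    equalize_fraction = equalize_fraction, filters = filters
  )
  class(cfg) <- "run_config"
  cfg
}

#' Simulate and analyze one virtual subject
#'
#' Runs the per-subject chain: chord assignment, block generation, forward
#' simulation, filtering and rereferencing, encoding maps and SVD basis,
#' basis projection, tone and chord decoding per condition, phase locking per
#' condition, and behavior.
#'
#' @param config A `run_config`.
#' @param subject Subject index (seeds derive from it).
#' @param keep_recordings Keep the filtered channel-space recordings (large).
#' @param analyses Which analysis stages to run (`"tones"`, `"chords"`,
#'   `"plv"`); behavior is always summarized.
#' @return A list with per-subject results (see `run_experiment()`), of class
#'   `subject_result`.
#' @export
run_subject <- function(config, subject = 1, keep_recordings = FALSE,
                        analyses = c("tones", "chords", "plv")) {
  grid <- build_frequency_grid()
  sensors <- make_sensor_array(
    config$sensors[["n_eeg"]], config$sensors[["n_mag"]],
    config$sensors[["n_grad"]],
    seed = seed_for(config$master_seed, 0, 1)
  )
  truth <- do.call(ground_truth, config$truth)
  assign <- assign_chord_frequencies(
    grid,
    seed = seed_for(config$master_seed, subject, 2)
  )
  conditions <- c("rhythmic", "jittered")
  recs <- list()
  responses <- list()
  k <- 0L
  for (cond in conditions) {
    for (b in seq_len(config$n_blocks[[cond]])) {
      k <- k + 1L
      block <- generate_block(
        cond, assign$chord_spec,
        n_trials = config$n_trials,
        seed = seed_for(config$master_seed, subject, 10 + k), grid = grid
      )
      rec <- simulate_recording(
        block, sensors, truth,
        seed = seed_for(config$master_seed, subject, 40 + k)
      )
      rec <- rereference_eeg(filter_continuous(rec,
        hp_hz = config$filters$hp_hz, notch_hz = config$filters$notch_hz,
        lp_hz = config$filters$lp_hz
      ))
      recs[[k]] <- rec
      responses[[k]] <- simulate_behavior(
        block, truth,
        seed = seed_for(config$master_seed, subject, 70 + k)
      )
    }
  }
  cond_of <- purrr::map_chr(recs, "condition")

  # encoding maps: grand-average per-band tone-evoked responses across blocks
  bm <- purrr::map(recs, band_mean_epochs,
    window_ms = config$enc_window_ms, smooth_ms = config$smooth_ms,
    max_per_band = config$max_per_band
  )
  wts <- purrr::map(bm, "n_per_band")
  band_means <- Reduce(`+`, purrr::map2(bm, wts, function(x, w) {
    x$band_means * mean(w)
  })) / sum(purrr::map_dbl(wts, mean))
  contrast <- contrast_vector("monotonic", grid$n_bands)
  fam_maps <- purrr::map(
    split(seq_len(nrow(sensors)), sensors$family),
    function(idx) {
      correlate_amplitude_frequency(
        band_means[, idx, , drop = FALSE], contrast
      )$rho
    }
  )
  basis <- compute_component_basis(fam_maps, config$var_target)
  # component-summarized encoding series per family (modes applied to the
  # correlation map, averaged across modes)
  encoding_series <- purrr::imap(fam_maps, function(m, fam) {
    colMeans(crossprod(basis[[fam]]$weights, m))
  })

  # concatenate basis-projected blocks per condition on a common time axis;
  # component series are smoothed with the same 20 ms window before decoding
  comp_events <- purrr::map(conditions, function(cond) {
    idx <- which(cond_of == cond)
    comps <- purrr::map(recs[idx], function(r) {
      t(smooth_epochs(t(apply_basis(r, basis)$data), config$smooth_ms))
    })
    evs <- purrr::map(recs[idx], "events")
    offs <- c(0, cumsum(purrr::map_int(comps, nrow)))[seq_along(comps)]
    evs <- purrr::map2(evs, offs, function(e, o) {
      e$abs_onset_ms <- e$abs_onset_ms + o
      e$trial <- e$trial + 10000 * o # keep trials distinct across blocks
      e
    })
    list(comp = do.call(rbind, comps), events = dplyr::bind_rows(evs))
  })
  names(comp_events) <- conditions

  # decoding quality depends on the trial count and on whether a condition's
  # analysis set is an exhaustive or a scattered subset of its chords, so both
  # conditions are subsampled to the same fraction below the common minimum:
  # equal counts and equal selection randomness
  n_eligible <- floor(config$equalize_fraction *
    min(purrr::map_int(comp_events, function(ce) {
      ev <- ce$events
      sum(ev$event_kind == "chord" & ev$chord_kind == "short" &
        !is.na(ev$preceding_isi_ms) & abs(ev$preceding_isi_ms - 1000) <= 0.5)
    })))
  tone_dec <- NULL
  scores <- NULL
  win_mats <- NULL
  if ("tones" %in% analyses) {
    tone_dec <- purrr::map(comp_events, function(ce) {
      decode_tone_frequency(ce$comp, ce$events,
        lags_ms = config$lags_ms,
        response_window_ms = config$response_window_ms,
        n_bands = grid$n_bands,
        n_max_trials = n_eligible,
        subsample_seed = seed_for(config$master_seed, subject, 95)
      )
    })
    scores <- purrr::imap_dfr(tone_dec, function(dec, cond) {
      dplyr::mutate(decoding_scores(dec, ideal_matrix(grid)), condition = cond)
    })
  }
  chord_dec <- NULL
  if ("chords" %in% analyses) {
    chord_dec <- purrr::imap_dfr(comp_events, function(ce, cond) {
      dplyr::mutate(
        decode_chord(ce$comp, ce$events,
          times_ms = config$chord_times_ms,
          response_window_ms = config$response_window_ms,
          n_max_trials = n_eligible,
          subsample_seed = seed_for(config$master_seed, subject, 96)
        ),
        condition = cond
      )
    })
  }

  # phase locking on channel-space data around eligible chords; PLV is biased
  # upward by 1/sqrt(N), so trial counts are equalized across conditions by
  # seeded subsampling before the maps are compared
  plv <- NULL
  if ("plv" %in% analyses) {
    half_win <- 1000
    pad <- max(abs(config$plv_times_ms)) + half_win
    plv_epochs <- purrr::map(conditions, function(cond) {
      idx <- which(cond_of == cond)
      eps <- purrr::map(recs[idx], function(r) {
        sel <- select_plv_chords(r$events)
        epoch_events(r, sel$abs_onset_ms, c(-pad, pad))
      })
      abind_epochs(eps)
    })
    n_min <- min(purrr::map_int(plv_epochs, function(e) dim(e$data)[1]))
    plv <- purrr::imap(plv_epochs, function(e, i) {
      n <- dim(e$data)[1]
      if (n > n_min) {
        keep <- withr_seed(
          seed_for(config$master_seed, subject, 90 + i),
          sort(sample.int(n, n_min))
        )
        e$data <- e$data[keep, , , drop = FALSE]
      }
      plv_map(morlet_transform(e,
        freqs_hz = config$plv_freqs_hz,
        times_ms = config$plv_times_ms
      ))
    })
    names(plv) <- conditions
  }

  # window-averaged distance matrices for the gain/tuning fits
  if (!is.null(tone_dec)) win_mats <- purrr::map(tone_dec, function(dec) {
    sel <- dec$lags_ms >= config$sig_window_ms[1] &
      dec$lags_ms <= config$sig_window_ms[2]
    ms <- dec$matrices[sel]
    ms <- ms[!purrr::map_lgl(ms, is.null)]
    if (length(ms) == 0) {
      return(NULL)
    }
    mean_matrices(ms)
  })

  out <- list(
    subject = subject,
    band_classes = assign$band_classes,
    sensors = sensors,
    basis = basis,
    encoding_series = encoding_series,
    enc_time_ms = round(config$enc_window_ms[1]):round(config$enc_window_ms[2]),
    scores = scores,
    tone_matrices = win_mats,
    chord_decoding = chord_dec,
    plv = plv,
    behavior = dplyr::bind_rows(responses)
  )
  if (keep_recordings) out$recordings <- recs
  class(out) <- "subject_result"
  out
}

# per-cell mean over finite entries (bands missing in one matrix do not
# knock the cell out of the average)
mean_matrices <- function(ms) {
  arr <- simplify2array(ms)
  out <- apply(arr, c(1, 2), function(v) {
    f <- v[is.finite(v)]
    if (length(f) == 0) NA_real_ else mean(f)
  })
  out
}

abind_epochs <- function(eps) {
  if (length(eps) == 1) {
    return(eps[[1]])
  }
  d <- dim(eps[[1]]$data)
  total <- sum(purrr::map_int(eps, function(e) dim(e$data)[1]))
  arr <- array(0, dim = c(total, d[2], d[3]))
  at <- 0L
  for (e in eps) {
    n <- dim(e$data)[1]
    arr[at + seq_len(n), , ] <- e$data
    at <- at + n
  }
  out <- eps[[1]]
  out$data <- arr
  out$labels <- NULL
  out
}

#' Run a full simulated experiment
#'
#' Simulates `n_subjects` virtual subjects, then performs the group-level
#' analyses: behavioral condition contrasts, a cluster-based permutation test
#' on the rhythmic-minus-jittered tone-decoding score series, the analogous
#' test on the chord-decoding series, channel x time-frequency cluster tests
#' on phase locking and on low-frequency power, gain/tuning model fits per
#' condition with paired parameter tests (Bonferroni-corrected), AIC-based
#' random-effects Bayesian model selection over the seven-model space,
#' class-specific fits entered into a 2 x 4 repeated-measures ANOVA, and
#' cross-measure correlations of the condition differences with influence
#' handling.
#'
#' @param config A `run_config`.
#' @return A list of class `experiment_result` with elements `subjects`,
#'   `behavior` (summaries + contrasts), `decoding` (score tibble + cluster
#'   test), `chords` (series + cluster test), `encoding` (per-family
#'   one-sample cluster tests on the component-summarized correlation
#'   series), `plv` (cluster tests for PLV and power), `tuning`
#'   (per-condition fits, parameter tests, BMS, ANOVA), `correlations`, and
#'   `manifest`.
#' @export
run_experiment <- function(config = run_config()) {
  subjects <- purrr::map(
    seq_len(config$n_subjects),
    function(s) run_subject(config, s)
  )

  # behavior
  behav <- purrr::map_dfr(subjects, function(sr) {
    dplyr::mutate(behavior_summary(sr$behavior), subject = sr$subject)
  })
  behav_tests <- condition_contrast(behav)

  # tone decoding scores: subjects x lags difference
  lags <- config$lags_ms
  score_diff <- t(purrr::map_dfc(subjects, function(sr) {
    w <- tidyr::pivot_wider(sr$scores[, c("lag_ms", "condition", "rho")],
      names_from = "condition", values_from = "rho"
    )
    tibble::tibble(d = w$rhythmic - w$jittered)
  }))
  keep_lags <- colSums(is.na(score_diff)) == 0
  dec_test <- cluster_test_1d(score_diff[, keep_lags, drop = FALSE],
    alpha_cluster = config$alpha, n_perm = config$n_perm,
    seed = seed_for(config$master_seed, 0, 101)
  )
  attr(dec_test, "lags_ms") <- lags[keep_lags]

  # chord decoding series
  chord_diff <- t(purrr::map_dfc(subjects, function(sr) {
    w <- tidyr::pivot_wider(
      sr$chord_decoding[, c("time_ms", "condition", "relative_distance")],
      names_from = "condition", values_from = "relative_distance"
    )
    tibble::tibble(d = w$rhythmic - w$jittered)
  }))
  keep_t <- colSums(is.na(chord_diff)) == 0
  chord_test <- cluster_test_1d(chord_diff[, keep_t, drop = FALSE],
    alpha_cluster = config$alpha, n_perm = config$n_perm,
    seed = seed_for(config$master_seed, 0, 102)
  )
  attr(chord_test, "times_ms") <- config$chord_times_ms[keep_t]

  # encoding: one-sample cluster tests on the component-summarized
  # correlation series, per channel family
  fams <- names(subjects[[1]]$encoding_series)
  enc_tests <- purrr::map(stats::setNames(fams, fams), function(fam) {
    mat <- t(sapply(subjects, function(sr) sr$encoding_series[[fam]]))
    ct <- cluster_test_1d(mat,
      alpha_cluster = config$alpha, n_perm = config$n_perm,
      seed = seed_for(config$master_seed, 0, 110)
    )
    attr(ct, "time_ms") <- subjects[[1]]$enc_time_ms
    ct
  })

  # phase locking: subjects x chan x freq x time condition differences
  adj <- channel_adjacency(subjects[[1]]$sensors)
  plv_diff <- subject_tf_diff(subjects, "plv")
  pow_diff <- subject_tf_diff(subjects, "power")
  plv_test <- cluster_test_chan_tf(plv_diff, adj,
    alpha_cluster = config$alpha, n_perm = config$n_perm,
    seed = seed_for(config$master_seed, 0, 103)
  )
  pow_test <- cluster_test_chan_tf(pow_diff, adj,
    alpha_cluster = config$alpha, n_perm = config$n_perm,
    seed = seed_for(config$master_seed, 0, 104)
  )

  # gain/tuning modeling
  tuning <- group_tuning_analysis(subjects, config)

  # cross-measure correlations of condition differences
  correlations <- cross_measure_correlations(subjects, behav, tuning, config)

  manifest <- list(
    config_hash = rlang::hash(config),
    master_seed = config$master_seed,
    n_subjects = config$n_subjects,
    package_version = as.character(utils::packageVersion("rhythmgain")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(
    list(
      subjects = subjects,
      behavior = list(summaries = behav, tests = behav_tests),
      decoding = list(
        scores = dplyr::bind_rows(purrr::map(subjects, function(sr) {
          dplyr::mutate(sr$scores, subject = sr$subject)
        })),
        cluster_test = dec_test
      ),
      chords = list(
        series = dplyr::bind_rows(purrr::map(subjects, function(sr) {
          dplyr::mutate(sr$chord_decoding, subject = sr$subject)
        })),
        cluster_test = chord_test
      ),
      encoding = list(cluster_tests = enc_tests),
      plv = list(plv_test = plv_test, power_test = pow_test),
      tuning = tuning,
      correlations = correlations,
      manifest = manifest
    ),
    class = "experiment_result"
  )
}

subject_tf_diff <- function(subjects, what) {
  one <- subjects[[1]]$plv$rhythmic[[what]]
  d <- dim(one)
  arr <- array(0, dim = c(length(subjects), d))
  for (s in seq_along(subjects)) {
    arr[s, , , ] <- subjects[[s]]$plv$rhythmic[[what]] -
      subjects[[s]]$plv$jittered[[what]]
  }
  arr
}

group_tuning_analysis <- function(subjects, config) {
  # grand-average matrix (across subjects and conditions) anchors the reduced
  # models and provides starting points
  mats_all <- purrr::map(subjects, function(sr) {
    ms <- sr$tone_matrices[!purrr::map_lgl(sr$tone_matrices, is.null)]
    if (length(ms) == 0) {
      return(NULL)
    }
    mean_matrices(ms)
  })
  ok <- !purrr::map_lgl(mats_all, is.null)
  if (!any(ok)) {
    return(NULL)
  }
  grand <- mean_matrices(mats_all[ok])
  if (nrow(distance_profile(grand)) < 4) {
    return(NULL) # too few usable band pairs for any model fit
  }
  grand_fit <- suppressWarnings(fit_tuning_model(grand))
  anchors <- list(g = grand_fit$g, sigma = grand_fit$sigma, c = grand_fit$c)

  # model space on the condition-averaged matrices
  space <- tuning_model_space()
  aics <- purrr::map(which(ok), function(s) {
    purrr::map_dbl(space$free, function(fr) {
      fit_tuning_model(mats_all[[s]],
        fixed = setdiff(c("g", "sigma", "c"), fr), anchors = anchors
      )$aic
    })
  })
  aic_mat <- do.call(rbind, aics)
  colnames(aic_mat) <- space$model
  finite_aics <- all(is.finite(aic_mat))
  bms <- if (nrow(aic_mat) >= 2 && finite_aics) {
    bayesian_model_selection(-aic_mat / 2,
      seed = seed_for(config$master_seed, 0, 105)
    )
  } else {
    NULL
  }

  # full-model fits per condition + paired parameter tests
  cond_fits <- purrr::map_dfr(which(ok), function(s) {
    purrr::imap_dfr(subjects[[s]]$tone_matrices, function(m, cond) {
      if (is.null(m)) {
        return(tibble::tibble())
      }
      f <- fit_tuning_model(m, anchors = anchors)
      tibble::tibble(
        subject = subjects[[s]]$subject, condition = cond,
        g = f$g, sigma = f$sigma, c = f$c, rss = f$rss, aic = f$aic,
        converged = f$converged
      )
    })
  })
  par_tests <- NULL
  wide <- tidyr::pivot_wider(cond_fits[, c("subject", "condition", "g", "sigma", "c")],
    names_from = "condition", values_from = c("g", "sigma", "c")
  )
  if (nrow(wide) >= 2 && all(c("g_rhythmic", "g_jittered") %in% names(wide))) {
    par_tests <- purrr::map_dfr(c("g", "sigma", "c"), function(pp) {
      res <- paired_ttest(
        wide[[paste0(pp, "_rhythmic")]], wide[[paste0(pp, "_jittered")]]
      )
      dplyr::bind_cols(tibble::tibble(parameter = pp), res)
    })
    par_tests$alpha_bonferroni <- bonferroni_alpha(0.05, 3)
  }

  # class-specific fits -> 2 x 4 repeated-measures ANOVA on the gain
  class_fits <- purrr::map_dfr(which(ok), function(s) {
    purrr::imap_dfr(subjects[[s]]$tone_matrices, function(m, cond) {
      if (is.null(m)) {
        return(tibble::tibble())
      }
      fits <- suppressWarnings(fit_by_frequency_class(
        m, subjects[[s]]$band_classes,
        anchors = anchors
      ))
      purrr::imap_dfr(fits, function(f, cl) {
        tibble::tibble(
          subject = subjects[[s]]$subject, condition = cond, class = cl,
          g = f$g, sigma = f$sigma, c = f$c
        )
      })
    })
  })
  anova <- NULL
  cf <- class_fits |>
    dplyr::mutate(
      a = factor(.data$condition, levels = c("rhythmic", "jittered")),
      b = factor(.data$class,
        levels = c("discriminant", "adjacent", "distant", "common")
      )
    ) |>
    dplyr::select(subject = "subject", "a", "b", value = "g")
  complete <- nrow(cf) == dplyr::n_distinct(cf$subject) * 8 &&
    dplyr::n_distinct(cf$subject) >= 3
  if (complete) anova <- rm_anova_2x4(cf)

  list(
    grand_fit = grand_fit, anchors = anchors, aic = aic_mat, bms = bms,
    condition_fits = cond_fits, parameter_tests = par_tests,
    class_fits = class_fits, anova = anova
  )
}

cross_measure_correlations <- function(subjects, behav, tuning, config) {
  diffs <- purrr::map_dfr(subjects, function(sr) {
    w <- tidyr::pivot_wider(sr$scores[, c("lag_ms", "condition", "rho")],
      names_from = "condition", values_from = "rho"
    )
    sel <- w$lag_ms >= config$sig_window_ms[1] &
      w$lag_ms <= config$sig_window_ms[2]
    cw <- tidyr::pivot_wider(
      sr$chord_decoding[, c("time_ms", "condition", "relative_distance")],
      names_from = "condition", values_from = "relative_distance"
    )
    tibble::tibble(
      subject = sr$subject,
      tone_decoding = mean(w$rhythmic[sel] - w$jittered[sel], na.rm = TRUE),
      chord_decoding = mean(cw$rhythmic - cw$jittered, na.rm = TRUE)
    )
  })
  gd <- NULL
  if (!is.null(tuning) && nrow(tuning$condition_fits) > 0) {
    gw <- tidyr::pivot_wider(
      tuning$condition_fits[, c("subject", "condition", "g")],
      names_from = "condition", values_from = "g"
    )
    gd <- tibble::tibble(subject = gw$subject, gain = gw$rhythmic - gw$jittered)
  }
  bw <- tidyr::pivot_wider(behav[, c("subject", "condition", "accuracy")],
    names_from = "condition", values_from = "accuracy"
  )
  tab <- diffs |>
    dplyr::left_join(
      tibble::tibble(
        subject = bw$subject, accuracy = bw$rhythmic - bw$jittered
      ),
      by = "subject"
    )
  if (!is.null(gd)) tab <- dplyr::left_join(tab, gd, by = "subject")
  vars <- intersect(
    c("tone_decoding", "gain", "chord_decoding", "accuracy"), names(tab)
  )
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    x <- tab[[pr[1]]]
    y <- tab[[pr[2]]]
    if (length(x) < 4 || stats::var(x) == 0 || stats::var(y) == 0) {
      return(tibble::tibble(
        var1 = pr[1], var2 = pr[2], r = NA_real_, p = NA_real_,
        r_excluded = NA_real_, n_excluded = NA_integer_
      ))
    }
    ci <- correlate_with_influence(x, y)
    tibble::tibble(
      var1 = pr[1], var2 = pr[2], r = ci$r, p = ci$p,
      r_excluded = ci$r_excluded, n_excluded = length(ci$excluded)
    )
  })
  res$alpha_bonferroni <- bonferroni_alpha(0.05, length(pairs))
  list(differences = tab, tests = res)
}

#' Equalize analysis samples across conditions
#'
#' Retains only chords preceded by the isochronous ISI in every block; with
#' the 3-rhythmic / 6-jittered block design, the expected retained counts are
#' approximately equal across conditions.
#'
#' @param blocks Named list of per-condition lists of `stimulus_block`s.
#' @param isi_ms The isochronous interval.
#' @return Named list (per condition) of tibbles of retained chord events
#'   with a `block` column.
#' @export
equalize_samples <- function(blocks, isi_ms = 1000) {
  stopifnot(
    all(c("rhythmic", "jittered") %in% names(blocks)),
    length(blocks$rhythmic) > 0, length(blocks$jittered) > 0
  )
  out <- purrr::map(blocks, function(bl) {
    purrr::imap_dfr(bl, function(b, i) {
      ev <- b$events
      sel <- ev$event_kind == "chord" & !is.na(ev$preceding_isi_ms) &
        abs(ev$preceding_isi_ms - isi_ms) <= 0.5
      dplyr::mutate(ev[sel, ], block = i)
    })
  })
  if (any(purrr::map_int(out, nrow) == 0)) {
    stop("a condition has no chords preceded by the isochronous ISI",
      call. = FALSE
    )
  }
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> %d subjects (config %s)\n",
    length(x$subjects), x$manifest$config_hash
  ))
  invisible(x)
}
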