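#' Reaction-time exclusion mask
#'
#' Retains responses whose RT is at most the median plus two standard
#' deviations (both computed over all responses before exclusion); trials
#' strictly above the threshold are excluded.
#'
#' @param rts_ms Reaction times in ms (length >= 2).
#' @return Logical mask of retained trials.
#' @export
filter_rts <- function(rts_ms) {
  if (length(rts_ms) == 0) stop("empty RT vector", call. = FALSE)
  if (length(rts_ms) < 2) stop("need at least 2 responses", call. = FALSE)
  thr <- stats::median(rts_ms) + 2 * stats::sd(rts_ms)
  rts_ms <= thr
}

#' Signal-detection sensitivity and criterion
#'
#' Identity A is treated as the signal: a hit is a response "A" to a true A,
#' a false alarm a response "A" to a true B. `d' = z(hit) - z(fa)`,
#' `criterion = -(z(hit) + z(fa)) / 2`. Extreme rates (0 or 1) are handled by
#' the log-linear correction (add 0.5 to the count and 1 to the denominator
#' for that rate).
#'
#' @param true_identity,chosen_identity Character vectors of "A"/"B".
#' @return List with `dprime`, `criterion`, `hit_rate`, `fa_rate`.
#' @export
signal_detection <- function(true_identity, chosen_identity) {
  stopifnot(length(true_identity) == length(chosen_identity))
  n_a <- sum(true_identity == "A")
  n_b <- sum(true_identity == "B")
  if (n_a == 0 || n_b == 0) {
    stop("need at least one trial of each identity", call. = FALSE)
  }
  hits <- sum(true_identity == "A" & chosen_identity == "A")
  fas <- sum(true_identity == "B" & chosen_identity == "A")
  rate <- function(k, n) {
    if (k == 0 || k == n) (k + 0.5) / (n + 1) else k / n
  }
  hr <- rate(hits, n_a)
  far <- rate(fas, n_b)
  list(
    dprime = stats::qnorm(hr) - stats::qnorm(far),
    criterion = -(stats::qnorm(hr) + stats::qnorm(far)) / 2,
    hit_rate = hr, fa_rate = far
  )
}

#' Per-condition behavioral summary
#'
#' Applies the RT exclusion, then computes accuracy (percent correct of
#' included responses), d', criterion, and mean RT. In the jittered condition
#' only targets preceded by the isochronous ISI are analyzed, so targets are
#' matched across conditions on their immediately preceding interval.
#'
#' @param responses Tibble from [simulate_behavior()] (columns `condition`,
#'   `true_identity`, `chosen_identity`, `correct`, `rt_ms`,
#'   `preceding_isi_ms`), possibly spanning several blocks.
#' @param isi_ms Isochronous interval for the jittered-condition selection.
#' @return Tibble with one row per condition: `condition`, `accuracy` (%),
#'   `dprime`, `criterion`, `mean_rt_ms`, `n_included`, `n_excluded`.
#' @export
behavior_summary <- function(responses, isi_ms = 1000) {
  responses |>
    dplyr::filter(
      .data$condition == "rhythmic" |
        (!is.na(.data$preceding_isi_ms) &
          abs(.data$preceding_isi_ms - isi_ms) <= 0.5)
    ) |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) {
      keep <- filter_rts(df$rt_ms)
      inc <- df[keep, ]
      sd_out <- signal_detection(inc$true_identity, inc$chosen_identity)
      tibble::tibble(
        accuracy = 100 * mean(inc$correct),
        dprime = sd_out$dprime,
        criterion = sd_out$criterion,
        mean_rt_ms = mean(inc$rt_ms),
        n_included = nrow(inc),
        n_excluded = sum(!keep)
      )
    }) |>
    dplyr::ungroup()
}

#' Condition contrasts of behavioral measures
#'
#' Paired t tests (rhythmic vs jittered) on accuracy, d', criterion, and mean
#' RT across subjects. Subjects missing a condition are dropped with a
#' warning.
#'
#' @param summaries Tibble of per-subject summaries: a `subject` column plus
#'   the columns of [behavior_summary()].
#' @return Tibble with `measure`, `t`, `df`, `p`, `mean_diff` (rhythmic minus
#'   jittered).
#' @export
condition_contrast <- function(summaries) {
  wide <- summaries |>
    dplyr::select(
      "subject", "condition", "accuracy", "dprime", "criterion", "mean_rt_ms"
    ) |>
    tidyr::pivot_wider(
      names_from = "condition",
      values_from = c("accuracy", "dprime", "criterion", "mean_rt_ms")
    )
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) missing a condition; dropped",
      call. = FALSE
    )
    wide <- wide[complete, ]
  }
  purrr::map_dfr(
    c("accuracy", "dprime", "criterion", "mean_rt_ms"),
    function(ms) {
      res <- paired_ttest(
        wide[[paste0(ms, "_rhythmic")]],
        wide[[paste0(ms, "_jittered")]]
      )
      dplyr::bind_cols(tibble::tibble(measure = ms), res)
    }
  )
}
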