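#' Persist a recording as a self-describing on-disk container
#'
#' Writes the amplitude matrix as an Arrow/Feather table (self-describing,
#' column-typed), the event table alongside it, and the channel metadata and
#' sampling information as structured text (YAML), into one directory.
#'
#' @param rec A `meeg_recording`.
#' @param dir Target directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "meeg_recording"))
  if (!requireNamespace("arrow", quietly = TRUE) ||
    !requireNamespace("yaml", quietly = TRUE)) {
    stop("writing recordings requires the 'arrow' and 'yaml' packages",
      call. = FALSE
    )
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dat <- as.data.frame(rec$data)
  names(dat) <- rec$sensors$channel
  arrow::write_feather(dat, file.path(dir, "data.feather"))
  arrow::write_feather(rec$events, file.path(dir, "events.feather"))
  yaml::write_yaml(
    list(
      sample_rate_hz = rec$sr,
      condition = rec$condition,
      n_samples = nrow(rec$data),
      channels = lapply(seq_len(nrow(rec$sensors)), function(i) {
        as.list(rec$sensors[i, c("channel", "family", "x", "y", "z")])
      })
    ),
    file.path(dir, "meta.yaml")
  )
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Directory containing `data.feather`, `events.feather`,
#'   `meta.yaml`.
#' @return A `meeg_recording`.
#' @export
read_recording <- function(dir) {
  if (!requireNamespace("arrow", quietly = TRUE) ||
    !requireNamespace("yaml", quietly = TRUE)) {
    stop("reading recordings requires the 'arrow' and 'yaml' packages",
      call. = FALSE
    )
  }
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  dat <- as.matrix(arrow::read_feather(file.path(dir, "data.feather")))
  sensors <- dplyr::bind_rows(lapply(meta$channels, tibble::as_tibble))
  class(sensors) <- c("sensor_array", class(sensors))
  structure(
    list(
      data = unname(dat),
      sr = meta$sample_rate_hz,
      sensors = sensors,
      events = tibble::as_tibble(
        arrow::read_feather(file.path(dir, "events.feather"))
      ),
      condition = meta$condition,
      block = NULL
    ),
    class = "meeg_recording"
  )
}

#' Save ground-truth parameters as structured text
#'
#' @param truth A `ground_truth`.
#' @param path Output YAML file path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("writing ground truth requires the 'yaml' package", call. = FALSE)
  }
  yaml::write_yaml(lapply(unclass(truth), function(v) {
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  }), path)
  invisible(path)
}

#' Read ground-truth parameters written by [write_ground_truth()]
#'
#' @param path YAML file path.
#' @return A `ground_truth`.
#' @export
read_ground_truth <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading ground truth requires the 'yaml' package", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  named <- c(
    "entrain_strength", "gain_boost", "accuracy", "boost_window_ms"
  )
  for (f in intersect(named, names(raw))) {
    raw[[f]] <- unlist(raw[[f]])
  }
  do.call(ground_truth, raw)
}
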