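#' Read an electronic-nose run table
#'
#' @param file Long-format CSV with columns `sample`, `sensor`, `time_s`,
#'   `response`.
#' @return A tibble of the run(s).
#' @export
read_enose <- function(file) {
  run <- readr::read_csv(file, col_types = "ccdd", progress = FALSE)
  if (!all(c("sample", "sensor", "time_s", "response") %in% names(run))) {
    abort("enose table needs sample, sensor, time_s, response columns")
  }
  run
}

#' Stable-phase sensor profile of an E-nose run
#'
#' E-nose sensor traces rise rapidly over the first part of the detection
#' phase and then plateau; the fingerprint used for pattern recognition is
#' the per-sensor response in the stable phase. This function takes the
#' mean response of each sensor over the stable window (default 30–60 s),
#' which is robust to sensor noise; set `stat = "max"` for the peak
#' response instead.
#'
#' @param run Long tibble (`sample`, `sensor`, `time_s`, `response`), one
#'   or more runs.
#' @param window Two-element numeric, the stable-phase time window in
#'   seconds (default `c(30, 60)`).
#' @param stat `"mean"` (default) or `"max"` over the window.
#' @param baseline If `TRUE`, subtract each sensor's first-sample response
#'   before summarising (off by default; the instrument regenerates with a
#'   clean-air purge rather than baseline arithmetic).
#' @return A tibble of `sample`, `sensor`, `response` — one row per sensor
#'   per run; feeds [pca_fit()] after pivoting wide.
#' @examples
#' run <- generate_enose_run(c(a = 2, b = 4, c = 6, d = 3, e = 5, f = 1),
#'                           tau = 8, noise_sd = 0, seed = 1)
#' enose_features(run)
#' @export
enose_features <- function(run, window = c(30, 60), stat = c("mean", "max"),
                           baseline = FALSE) {
  stat <- arg_match(stat)
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("window must be an increasing time interval")
  }
  if (window[1] < min(run$time_s) || window[2] > max(run$time_s)) {
    abort("window outside the run's time span")
  }
  if (baseline) {
    run <- dplyr::mutate(
      dplyr::group_by(run, .data$sample, .data$sensor),
      response = .data$response - .data$response[which.min(.data$time_s)]
    )
    run <- dplyr::ungroup(run)
  }
  win <- dplyr::filter(run, .data$time_s >= window[1], .data$time_s <= window[2])
  if (nrow(win) == 0) abort("no observations inside the window")
  dplyr::summarise(
    dplyr::group_by(win, .data$sample, .data$sensor),
    response = if (stat == "mean") mean(.data$response) else max(.data$response),
    .groups = "drop"
  )
}

#' Fraction of maximum response reached at a given time
#'
#' Per sensor, the response at time `t` (nearest sampled point) divided by
#' that sensor's maximum response over the run, averaged across sensors.
#' Used to verify the rapid-rise phase, e.g. that the signal reaches 85% of
#' its maximum by 30 s.
#'
#' @param run Long tibble for a single run.
#' @param t Time in seconds, within the run's span.
#' @return A single fraction in \[0, 1\].
#' @export
rise_fraction <- function(run, t) {
  if (t < min(run$time_s) || t > max(run$time_s)) {
    abort("t outside the run's time span")
  }
  per_sensor <- dplyr::summarise(
    dplyr::group_by(run, .data$sensor),
    at_t = .data$response[which.min(abs(.data$time_s - t))],
    max_r = max(.data$response),
    .groups = "drop"
  )
  if (all(per_sensor$max_r <= 0)) abort("all-zero run")
  mean(per_sensor$at_t / per_sensor$max_r)
}

#' Radar-style plot of stable-phase sensor profiles
#'
#' @param profiles Tibble from [enose_features()].
#' @return A ggplot: sensors on a polar axis, one trace per sample.
#' @export
plot_sensor_profile <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$sensor, y = .data$response,
                               group = .data$sample, colour = .data$sample)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "stable-phase response") +
    ggplot2::theme_minimal()
}
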