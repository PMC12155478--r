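#' Read an odor-threshold table
#'
#' @param file CSV with columns `compound`, `ot_ug_per_l` — the olfactory
#'   threshold of each compound in water, μg/L.
#' @return A tibble; all thresholds must be positive.
#' @export
read_odor_thresholds <- function(file) {
  ot <- readr::read_csv(file, col_types = "cd", progress = FALSE)
  if (!all(c("compound", "ot_ug_per_l") %in% names(ot))) {
    abort("threshold table needs compound and ot_ug_per_l columns")
  }
  if (any(ot$ot_ug_per_l <= 0)) abort("odor thresholds must be positive")
  ot
}

#' Compute odor activity values (OAV)
#'
#' The OAV of a volatile in a sample is its concentration divided by its
#' olfactory threshold in water, \eqn{OAV_i = C_i / OT_i}. Compounds with
#' OAV above 1 are taken to contribute perceptibly to the aroma.
#'
#' Reported values follow the conventions of published OAV tables: censored
#' (not detected) concentrations report `"n.d."`; a raw OAV below 1 reports
#' `"<1"`; otherwise the raw value is rounded half-up to an integer. Raw
#' values are kept at full precision for downstream fold ranges and screens.
#'
#' @param table Long peak-table tibble from [read_peak_table()].
#' @param thresholds Threshold tibble from [read_odor_thresholds()].
#' @param compounds Compounds to score; defaults to every compound in
#'   `thresholds`. A requested compound missing an OT (or absent from the
#'   peak table) is an error naming the compound.
#' @return A tibble of `compound`, `sample`, `mean_conc`, `ot_ug_per_l`,
#'   `raw_oav` (`NA` when censored), and `report` (character).
#' @examples
#' tab <- read_peak_table(aromarker_example("tongcheng_peak_table.csv"))
#' ot <- read_odor_thresholds(aromarker_example("tongcheng_odor_thresholds.csv"))
#' oav <- compute_oav(tab, ot)
#' oav[oav$compound == "Dimethyl sulfide", ]
#' @export
compute_oav <- function(table, thresholds, compounds = NULL) {
  compounds <- compounds %||% thresholds$compound
  missing_ot <- setdiff(compounds, thresholds$compound)
  if (length(missing_ot) > 0) {
    abort(paste0("no odor threshold for: ", paste(missing_ot, collapse = ", ")))
  }
  missing_tab <- setdiff(compounds, table$compound)
  if (length(missing_tab) > 0) {
    abort(paste0("compound(s) not in peak table: ", paste(missing_tab, collapse = ", ")))
  }
  out <- dplyr::inner_join(
    dplyr::filter(table, .data$compound %in% compounds),
    thresholds,
    by = "compound"
  )
  out$raw_oav <- ifelse(out$detected, out$mean_conc / out$ot_ug_per_l, NA_real_)
  out$report <- oav_report(out$raw_oav)
  dplyr::select(out, "compound", "sample", "mean_conc", "ot_ug_per_l",
                "raw_oav", "report")
}

#' Format raw OAVs using the reporting rules
#'
#' @param raw_oav Numeric raw OAVs; `NA` means censored.
#' @return Character: `"n.d."` for censored, `"<1"` for raw values below 1,
#'   else the integer rounded half-up.
#' @export
oav_report <- function(raw_oav) {
  dplyr::case_when(
    is.na(raw_oav) ~ "n.d.",
    raw_oav < 1 ~ "<1",
    TRUE ~ as.character(round_half_up(raw_oav))
  )
}

#' Screen aroma-active compounds by maximum OAV
#'
#' A compound is active when its maximum raw (unrounded) OAV over samples
#' strictly exceeds the threshold.
#'
#' @param oav OAV tibble from [compute_oav()].
#' @param threshold Activity cut-off on the raw OAV (default 1).
#' @return A tibble of `compound`, `max_oav`, ordered by descending
#'   `max_oav`.
#' @export
screen_active <- function(oav, threshold = 1) {
  if (nrow(oav) == 0) abort("OAV matrix is empty")
  maxima <- dplyr::summarise(
    dplyr::group_by(oav, .data$compound),
    max_oav = if (all(is.na(.data$raw_oav))) NA_real_ else max(.data$raw_oav, na.rm = TRUE),
    .groups = "drop"
  )
  out <- dplyr::filter(maxima, !is.na(.data$max_oav) & .data$max_oav > threshold)
  dplyr::arrange(out, dplyr::desc(.data$max_oav))
}

#' Fold range of a compound's OAV across samples
#'
#' Maximum over minimum raw OAV among samples where the compound was
#' detected; a measure of how strongly the environment modulates an
#' odorant's activity.
#'
#' @param oav OAV tibble from [compute_oav()].
#' @param compound Compound name.
#' @return A single number ≥ 1 (full precision; report to 1 decimal).
#' @export
oav_fold_range <- function(oav, compound) {
  vals <- oav$raw_oav[oav$compound == compound & !is.na(oav$raw_oav)]
  if (length(vals) < 2) {
    abort(paste0(compound, " detected in fewer than 2 samples"))
  }
  max(vals) / min(vals)
}

#' Percent change relative to a reference value
#'
#' Signed percent, `(reference - comparison) / reference * 100`; positive
#' values are decreases from the reference. Round half-up to an integer for
#' reporting.
#'
#' @param reference Reference value (> 0), e.g. the standard-grade
#'   concentration.
#' @param comparison Comparison value, e.g. the premium-grade concentration.
#' @return Signed percent change at full precision.
#' @examples
#' percent_change(17.56, 2.98)  # ~83% decrease
#' @export
percent_change <- function(reference, comparison) {
  if (any(reference <= 0)) abort("reference must be positive")
  (reference - comparison) / reference * 100
}

#' Fold ratio of two values
#'
#' @param a Numerator.
#' @param b Denominator (> 0).
#' @return `a / b` at full precision; report to 1 decimal (half-up).
#' @examples
#' fold_ratio(142.51, 68.63)  # ~2.1-fold
#' @export
fold_ratio <- function(a, b) {
  if (any(b <= 0)) abort("denominator must be positive")
  a / b
}
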