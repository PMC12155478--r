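#' Internal-standard semi-quantification
#'
#' Single-point internal-standard method: the concentration of a target
#' compound is its peak area relative to the internal-standard area, scaled
#' by the known internal-standard concentration,
#' \deqn{C_i = (A_i / A_{IS}) \times C_{IS}.}
#' For the tea protocol (5 μL of 5 μg/mL 2-octanol into 10 mL of infusion)
#' the effective \eqn{C_{IS}} is 2.5 μg/L.
#'
#' @param area Peak area(s) of the target compound(s), arbitrary detector
#'   units, ≥ 0.
#' @param is_area Peak area of the internal standard (> 0).
#' @param is_conc Concentration of the internal standard, μg/L (> 0).
#' @return Concentration(s) in μg/L, linear in `area`.
#' @examples
#' semi_quantify(2e6, is_area = 1e6, is_conc = 2.5)  # 5 ug/L
#' @export
semi_quantify <- function(area, is_area, is_conc) {
  if (length(is_area) != 1 || is.na(is_area) || is_area <= 0) {
    abort("internal standard area must be a single positive number")
  }
  if (length(is_conc) != 1 || is.na(is_conc) || is_conc <= 0) {
    abort("internal standard concentration must be a single positive number")
  }
  if (any(area < 0, na.rm = TRUE)) abort("peak areas must be >= 0")
  (area / is_area) * is_conc
}

#' Semi-quantify a tidy peak-area table
#'
#' @param areas A data frame with at least `compound` and `area` columns
#'   (a `retention_time` column, minutes, is carried through if present).
#' @param is_area,is_conc Internal-standard peak area and concentration
#'   (μg/L); see [semi_quantify()].
#' @return The input tibble with a `conc` column (μg/L) appended.
#' @export
quantify_peaks <- function(areas, is_area, is_conc = 2.5) {
  areas <- tibble::as_tibble(areas)
  areas$conc <- semi_quantify(areas$area, is_area, is_conc)
  areas
}

#' Read an n-alkane retention-time ladder
#'
#' @param file CSV with columns `carbon_number`, `rt_min`.
#' @return A validated ladder tibble.
#' @export
read_alkane_ladder <- function(file) {
  ladder <- readr::read_csv(file, col_types = "id", progress = FALSE)
  validate_ladder(ladder)
}

validate_ladder <- function(ladder) {
  ladder <- tibble::as_tibble(ladder)
  if (!all(c("carbon_number", "rt_min") %in% names(ladder))) {
    abort("ladder needs carbon_number and rt_min columns")
  }
  ladder <- dplyr::arrange(ladder, .data$carbon_number)
  if (nrow(ladder) < 2) abort("ladder needs at least two alkanes")
  if (any(diff(ladder$carbon_number) <= 0)) abort("carbon numbers must be strictly increasing")
  if (any(diff(ladder$rt_min) <= 0)) abort("ladder retention times must be strictly increasing")
  ladder
}

#' Linear retention index under temperature-programmed GC
#'
#' van den Dool–Kratz index against a homologous n-alkane series:
#' \deqn{LRI = 100 n + 100 \frac{rt - t_n}{t_{n+1} - t_n}}
#' for a retention time bracketed by the alkanes with n and n+1 carbons.
#' Retention times outside the ladder span are an error — the caller may
#' then report `"<700"` for analytes eluting before the C7 alkane, as
#' published tables do, rather than extrapolate.
#'
#' @param rt Retention time(s), minutes.
#' @param ladder Ladder tibble (`carbon_number`, `rt_min`), e.g. from
#'   [read_alkane_ladder()] or [generate_alkane_ladder()].
#' @return Numeric LRI value(s); `100 * n` exactly at the n-alkane's own
#'   retention time, piecewise-linear and strictly increasing in `rt`.
#' @examples
#' ladder <- tibble::tibble(carbon_number = 7:12, rt_min = 2 * (7:12))
#' linear_retention_index(20.8, ladder)  # 1040
#' @export
linear_retention_index <- function(rt, ladder) {
  ladder <- validate_ladder(ladder)
  tn <- ladder$rt_min
  cn <- ladder$carbon_number
  if (any(rt < tn[1] | rt > tn[length(tn)])) {
    abort("retention time outside the alkane ladder span")
  }
  idx <- findInterval(rt, tn, rightmost.closed = TRUE)
  100 * cn[idx] + 100 * (cn[idx + 1] - cn[idx]) * (rt - tn[idx]) / (tn[idx + 1] - tn[idx])
}

#' Label retention indices the way published tables do
#'
#' Wraps [linear_retention_index()] but labels analytes eluting before the
#' first ladder alkane as `"<n00"` (e.g. `"<700"` for a C7-anchored ladder)
#' instead of extrapolating.
#'
#' @inheritParams linear_retention_index
#' @return Character vector: the rounded LRI, or `"<n00"` below the ladder.
#' @export
retention_index_label <- function(rt, ladder) {
  ladder <- validate_ladder(ladder)
  low <- rt < ladder$rt_min[1]
  out <- character(length(rt))
  out[low] <- paste0("<", 100 * ladder$carbon_number[1])
  if (any(!low)) {
    out[!low] <- as.character(round_half_up(linear_retention_index(rt[!low], ladder)))
  }
  out
}
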