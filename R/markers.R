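#' Select aroma markers by the joint VIP and OAV screen
#'
#' A compound is a candidate origin marker when it both discriminates the
#' classes in the PLS-DA model (VIP above the threshold) and is
#' aroma-active (maximum raw OAV over samples above the threshold). Both
#' comparisons are strict and applied to raw, unrounded values.
#'
#' @param vip VIP scores: a tibble with `compound` and `vip` columns (as
#'   from `tidy(model, "vip")`) or a named numeric vector.
#' @param oav OAV tibble from [compute_oav()]; must cover every compound in
#'   `vip`.
#' @param vip_threshold,oav_threshold Strict lower cut-offs (default 1).
#' @return A tibble of `compound`, `vip`, `max_oav`, `selected`, ordered by
#'   descending VIP. Raising either threshold never adds a compound.
#' @export
select_markers <- function(vip, oav, vip_threshold = 1, oav_threshold = 1) {
  if (is.numeric(vip) && !is.null(names(vip))) {
    vip <- tibble::tibble(compound = names(vip), vip = unname(vip))
  }
  vip <- tibble::as_tibble(vip)
  missing <- setdiff(vip$compound, oav$compound)
  if (length(missing) > 0) {
    abort(paste0("compound(s) missing from the OAV matrix: ",
                 paste(missing, collapse = ", ")))
  }
  maxima <- dplyr::summarise(
    dplyr::group_by(oav, .data$compound),
    max_oav = if (all(is.na(.data$raw_oav))) NA_real_ else max(.data$raw_oav, na.rm = TRUE),
    .groups = "drop"
  )
  out <- dplyr::left_join(vip, maxima, by = "compound")
  out$selected <- !is.na(out$max_oav) &
    out$vip > vip_threshold & out$max_oav > oav_threshold
  dplyr::arrange(out, dplyr::desc(.data$vip))
}

#' Contrast standard and premium grades within a region
#'
#' Per-compound comparison of the two batches of one region: the
#' premium/standard fold ratio and the percent decrease from standard to
#' premium (see [fold_ratio()] and [percent_change()]). Compounds censored
#' in one grade are flagged `"appeared"` (n.d. in standard, detected in
#' premium) or `"disappeared"` rather than given a ratio; compounds
#' censored in both are `"absent"`.
#'
#' @param table Long peak-table tibble.
#' @param region Region code present in `table`.
#' @param grades Length-2 character vector naming the reference (standard)
#'   and comparison (premium) grade codes.
#' @return A tibble of `compound`, `conc_S`, `conc_P`, `status`,
#'   `fold_ratio` (P/S), and `percent_change` (positive = decrease in
#'   premium).
#' @examples
#' tab <- read_peak_table(aromarker_example("tongcheng_peak_table.csv"))
#' yt <- grade_contrast(tab, "YT")
#' yt[yt$compound == "Dimethyl sulfide", ]
#' @export
grade_contrast <- function(table, region, grades = c("S", "P")) {
  sub <- dplyr::filter(table, .data$region == !!region)
  if (nrow(sub) == 0) abort(paste0("no samples for region ", region))
  have <- unique(sub$grade)
  if (!all(grades %in% have)) {
    abort(paste0("region ", region, " is missing grade(s): ",
                 paste(setdiff(grades, have), collapse = ", ")))
  }
  s_tab <- dplyr::filter(sub, .data$grade == grades[1])
  p_tab <- dplyr::filter(sub, .data$grade == grades[2])
  out <- dplyr::left_join(
    dplyr::select(s_tab, "compound", conc_S = "mean_conc", det_S = "detected"),
    dplyr::select(p_tab, "compound", conc_P = "mean_conc", det_P = "detected"),
    by = "compound"
  )
  out$status <- dplyr::case_when(
    out$det_S & out$det_P ~ "both",
    out$det_S & !out$det_P ~ "disappeared",
    !out$det_S & out$det_P ~ "appeared",
    TRUE ~ "absent"
  )
  both <- out$status == "both"
  out$fold_ratio <- ifelse(both, out$conc_P / out$conc_S, NA_real_)
  out$percent_change <- ifelse(both, (out$conc_S - out$conc_P) / out$conc_S * 100,
                               NA_real_)
  dplyr::select(out, "compound", "conc_S", "conc_P", "status",
                "fold_ratio", "percent_change")
}

# core of Duncan's multiple range test, working from per-group summary
# statistics (means, SDs, replicate counts)
duncan_core <- function(labels, means, sds, ns, alpha) {
  k <- length(means)
  if (k < 2) abort("need at least 2 groups")
  if (any(ns < 2)) abort("every group needs at least 2 replicates")
  df_err <- sum(ns) - k
  mse <- sum((ns - 1) * sds^2) / df_err
  if (length(unique(ns)) > 1) {
    warn("unequal replicate counts; using the harmonic mean n")
  }
  n_h <- k / sum(1 / ns)

  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  lab <- labels[ord]

  # protected least significant ranges for spans p = 2..k
  r_p <- vapply(2:k, function(p) {
    alpha_p <- 1 - (1 - alpha)^(p - 1)
    stats::qtukey(1 - alpha_p, p, df_err) * sqrt(mse / n_h)
  }, numeric(1))

  # range test with protection: a range is declared non-significant if its
  # spread is within r_p or if any containing range already was
  nonsig <- matrix(FALSE, k, k)
  for (p in k:2) {
    for (i in seq_len(k - p + 1)) {
      j <- i + p - 1
      covered <- FALSE
      if (p < k) {
        for (i2 in seq_len(i)) {
          j2_min <- max(j, i2 + p)  # strictly larger span
          if (j2_min <= k && any(nonsig[i2, j2_min:k])) covered <- TRUE
        }
      }
      if (covered || (m[i] - m[j]) <= r_p[p - 1]) nonsig[i, j] <- TRUE
    }
  }

  # letters: maximal non-significant runs in descending-mean order
  run_end <- vapply(seq_len(k), function(i) {
    ends <- which(nonsig[i, ])
    if (length(ends) == 0) i else max(ends)
  }, integer(1))
  # keep only maximal intervals (not contained in an earlier one)
  letters_out <- rep("", k)
  letter_i <- 0
  prev_end <- 0
  for (i in seq_len(k)) {
    if (run_end[i] > prev_end || (i > prev_end)) {
      letter_i <- letter_i + 1
      span <- i:run_end[i]
      letters_out[span] <- paste0(letters_out[span], letters[letter_i])
      prev_end <- run_end[i]
    }
  }

  tibble::tibble(group = lab, mean = m, n = ns[ord], letters = letters_out)
}

#' Duncan's multiple range test letters
#'
#' Post-ANOVA multiple comparison using Duncan's protected least
#' significant ranges. The error mean square and its degrees of freedom
#' come from the one-way ANOVA of the replicate values; the critical range
#' for a span of `p` ordered means is
#' \deqn{R_p = q^*(\alpha_p, p, df)\sqrt{MS_E/n}, \qquad
#' \alpha_p = 1 - (1-\alpha)^{p-1},}
#' with studentized-range quantiles `q*`. Means are sorted in descending
#' order and letters assigned by the standard covering procedure: groups
#' sharing any letter are not significantly different at level `alpha`.
#' Unequal replicate counts fall back to the harmonic mean `n` with a
#' warning. The letter pattern is invariant under positive affine
#' transformation of the data.
#'
#' @param data Data frame of replicate observations.
#' @param value,group Columns (unquoted) holding the measured value and the
#'   group label.
#' @param alpha Significance level (default 0.05).
#' @return A tibble of `group`, `mean`, `n`, `letters`, in descending mean
#'   order (letter `a` attaches to the largest mean).
#' @examples
#' d <- data.frame(
#'   g = rep(c("A", "B", "C"), each = 3),
#'   y = c(100, 101, 99, 50, 51, 49, 0, 1, -1)
#' )
#' duncan_letters(d, y, g)
#' @export
duncan_letters <- function(data, value, group, alpha = 0.05) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(v = v, g = g), .data$g),
    mean = mean(.data$v), sd = stats::sd(.data$v), n = dplyr::n(),
    .groups = "drop"
  )
  duncan_core(as.character(stats_tbl$g), stats_tbl$mean, stats_tbl$sd,
              stats_tbl$n, alpha)
}

#' Duncan letters from published summary statistics
#'
#' Variant of [duncan_letters()] for mean ± SD (n) tables, where replicate
#' values are not available but the pooled error mean square is recoverable
#' from the per-group SDs.
#'
#' @param data Data frame with one row per group.
#' @param group,mean,sd,n Columns (unquoted) holding the group label,
#'   mean, standard deviation, and replicate count.
#' @param alpha Significance level (default 0.05).
#' @return As [duncan_letters()].
#' @export
duncan_letters_from_stats <- function(data, group, mean, sd, n, alpha = 0.05) {
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  m <- rlang::eval_tidy(rlang::enquo(mean), data)
  s <- rlang::eval_tidy(rlang::enquo(sd), data)
  nn <- rlang::eval_tidy(rlang::enquo(n), data)
  duncan_core(as.character(g), m, s, nn, alpha)
}
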