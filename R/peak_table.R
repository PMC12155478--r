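#' Read a censored GC-MS peak (concentration) table
#'
#' Parses the wide CSV dialect used throughout the package: compound metadata
#' columns (`compound`, `cas`, `ri`, `id_basis`, `chem_class`,
#' `aroma_category`) followed by one `<sample>_mean` / `<sample>_sd` column
#' pair per sample, where a sample is named `<region>-<grade>` (e.g. `HY-S`).
#' The literal token `n.d.` (or an empty cell) marks a concentration censored
#' below the detection criterion; such cells parse to `detected = FALSE` with
#' missing mean and SD.
#'
#' @param file Path to the CSV file.
#' @param regions,grades Allowed region and grade codes; sample names outside
#'   these sets are an error.
#' @param n_replicates Number of replicate injections behind each mean ± SD
#'   cell (the standard protocol uses 3).
#' @return A tibble in long form with one row per compound × sample:
#'   compound metadata, `sample`, `region`, `grade`, `mean_conc` (μg/L, `NA`
#'   when censored), `sd` (μg/L), `detected`, and `n_replicates`.
#' @seealso [write_peak_table()] for the inverse, [region_presence()],
#'   [composition_profile()], [compute_oav()].
#' @examples
#' tab <- read_peak_table(aromarker_example("tongcheng_peak_table.csv"))
#' dplyr::count(tab, detected)
#' @export
read_peak_table <- function(file, regions = default_regions,
                            grades = default_grades, n_replicates = 3L) {
  raw <- readr::read_csv(file, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  meta_cols <- c("compound", "cas", "ri", "id_basis", "chem_class", "aroma_category")
  missing_meta <- setdiff("compound", names(raw))
  if (length(missing_meta) > 0) {
    abort("peak table must have a 'compound' column")
  }
  if (anyDuplicated(raw$compound)) {
    abort(paste0(
      "duplicate compound names: ",
      paste(unique(raw$compound[duplicated(raw$compound)]), collapse = ", ")
    ))
  }
  value_cols <- setdiff(names(raw), meta_cols)
  mean_cols <- grep("_mean$", value_cols, value = TRUE)
  sd_cols <- grep("_sd$", value_cols, value = TRUE)
  samples <- sub("_mean$", "", mean_cols)
  if (!setequal(samples, sub("_sd$", "", sd_cols))) {
    abort("every sample needs both a _mean and an _sd column")
  }
  key <- split_sample_key(samples, regions, grades)

  parse_cell <- function(x) {
    x <- ifelse(is.na(x) | x == "" | x == "n.d.", NA_character_, x)
    suppressWarnings(out <- as.numeric(x))
    if (any(is.na(out) & !is.na(x))) {
      abort(paste0("unparseable numeric cell(s): ",
                   paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", ")))
    }
    out
  }

  long <- purrr::map2_dfr(samples, seq_along(samples), function(s, i) {
    mean_conc <- parse_cell(raw[[paste0(s, "_mean")]])
    sd_val <- parse_cell(raw[[paste0(s, "_sd")]])
    tibble::tibble(
      compound = raw$compound,
      sample = s,
      region = key$region[i],
      grade = key$grade[i],
      mean_conc = mean_conc,
      sd = ifelse(is.na(mean_conc), NA_real_, sd_val),
      detected = !is.na(mean_conc),
      n_replicates = as.integer(n_replicates)
    )
  })
  if (any(long$mean_conc < 0, na.rm = TRUE) || any(long$sd < 0, na.rm = TRUE)) {
    abort("negative mean or sd in peak table")
  }

  meta <- tibble::tibble(compound = raw$compound)
  for (mc in setdiff(meta_cols, "compound")) {
    meta[[mc]] <- if (mc %in% names(raw)) raw[[mc]] else NA_character_
  }
  out <- dplyr::left_join(meta, long, by = "compound")
  # preserve compound order, then sample order, for deterministic output
  out$compound <- factor(out$compound, levels = raw$compound)
  out <- dplyr::arrange(out, .data$compound, match(.data$sample, samples))
  out$compound <- as.character(out$compound)
  out
}

#' Write a peak table back to the wide CSV dialect
#'
#' The inverse of [read_peak_table()]: censored cells are written as the
#' literal `n.d.`, numbers in canonical (shortest) decimal form, columns in
#' deterministic order. `write_peak_table(read_peak_table(f), f2)` reproduces
#' `f` byte-for-byte for files in canonical form.
#'
#' @param table Long peak-table tibble as returned by [read_peak_table()].
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_peak_table <- function(table, file) {
  samples <- unique(table$sample)
  meta_cols <- intersect(
    c("compound", "cas", "ri", "id_basis", "chem_class", "aroma_category"),
    names(table)
  )
  meta <- dplyr::distinct(table[, meta_cols, drop = FALSE])
  wide <- meta
  for (s in samples) {
    rows <- table[table$sample == s, ]
    rows <- rows[match(meta$compound, rows$compound), ]
    wide[[paste0(s, "_mean")]] <- ifelse(rows$detected, format_num(rows$mean_conc), "n.d.")
    wide[[paste0(s, "_sd")]] <- ifelse(rows$detected, format_num(rows$sd), "n.d.")
  }
  readr::write_csv(wide, file, progress = FALSE)
  invisible(file)
}

#' Path to a packaged example data set
#'
#' @param file Name of a file under the package's `extdata` directory; with
#'   no argument, lists the available files. Shipped fixtures are the
#'   66-compound × 8-sample tea volatile concentration table and the matching
#'   odor-threshold table.
#' @return A file path (or a character vector of file names).
#' @examples
#' aromarker_example()
#' @export
aromarker_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "aromarker"))
  } else {
    path <- system.file("extdata", file, package = "aromarker")
    if (path == "") abort(paste0("no packaged file called '", file, "'"))
    path
  }
}

#' Region presence of each compound
#'
#' A compound is counted as present in a region when it was detected in at
#' least one sample (either grade/batch) from that region. This
#' detected-in-at-least-one-batch rule is what reproduces the published
#' per-region volatile counts for the packaged tea table.
#'
#' @param table Long peak-table tibble.
#' @return A tibble with one row per (compound, region) presence pair,
#'   compounds detected nowhere are dropped.
#' @seealso [presence_counts()], [venn_partition()]
#' @examples
#' tab <- read_peak_table(aromarker_example("tongcheng_peak_table.csv"))
#' presence_counts(region_presence(tab))
#' @export
region_presence <- function(table) {
  regions <- unique(table$region)
  per_region <- dplyr::summarise(
    dplyr::group_by(table, .data$compound, .data$region),
    present = any(.data$detected),
    .groups = "drop"
  )
  n_samples <- dplyr::count(dplyr::distinct(table, .data$sample, .data$region), .data$region)
  if (any(!regions %in% n_samples$region)) {
    abort("region with zero samples")
  }
  dplyr::select(
    dplyr::filter(per_region, .data$present),
    "compound", "region"
  )
}

#' Per-region presence counts
#'
#' @param presence Presence tibble from [region_presence()].
#' @return A tibble of `region`, `n_compounds`.
#' @export
presence_counts <- function(presence) {
  dplyr::count(presence, .data$region, name = "n_compounds")
}

#' Venn partition of compound presence across regions
#'
#' Tallies, for every non-empty subset of regions, the number of compounds
#' present in exactly that subset. Counts sum to the number of compounds
#' present anywhere; the full-subset count is the shared core.
#'
#' @param presence Presence tibble from [region_presence()].
#' @return A tibble of `regions` (a `+`-joined subset label, regions in
#'   sorted order), `n_regions`, and `n_compounds`, covering all
#'   `2^k - 1` non-empty subsets (zero counts included).
#' @examples
#' tab <- read_peak_table(aromarker_example("tongcheng_peak_table.csv"))
#' vp <- venn_partition(region_presence(tab))
#' vp[vp$n_regions == 4, ]  # compounds shared by all four regions
#' @export
venn_partition <- function(presence) {
  if (nrow(presence) == 0) abort("presence mapping is empty")
  regions <- sort(unique(presence$region))
  sets <- dplyr::summarise(
    dplyr::group_by(presence, .data$compound),
    regions = paste(sort(unique(.data$region)), collapse = "+"),
    .groups = "drop"
  )
  combos <- unlist(lapply(seq_along(regions), function(k) {
    apply(utils::combn(regions, k), 2, paste, collapse = "+")
  }))
  counts <- table(factor(sets$regions, levels = combos))
  tibble::tibble(
    regions = combos,
    n_regions = stringr::str_count(combos, stringr::fixed("+")) + 1L,
    n_compounds = as.integer(counts)
  )
}

#' Composition profile by chemical class or aroma category
#'
#' Per-sample percentage of the summed detected concentration contributed by
#' each category. Censored cells contribute zero (proportions are of
#' identified volatiles only, no imputation below the detection limit).
#'
#' @param table Long peak-table tibble.
#' @param by `"chem_class"` or `"aroma_category"`.
#' @return A tibble of `sample`, category column, and `percent`; percentages
#'   sum to 100 within each sample.
#' @examples
#' tab <- read_peak_table(aromarker_example("tongcheng_peak_table.csv"))
#' composition_profile(tab, "chem_class")
#' @export
composition_profile <- function(table, by = c("chem_class", "aroma_category")) {
  by <- arg_match(by)
  if (any(is.na(table[[by]]))) {
    abort(paste0("every compound needs a ", by, " label"))
  }
  conc <- dplyr::mutate(table, conc = ifelse(.data$detected, .data$mean_conc, 0))
  totals <- dplyr::summarise(dplyr::group_by(conc, .data$sample),
                             total = sum(.data$conc), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort(paste0("sample(s) with zero total detected concentration: ",
                 paste(totals$sample[totals$total <= 0], collapse = ", ")))
  }
  out <- dplyr::summarise(
    dplyr::group_by(conc, .data$sample, .data[[by]]),
    conc = sum(.data$conc), .groups = "drop"
  )
  out <- dplyr::left_join(out, totals, by = "sample")
  out$percent <- 100 * out$conc / out$total
  dplyr::select(out, "sample", dplyr::all_of(by), "percent")
}
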