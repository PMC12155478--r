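write_stamped_csv <- function(x, file) {
  version <- as.character(utils::packageVersion("aromarker"))
  readr::write_lines(paste0("# aromarker ", version), file)
  readr::write_csv(x, file, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(file)
}

#' Run the full volatile-profiling pipeline
#'
#' One-shot, deterministic orchestration of every stage: OAV computation
#' and screening, composition profiles, region presence and Venn
#' partition, autoscaled PCA and hierarchical clustering, region PLS-DA
#' with VIP scores, the joint VIP/OAV marker screen, per-region grade
#' contrasts, and Duncan letters per compound. All outputs are written as
#' version-stamped CSVs plus a JSON summary; re-running with the same
#' inputs reproduces the files byte-for-byte.
#'
#' @param peak_file Peak-table CSV (see [read_peak_table()]).
#' @param thresholds_file Odor-threshold CSV (see
#'   [read_odor_thresholds()]).
#' @param out_dir Output directory (created if needed).
#' @param vip_cut,oav_cut Strict marker-screen thresholds (default 1).
#' @param alpha Significance level for Duncan letters.
#' @param n_components PLS-DA components; default is number of regions − 1.
#' @param pca_k PCA components to keep (default 2).
#' @param hca_linkage Linkage for the sample dendrogram.
#' @return The summary list (also written to `summary.json`), invisibly.
#' @examples
#' \donttest{
#' out <- run_pipeline(
#'   aromarker_example("tongcheng_peak_table.csv"),
#'   aromarker_example("tongcheng_odor_thresholds.csv"),
#'   tempfile("aromarker-run-")
#' )
#' out$n_active_compounds
#' }
#' @export
run_pipeline <- function(peak_file, thresholds_file, out_dir,
                         vip_cut = 1, oav_cut = 1, alpha = 0.05,
                         n_components = NULL, pca_k = 2,
                         hca_linkage = "ward") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  table <- stage("parse", read_peak_table(peak_file))
  thresholds <- stage("parse", read_odor_thresholds(thresholds_file))

  oav <- stage("oav", compute_oav(table, thresholds))
  write_stamped_csv(oav, file.path(out_dir, "oav_matrix.csv"))

  active <- stage("oav", screen_active(oav, oav_cut))
  write_stamped_csv(active, file.path(out_dir, "active_compounds.csv"))

  composition <- stage("composition", dplyr::bind_rows(
    dplyr::mutate(
      dplyr::rename(composition_profile(table, "chem_class"), category = "chem_class"),
      by = "chem_class"
    ),
    dplyr::mutate(
      dplyr::rename(composition_profile(table, "aroma_category"), category = "aroma_category"),
      by = "aroma_category"
    )
  ))
  write_stamped_csv(composition, file.path(out_dir, "composition.csv"))

  presence <- stage("presence", region_presence(table))
  venn <- stage("presence", venn_partition(presence))
  write_stamped_csv(venn, file.path(out_dir, "venn.csv"))

  m <- stage("chemometrics", suppressWarnings(autoscale(peak_matrix(table))))
  pca <- stage("chemometrics", pca_fit(m, k = pca_k))
  write_stamped_csv(tidy(pca, "scores"), file.path(out_dir, "pca_scores.csv"))

  hca <- stage("chemometrics", hca_fit(m, linkage = hca_linkage))
  merges <- tidy(hca)
  merges$members <- vapply(seq_len(nrow(merges)), function(i) {
    leaves <- function(node) {
      if (node < 0) return(hca$labels[-node])
      unlist(lapply(hca$merge[node, ], leaves))
    }
    paste(sort(leaves(i)), collapse = "+")
  }, character(1))
  write_stamped_csv(merges, file.path(out_dir, "hca_merges.csv"))

  classes <- table$region[match(rownames(m), table$sample)]
  plsda <- stage("plsda", plsda_fit(m, classes, n_components = n_components,
                                    scale. = FALSE))
  vip_tbl <- tidy(plsda, "vip")
  write_stamped_csv(vip_tbl, file.path(out_dir, "plsda_vip.csv"))

  vip_scored <- dplyr::filter(vip_tbl, .data$compound %in% oav$compound)
  markers <- stage("markers", select_markers(vip_scored, oav,
                                             vip_threshold = vip_cut,
                                             oav_threshold = oav_cut))
  write_stamped_csv(markers, file.path(out_dir, "markers.csv"))

  contrasts <- stage("grade_contrast", dplyr::bind_rows(lapply(
    sort(unique(table$region)),
    function(r) dplyr::mutate(grade_contrast(table, r), region = r, .before = 1)
  )))
  write_stamped_csv(contrasts, file.path(out_dir, "grade_contrasts.csv"))

  letters_tbl <- stage("duncan", dplyr::bind_rows(lapply(
    unique(table$compound),
    function(cp) {
      rows <- table[table$compound == cp & table$detected, ]
      if (nrow(rows) < 2) return(NULL)
      out <- duncan_letters_from_stats(rows, .data$sample, .data$mean_conc,
                                       .data$sd, .data$n_replicates,
                                       alpha = alpha)
      dplyr::mutate(out, compound = cp, .before = 1)
    }
  )))
  write_stamped_csv(letters_tbl, file.path(out_dir, "duncan_letters.csv"))

  counts <- presence_counts(presence)
  summary <- list(
    package_version = as.character(utils::packageVersion("aromarker")),
    n_compounds = length(unique(table$compound)),
    n_samples = length(unique(table$sample)),
    n_active_compounds = nrow(active),
    active_compounds = active$compound,
    presence_counts = setNames(as.list(counts$n_compounds), counts$region),
    shared_core = venn$n_compounds[which.max(venn$n_regions)],
    selected_markers = markers$compound[markers$selected],
    pca_explained_variance = round(100 * pca$explained_variance, 1)
  )
  # headline OAV reports for the screened compounds
  headline <- dplyr::filter(oav, .data$compound %in% active$compound)
  summary$oav_reports <- split(
    setNames(headline$report, headline$sample), headline$compound
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
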