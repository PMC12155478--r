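# packaged in-paper fixtures (read once per test file)
fixture_peaks <- function() {
  read_peak_table(aromarker_example("tongcheng_peak_table.csv"))
}
fixture_thresholds <- function() {
  read_odor_thresholds(aromarker_example("tongcheng_odor_thresholds.csv"))
}

# build a long peak-table tibble from a compounds x samples matrix of means
# (NA = censored); sds defaults to 10% of the mean
make_peak_tbl <- function(means, sds = NULL, chem_class = NULL,
                          aroma_category = NULL, n_replicates = 3L) {
  compounds <- rownames(means)
  samples <- colnames(means)
  if (is.null(sds)) sds <- means * 0.1
  if (is.null(chem_class)) chem_class <- rep("terpene", length(compounds))
  if (is.null(aroma_category)) aroma_category <- rep("floral", length(compounds))
  region <- sub("-.*", "", samples)
  grade <- sub(".*-", "", samples)
  purrr::map_dfr(seq_along(compounds), function(i) {
    tibble::tibble(
      compound = compounds[i], cas = NA_character_, ri = NA_character_,
      id_basis = "MS", chem_class = chem_class[i],
      aroma_category = aroma_category[i],
      sample = samples, region = region, grade = grade,
      mean_conc = unname(means[i, ]),
      sd = unname(ifelse(is.na(means[i, ]), NA, sds[i, ])),
      detected = unname(!is.na(means[i, ])), n_replicates = n_replicates
    )
  })
}

# brute-force agglomeration oracle (Lance-Williams updates on a full
# distance matrix); returns merge heights in order
bf_hca_heights <- function(m, linkage) {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  use_sq <- linkage == "ward"
  D <- if (use_sq) d^2 else d
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- c(NA, NA); best_d <- Inf
    for (a in idx) for (b in idx) if (a < b && D[a, b] < best_d) {
      best <- c(a, b); best_d <- D[a, b]
    }
    i <- best[1]; j <- best[2]
    heights[step] <- if (use_sq) sqrt(best_d) else best_d
    for (k in idx) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- switch(linkage,
        ward = ((sizes[i] + sizes[k]) * D[i, k] +
                (sizes[j] + sizes[k]) * D[j, k] -
                sizes[k] * D[i, j]) / (sizes[i] + sizes[j] + sizes[k]),
        average = (sizes[i] * D[i, k] + sizes[j] * D[j, k]) /
          (sizes[i] + sizes[j]),
        complete = max(D[i, k], D[j, k])
      )
    }
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  heights
}

# one full synthetic screen: generate -> OAV -> PLS-DA VIP -> joint screen;
# study conditions: 5 planted markers at 4x region effect, 12/40 compounds
# aroma-active (the study's ~27% active fraction), triplicate CV 0.15
recovery_run <- function(seed) {
  markers <- sprintf("C%02d", c(3, 11, 19, 27, 35))
  regions <- c("HY", "LM", "SX", "YT")
  eff <- tibble::tibble(compound = markers,
                        region = regions[c(1, 2, 3, 4, 1)], factor = 4)
  cfg <- synth_config(n_compounds = 40, cv_replicate = 0.15, lod = 0.05,
                      region_effects = eff)
  gen <- generate_peak_table(cfg, seed = seed)
  bl <- setNames(gen$truth$baseline$baseline, gen$truth$baseline$compound)
  nulls <- setdiff(names(bl), markers)
  active_nulls <- nulls[seq_len(7)]
  ot <- tibble::tibble(
    compound = names(bl),
    ot_ug_per_l = dplyr::case_when(
      names(bl) %in% markers ~ bl / 2,
      names(bl) %in% active_nulls ~ bl,
      TRUE ~ 3 * bl
    )
  )
  oav <- compute_oav(gen$peaks, ot)
  m <- suppressWarnings(autoscale(replicate_matrix(gen)))
  cls <- sub("-.*", "", rownames(m))
  fit <- plsda_fit(m, cls, n_components = 3, scale. = FALSE)
  sel <- select_markers(tidy(fit, "vip"), oav)
  picked <- sel$compound[sel$selected]
  list(planted = markers, picked = picked,
       recovered_all = all(markers %in% picked),
       false_positives = length(setdiff(picked, markers)))
}
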