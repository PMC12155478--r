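# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic peak-table generator
#'
#' Defaults emulate the study design the pipeline targets: 8 samples
#' (4 regions × 2 grades) of roughly 66 volatiles measured in triplicate,
#' with lognormal baseline concentrations of a few μg/L, ~20% replicate
#' CV (the scale-free noise typical of semi-quantified GC-MS tables),
#' multiplicative region/grade effects, and all-or-nothing censoring of
#' cell means below a detection limit.
#'
#' @param n_compounds Number of volatiles.
#' @param regions,grades Factor levels of the design.
#' @param n_replicates Replicate injections per cell (default 3).
#' @param base_log_mean,base_log_sd Lognormal parameters of per-compound
#'   baseline concentrations (μg/L).
#' @param region_effects,grade_effects Optional tibbles
#'   (`compound`, `region`/`grade`, `factor`) of multiplicative effects;
#'   all factors must be positive. Compounds given a region effect are the
#'   planted markers recorded in the ground truth.
#' @param cv_replicate Relative SD of replicate draws, in \[0, 1).
#' @param lod Detection limit, μg/L: cells whose replicate mean falls below
#'   it are censored to `n.d.`.
#' @return A validated config list of class `synth_config`.
#' @export
synth_config <- function(n_compounds = 66, regions = default_regions,
                         grades = default_grades, n_replicates = 3,
                         base_log_mean = log(5), base_log_sd = 1,
                         region_effects = NULL, grade_effects = NULL,
                         cv_replicate = 0.2, lod = 0.5) {
  if (n_compounds < 1) abort("n_compounds must be >= 1")
  if (cv_replicate < 0 || cv_replicate >= 1) abort("cv_replicate must be in [0, 1)")
  if (lod < 0) abort("lod must be >= 0")
  for (eff in list(region_effects, grade_effects)) {
    if (!is.null(eff) && any(eff$factor <= 0)) abort("effect factors must be positive")
  }
  structure(
    list(n_compounds = as.integer(n_compounds), regions = regions,
         grades = grades, n_replicates = as.integer(n_replicates),
         base_log_mean = base_log_mean, base_log_sd = base_log_sd,
         region_effects = region_effects, grade_effects = grade_effects,
         cv_replicate = cv_replicate, lod = lod),
    class = "synth_config"
  )
}

#' Generate a synthetic censored peak table with ground truth
#'
#' Replicate concentrations are drawn lognormally around region- and
#' grade-adjusted baselines (moment-matched so the expected replicate mean
#' equals the true cell concentration and the relative SD equals
#' `cv_replicate`), summarised to per-cell mean ± SD, and censored to
#' `n.d.` when the cell mean falls below the detection limit. Identical
#' seeds give identical output.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A list with `peaks` (long peak-table tibble, same schema as
#'   [read_peak_table()]), `replicates` (compound × sample × replicate
#'   draws, with a `censored` flag copied from the cell), and `truth`
#'   (per-compound baselines, the true noise-free cell means, and the
#'   planted marker compounds with their effect sizes).
#' @examples
#' gen <- generate_peak_table(synth_config(n_compounds = 10), seed = 1)
#' head(gen$peaks)
#' @export
generate_peak_table <- function(config, seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    chem_levels <- c("terpene", "aldehyde", "alcohol", "ester", "ketone",
                     "heterocyclic", "other")
    aroma_levels <- c("floral", "woody", "green", "fruity", "malty",
                      "roasty", "other")
    compounds <- sprintf("C%02d", seq_len(config$n_compounds))
    meta <- tibble::tibble(
      compound = compounds,
      cas = NA_character_, ri = NA_character_, id_basis = "MS",
      chem_class = rep_len(chem_levels, config$n_compounds),
      aroma_category = rep_len(aroma_levels, config$n_compounds)
    )
    baseline <- exp(rnorm(config$n_compounds, config$base_log_mean,
                          config$base_log_sd))
    names(baseline) <- compounds

    design <- tidyr::expand_grid(
      compound = compounds,
      region = config$regions,
      grade = config$grades
    )
    design$sample <- paste(design$region, design$grade, sep = "-")
    design$true_conc <- unname(baseline[design$compound])
    if (!is.null(config$region_effects)) {
      eff <- dplyr::left_join(design, config$region_effects,
                              by = c("compound", "region"))
      design$true_conc <- design$true_conc * dplyr::coalesce(eff$factor, 1)
    }
    if (!is.null(config$grade_effects)) {
      eff <- dplyr::left_join(design, config$grade_effects,
                              by = c("compound", "grade"))
      design$true_conc <- design$true_conc * dplyr::coalesce(eff$factor, 1)
    }

    cv <- config$cv_replicate
    n_rep <- config$n_replicates
    sdlog <- sqrt(log1p(cv^2))
    draws <- if (cv > 0) {
      matrix(
        exp(rnorm(nrow(design) * n_rep,
                  mean = rep(log(design$true_conc) - sdlog^2 / 2, each = n_rep),
                  sd = sdlog)),
        nrow = nrow(design), byrow = TRUE
      )
    } else {
      matrix(rep(design$true_conc, each = n_rep),
             nrow = nrow(design), byrow = TRUE)
    }
    design$mean_conc <- rowMeans(draws)
    design$sd <- apply(draws, 1, stats::sd)
    design$detected <- design$mean_conc >= config$lod

    replicates <- tibble::tibble(
      compound = rep(design$compound, each = n_rep),
      sample = rep(design$sample, each = n_rep),
      region = rep(design$region, each = n_rep),
      grade = rep(design$grade, each = n_rep),
      replicate = rep(seq_len(n_rep), nrow(design)),
      conc = as.vector(t(draws)),
      censored = rep(!design$detected, each = n_rep)
    )

    peaks <- dplyr::left_join(meta, design, by = "compound")
    peaks <- dplyr::mutate(
      peaks,
      mean_conc = ifelse(.data$detected, .data$mean_conc, NA_real_),
      sd = ifelse(.data$detected, .data$sd, NA_real_),
      n_replicates = n_rep
    )
    peaks <- dplyr::select(
      peaks, "compound", "cas", "ri", "id_basis", "chem_class",
      "aroma_category", "sample", "region", "grade", "mean_conc", "sd",
      "detected", "n_replicates"
    )

    markers <- if (is.null(config$region_effects)) {
      tibble::tibble(compound = character(), region = character(),
                     factor = numeric())
    } else {
      config$region_effects
    }
    list(
      peaks = peaks,
      replicates = replicates,
      truth = list(
        baseline = tibble::tibble(compound = compounds,
                                  baseline = unname(baseline)),
        true_means = dplyr::select(design, "compound", "sample", "true_conc"),
        planted_markers = markers
      )
    )
  })
}

#' Replicate-level data matrix from a synthetic generation
#'
#' @param gen Result of [generate_peak_table()].
#' @return A numeric matrix with one row per sample × replicate (rownames
#'   `sample.replicate`) and one column per compound; replicates belonging
#'   to censored cells are set to 0, mirroring how censored cells enter the
#'   chemometric matrix.
#' @export
replicate_matrix <- function(gen) {
  reps <- gen$replicates
  reps$conc[reps$censored] <- 0
  reps$row_id <- paste(reps$sample, reps$replicate, sep = ".")
  wide <- tidyr::pivot_wider(
    dplyr::select(reps, "row_id", "compound", "conc"),
    names_from = "compound", values_from = "conc"
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$row_id
  m
}

#' Sample × compound concentration matrix from a peak table
#'
#' @param table Long peak-table tibble.
#' @return Numeric matrix, samples in rows, compounds in columns; censored
#'   cells are 0.
#' @export
peak_matrix <- function(table) {
  tab <- dplyr::mutate(table, conc = ifelse(.data$detected, .data$mean_conc, 0))
  wide <- tidyr::pivot_wider(
    dplyr::select(tab, "sample", "compound", "conc"),
    names_from = "compound", values_from = "conc"
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample
  m
}

#' Generate a synthetic E-nose run
#'
#' Each sensor follows a saturating exponential rise to its archetype
#' plateau, \eqn{r_s(t) = R_s (1 - e^{-t/\tau})}, plus Gaussian noise —
#' the rapid-rise-then-plateau shape of metal-oxide sensor traces. With
#' the default `tau = 8` s the trace reaches ~98% of its plateau by 30 s,
#' comfortably past the 85%-of-maximum benchmark of the rise phase.
#'
#' @param archetype Named numeric vector of plateau responses, one per
#'   sensor (names become sensor ids; 6 sensors in the standard array).
#' @param tau Rise time constant, seconds (> 0).
#' @param noise_sd SD of additive Gaussian noise.
#' @param seed Integer seed (noise only; the noise-free component is
#'   deterministic).
#' @param sample Sample label for the run.
#' @param times Sampling grid, seconds (default 0–60 s at 0.5 s).
#' @return Long tibble (`sample`, `sensor`, `time_s`, `response`).
#' @export
generate_enose_run <- function(archetype, tau = 8, noise_sd = 0.05, seed = 1,
                               sample = "run1", times = seq(0, 60, by = 0.5)) {
  if (tau <= 0) abort("tau must be positive")
  sensors <- names(archetype) %||% paste0("S", seq_along(archetype))
  with_seed(seed, {
    grid <- tidyr::expand_grid(sensor = sensors, time_s = times)
    plateau <- setNames(as.numeric(archetype), sensors)
    clean <- unname(plateau[grid$sensor]) * (1 - exp(-grid$time_s / tau))
    tibble::tibble(
      sample = sample,
      sensor = grid$sensor,
      time_s = grid$time_s,
      response = clean + rnorm(nrow(grid), 0, noise_sd)
    )
  })
}

#' Generate a synthetic n-alkane retention-time ladder
#'
#' An arithmetic retention-time grid over the requested carbon range, with
#' optional uniform jitter; regeneration is attempted (up to 100 draws) if
#' jitter breaks strict monotonicity.
#'
#' @param c_min,c_max First and last carbon numbers (default C7–C40).
#' @param t0 Retention time of the first alkane, minutes.
#' @param spacing Retention-time spacing between consecutive alkanes,
#'   minutes (> 0).
#' @param jitter Half-width of uniform retention-time jitter, minutes.
#' @param seed Integer seed.
#' @return Ladder tibble (`carbon_number`, `rt_min`), strictly increasing.
#' @export
generate_alkane_ladder <- function(c_min = 7, c_max = 40, t0 = 2,
                                   spacing = 1.2, jitter = 0, seed = 1) {
  if (spacing <= 0) abort("spacing must be positive")
  if (c_max < c_min) abort("c_max must be >= c_min")
  cn <- seq(c_min, c_max)
  base_rt <- t0 + spacing * (cn - c_min)
  with_seed(seed, {
    for (attempt in seq_len(100)) {
      rt <- base_rt + runif(length(cn), -jitter, jitter)
      if (length(rt) < 2 || all(diff(rt) > 0)) {
        return(tibble::tibble(carbon_number = cn, rt_min = rt))
      }
    }
    abort("could not generate a monotone ladder in 100 attempts; reduce jitter")
  })
}
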