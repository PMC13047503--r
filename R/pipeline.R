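#' Run configuration
#'
#' Bundles every tunable of the simulate/analyze pipeline with its
#' default, so a run is fully described by one object plus a master
#' seed. All defaults are recorded into the run log.
#'
#' @param presets Named list of [cohort_preset()]s.
#' @param protocol A [nirs_protocol()].
#' @param fit_config A [nirs_fit_config()].
#' @param asl An [asl_params()].
#' @param oximetry An [oximetry_params()].
#' @param geometry An [asl_geometry()].
#' @param noise_sd_od NIRS frame noise (OD).
#' @param asl_noise_sd ASL single-average image noise (signal units).
#' @param frame_stride NIRS frame thinning factor.
#' @param seed Master seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(presets = builtin_presets(),
                       protocol = nirs_protocol(),
                       fit_config = nirs_fit_config(),
                       asl = asl_params(),
                       oximetry = oximetry_params(),
                       geometry = asl_geometry(),
                       noise_sd_od = 1e-3, asl_noise_sd = 20,
                       frame_stride = 1, seed = 1) {
  stopifnot(inherits(protocol, "nirs_protocol"),
            inherits(fit_config, "nirs_fit_config"),
            inherits(asl, "asl_params"),
            inherits(oximetry, "oximetry_params"))
  if (!all(vapply(presets, inherits, logical(1), "cohort_preset"))) {
    abort("presets must be cohort_preset objects",
          class = "oxymetr_config_error")
  }
  structure(list(presets = presets, protocol = protocol,
                 fit_config = fit_config, asl = asl, oximetry = oximetry,
                 geometry = geometry, noise_sd_od = noise_sd_od,
                 asl_noise_sd = asl_noise_sd, frame_stride = frame_stride,
                 seed = seed),
            class = "run_config")
}

#' Simulate a full synthetic dataset to disk
#'
#' Wraps [generate_cohort()] with a [run_config()] and writes a
#' provenance log (`run_log.json`: package version, seed, configuration)
#' next to the data.
#'
#' @param config A [run_config()].
#' @param dir Output directory.
#' @return The ground-truth manifest tibble, invisibly.
#' @export
run_simulate <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  manifest <- generate_cohort(dir, presets = config$presets,
                              seed = config$seed,
                              protocol = config$protocol,
                              noise_sd_od = config$noise_sd_od,
                              asl_noise_sd = config$asl_noise_sd,
                              frame_stride = config$frame_stride,
                              geometry = config$geometry)
  log <- list(package = "oxymetr",
              version = as.character(utils::packageVersion("oxymetr")),
              seed = config$seed,
              n_animals = nrow(manifest),
              protocol = unclass(config$protocol),
              fit_config = unclass(config$fit_config),
              asl = unclass(config$asl),
              oximetry = unclass(config$oximetry),
              noise_sd_od = config$noise_sd_od,
              asl_noise_sd = config$asl_noise_sd,
              frame_stride = config$frame_stride)
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

analyze_one_animal <- function(adir, config, projectors) {
  frames <- readr::read_csv(file.path(adir, "spectra.csv"),
                            show_col_types = FALSE, progress = FALSE)
  table <- builtin_extinction_table()
  nirs <- analyze_nirs(frames, table, config$protocol, config$fit_config,
                       projectors = projectors)
  stack <- read_asl_stack(file.path(adir, "asl"))
  asl <- analyze_asl(stack, config$asl, fit_mask = stack$mask)
  dplyr::bind_cols(
    nirs,
    tibble::tibble(CBF = asl$roi$mean, CBF_sd = asl$roi$sd,
                   n_voxels = asl$roi$n_voxels)
  )
}

#' Analyze a simulated or measured dataset directory
#'
#' Runs the per-animal NIRS + ASL + oximetry quantification over a
#' dataset tree written by [run_simulate()] / [generate_cohort()], then
#' the cohort statistics: Kruskal-Wallis with Bonferroni pairwise
#' comparisons per metric, per-group summaries, and the 2-SD hypoxia
#' classification against the recovered naive reference. Animals with
#' missing files are excluded (listed in the exclusion log) and the run
#' continues. The ground-truth manifest is never read.
#'
#' @param config A [run_config()].
#' @param dir Dataset directory.
#' @param out_dir Optional output directory for `cohort.csv` and
#'   `stats.json`.
#' @return List: `cohort` (per-animal tibble), `stats` (named list of
#'   `oxy_kw` objects), `group_summary` tibble, `excluded` character
#'   vector.
#' @export
run_analyze <- function(config, dir, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  root <- file.path(dir, "cohort")
  if (!dir.exists(root)) {
    abort(paste0("no cohort/ tree under ", dir), class = "oxymetr_io_error")
  }
  groups <- list.dirs(root, recursive = FALSE)
  if (length(groups) == 0) {
    abort("dataset contains no groups", class = "oxymetr_io_error")
  }
  table <- builtin_extinction_table()
  projectors <- chromophore_projectors(table, config$fit_config)
  rows <- list(); excluded <- character(0)
  for (gdir in groups) {
    for (adir in list.dirs(gdir, recursive = FALSE)) {
      id <- basename(adir)
      if (!file.exists(file.path(adir, "spectra.csv")) ||
          !file.exists(file.path(adir, "asl", "sidecar.json"))) {
        excluded <- c(excluded, id)
        next
      }
      est <- analyze_one_animal(adir, config, projectors)
      rows[[id]] <- dplyr::mutate(est, animal_id = id,
                                  group = basename(gdir), .before = 1)
    }
  }
  if (length(rows) == 0) {
    abort("no analyzable animals found", class = "oxymetr_io_error")
  }
  cohort <- compute_oximetry(dplyr::bind_rows(rows), config$oximetry)

  ref <- dplyr::filter(cohort, group == "naive")
  if (nrow(ref) >= 2) {
    hx <- classify_hypoxia(cohort$StO2_pct, mean(ref$StO2_pct),
                           sd(ref$StO2_pct))
    cohort$hypoxic_flag <- hx$flags
  }

  cohort$oxidized_fraction <- cohort$oxCCO_uM / cohort$totCCO_uM
  metrics <- intersect(c("CBF", "StO2_pct", "OEF", "CMRO2_mlO2_100g_min",
                         "totCCO_uM", "oxidized_fraction"), names(cohort))
  # group tests need >= 2 groups with >= 2 animals each; smaller runs
  # still get per-animal estimates and summaries
  stats <- NULL
  if (dplyr::n_distinct(cohort$group) >= 2 &&
      all(table(cohort$group) >= 2)) {
    stats <- lapply(setNames(metrics, metrics), function(m)
      kruskal_wallis_pairwise(cohort, m, "group"))
  }
  group_summary <- dplyr::bind_rows(lapply(metrics, function(m)
    dplyr::summarise(dplyr::group_by(cohort, group),
                     metric = m, mean = mean(.data[[m]]),
                     sd = sd(.data[[m]]), n = dplyr::n(),
                     cv_pct = 100 * sd(.data[[m]]) / mean(.data[[m]]),
                     .groups = "drop")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cohort, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(
      list(group_summary = group_summary,
           omnibus = lapply(stats, function(s) s$omnibus),
           pairwise = lapply(stats, function(s) s$pairwise),
           excluded = excluded),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, stats = stats, group_summary = group_summary,
       excluded = excluded)
}

#' Simulate and recover one cohort in memory
#'
#' The recovery protocol used by the simulation study: draws a cohort
#' from a preset, forward-models each animal's NIRS series and ASL
#' stack, pushes both through the full quantification (spectral
#' inversion, anoxia tHb, StO2; T1 map, perfusion-weighted map, CBF,
#' ROI statistics) and the oximetry chain. Only recovered quantities are
#' returned; the ground truth never leaks into the estimates.
#'
#' @param preset A [cohort_preset()].
#' @param seed Cohort seed.
#' @param config A [run_config()] (noise levels, protocol, constants).
#' @param projectors Optional precomputed [chromophore_projectors()].
#' @param do_nirs,do_asl Toggle the two arms (both on by default).
#' @return Per-animal tibble of recovered metrics (`StO2_pct`,
#'   `totCCO_uM`, `oxidized_fraction`, `tHb_uM`, `CBF`, `SvO2_pct`,
#'   `OEF`, `CMRO2_mlO2_100g_min`, ...).
#' @export
recover_cohort <- function(preset, seed, config = run_config(),
                           projectors = NULL, do_nirs = TRUE,
                           do_asl = TRUE) {
  table <- builtin_extinction_table()
  pj <- projectors %||% chromophore_projectors(table, config$fit_config)
  sub_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max,
                                           3 * preset$n))
  rows <- vector("list", preset$n)
  for (j in seq_len(preset$n)) {
    an <- sample_animal(preset, sub_seeds[3 * j - 2],
                        animal_id = sprintf("%s_%02d", preset$name, j))
    out <- tibble::tibble(animal_id = an$animal_id, group = an$group)
    if (do_nirs) {
      frames <- simulate_nirs_timeseries(an, config$protocol, table,
                                         config$noise_sd_od,
                                         seed = sub_seeds[3 * j - 1],
                                         frame_stride = config$frame_stride)
      out <- dplyr::bind_cols(out,
                              analyze_nirs(frames, table, config$protocol,
                                           config$fit_config,
                                           projectors = pj))
    }
    if (do_asl) {
      stack <- simulate_asl_stack(an, config$geometry, config$asl,
                                  noise_sd = config$asl_noise_sd,
                                  seed = sub_seeds[3 * j])
      asl <- analyze_asl(stack, config$asl, fit_mask = stack$mask)
      out$CBF <- asl$roi$mean
      out$CBF_sd <- asl$roi$sd
    }
    rows[[j]] <- out
  }
  cohort <- dplyr::bind_rows(rows)
  if (do_nirs) {
    cohort$oxidized_fraction <- cohort$oxCCO_uM / cohort$totCCO_uM
    if (do_asl) cohort <- compute_oximetry(cohort, config$oximetry)
  }
  cohort
}

#' Repeated-cohort simulation study
#'
#' Recovers `n_cohorts` independently seeded synthetic cohorts for the
#' given presets through the complete raw-data pipeline and returns the
#' per-cohort means, their grand means, and the pooled per-animal
#' estimates. This is the package's acceptance protocol: the grand
#' means of the recovered group metrics should reproduce the preset
#' (published) group statistics.
#'
#' @param preset A [cohort_preset()].
#' @param n_cohorts Number of seeded cohorts (default 200).
#' @param seed Master seed; cohort seeds are drawn from it.
#' @param config A [run_config()].
#' @param ... Passed to [recover_cohort()] (`do_nirs`, `do_asl`).
#' @return List: `cohort_means` tibble (one row per cohort), `grand`
#'   one-row tibble of grand means, `pooled` per-animal tibble.
#' @export
simulation_study <- function(preset, n_cohorts = 200, seed = 1,
                             config = run_config(), ...) {
  table <- builtin_extinction_table()
  pj <- chromophore_projectors(table, config$fit_config)
  cohort_seeds <- withr::with_seed(seed,
                                   sample.int(.Machine$integer.max,
                                              n_cohorts))
  pooled <- vector("list", n_cohorts)
  for (i in seq_len(n_cohorts)) {
    rec <- recover_cohort(preset, cohort_seeds[i], config,
                          projectors = pj, ...)
    rec$cohort <- i
    pooled[[i]] <- rec
  }
  pooled <- dplyr::bind_rows(pooled)
  num <- names(pooled)[vapply(pooled, is.numeric, logical(1))]
  num <- setdiff(num, "cohort")
  cohort_means <- dplyr::summarise(dplyr::group_by(pooled, cohort),
                                   dplyr::across(dplyr::all_of(num), mean),
                                   .groups = "drop")
  grand <- dplyr::summarise(cohort_means,
                            dplyr::across(dplyr::all_of(num), mean))
  list(cohort_means = cohort_means, grand = grand, pooled = pooled)
}

#' Recompute the headline study metrics from scratch
#'
#' Runs the complete synthetic-recovery protocol -- repeated seeded
#' cohorts through the full NIRS and ASL pipelines, the preset-based
#' hypoxia Monte Carlo and the disease-course simulation -- and returns
#' the recovered group-level quantities with the problem size behind
#' each. See the methods vignette for the protocol sizes.
#'
#' @param seed Master seed for every source of randomness.
#' @param n_cohorts Seeded cohorts per group (default 200).
#' @param n_mc Monte-Carlo draws for the hypoxic-fraction estimate
#'   (default 1e5).
#' @param frame_stride NIRS frame thinning (default 10; estimates are
#'   unbiased under thinning).
#' @param config Optional [run_config()] override.
#' @return Tibble: `metric`, `value`, `n`.
#' @export
compute_study_metrics <- function(seed = 1, n_cohorts = 200, n_mc = 1e5,
                                  frame_stride = 10, config = NULL) {
  presets <- builtin_presets()
  config <- config %||% run_config(frame_stride = frame_stride, seed = seed)
  seeds <- withr::with_seed(seed, sample.int(2^30, 6))

  naive <- simulation_study(presets$naive, n_cohorts, seed = seeds[1],
                            config = config)
  eae <- simulation_study(presets$eae, n_cohorts, seed = seeds[2],
                          config = config)
  n_naive <- nrow(naive$pooled); n_eae <- nrow(eae$pooled)

  # preset-based Monte Carlo of the 2-SD hypoxia criterion
  ref <- presets$naive$sto2; dist <- presets$eae$sto2
  draws <- withr::with_seed(seeds[3],
                            rnorm_trunc(n_mc, dist[1], dist[2], 0, 100))
  hypox <- classify_hypoxia(draws, ref[1], ref[2])

  # disease-course simulation: mean score over the peak-disease days
  course_seeds <- withr::with_seed(seeds[4],
                                   sample.int(.Machine$integer.max,
                                              n_cohorts * presets$eae$n))
  peak <- purrr::map_dbl(course_seeds, function(s) {
    sc <- simulate_disease_course(presets$eae, s)
    mean(sc$total[sc$day >= 15 & sc$day <= 17])
  })

  tibble::tibble(
    metric = c("cbf_naive", "cbf_eae", "sto2_naive", "sto2_eae",
               "oef_naive", "oef_eae", "totcco_eae", "oxfrac_pct_eae",
               "hypoxic_pct_eae", "cmro2_naive", "cv_sto2_eae",
               "disease_score_peak_eae"),
    value = c(naive$grand$CBF, eae$grand$CBF,
              naive$grand$StO2_pct, eae$grand$StO2_pct,
              naive$grand$OEF, eae$grand$OEF,
              eae$grand$totCCO_uM, 100 * eae$grand$oxidized_fraction,
              100 * hypox$fraction,
              naive$grand$CMRO2_mlO2_100g_min,
              coefficient_of_variation(eae$pooled$StO2_pct),
              mean(peak)),
    n = c(n_naive, n_eae, n_naive, n_eae, n_naive, n_eae, n_eae, n_eae,
          n_mc, n_naive, n_eae, length(peak))
  )
}

#' Acceptance self-check
#'
#' Recomputes the headline metrics with [compute_study_metrics()] and
#' compares each against the corresponding preset (published) group
#' value.
#'
#' @param seed Master seed.
#' @param n_cohorts Seeded cohorts per group.
#' @param ... Passed to [compute_study_metrics()].
#' @return Tibble: `metric`, `observed`, `expected`, `rel_diff_pct`.
#' @export
run_acceptance <- function(seed = 1, n_cohorts = 200, ...) {
  presets <- builtin_presets()
  obs <- compute_study_metrics(seed = seed, n_cohorts = n_cohorts, ...)
  oef_of <- function(sto2, sao2 = 98) {
    sv <- (sto2 - 0.25 * sao2) / 0.75
    (sao2 - sv) / sao2
  }
  expected <- c(
    cbf_naive = presets$naive$cbf[1], cbf_eae = presets$eae$cbf[1],
    sto2_naive = presets$naive$sto2[1], sto2_eae = presets$eae$sto2[1],
    oef_naive = oef_of(presets$naive$sto2[1]),
    oef_eae = oef_of(presets$eae$sto2[1]),
    totcco_eae = presets$eae$totcco[1],
    oxfrac_pct_eae = 100 * presets$eae$oxidized_fraction[1],
    hypoxic_pct_eae = 100 * pnorm((presets$naive$sto2[1] -
                                     2 * presets$naive$sto2[2] -
                                     presets$eae$sto2[1]) /
                                    presets$eae$sto2[2]),
    cmro2_naive = presets$naive$cbf[1] * oef_of(presets$naive$sto2[1]) *
      0.98 * 0.107,
    cv_sto2_eae = 100 * presets$eae$sto2[2] / presets$eae$sto2[1],
    disease_score_peak_eae = presets$eae$disease$plateau_mean
  )
  dplyr::mutate(obs, expected = unname(expected[metric]),
                rel_diff_pct = 100 * (value - expected) / expected)
}
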