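#' Simulate a broadband NIRS attenuation time series
#'
#' Forward-models one animal's measurement: a constant-physiology
#' baseline (dHb fixed at `tHb (1 - StO2/100)`, CCO states constant),
#' the terminal anoxia pulse during which StO2 decays exponentially to
#' ~0 over ~20 s so dHb rises to tHb, spectra from the Beer-Lambert
#' forward model with the animal's pathlength and scattering baseline,
#' and i.i.d. Gaussian OD noise per frame and wavelength. Deterministic
#' per seed.
#'
#' @param animal One-row tibble from [sample_animal()].
#' @param protocol A [nirs_protocol()].
#' @param table Extinction tibble.
#' @param noise_sd_od Frame noise SD in OD (default 1e-3; >= 0).
#' @param seed Integer seed.
#' @param frame_stride Integer thinning factor on the frame grid
#'   (default 1 = full rate). Averaged estimates are unbiased under
#'   thinning; it only trades precision for runtime.
#' @param anoxia_tau_s Time constant of the desaturation ramp (s).
#' @return Wide tibble: `time_s` plus one `od_<nm>` column per
#'   wavelength.
#' @export
simulate_nirs_timeseries <- function(animal, protocol = nirs_protocol(),
                                     table = builtin_extinction_table(),
                                     noise_sd_od = 1e-3, seed = 1,
                                     frame_stride = 1, anoxia_tau_s = 4) {
  if (noise_sd_od < 0) {
    abort("noise_sd_od must be non-negative", class = "oxymetr_preset_error")
  }
  dt <- frame_stride / protocol$sampling_rate
  t <- seq(0, protocol$total_duration - 1 / protocol$sampling_rate, by = dt)

  sto2 <- rep(animal$StO2_pct, length(t))
  aw <- protocol$anoxia_window
  if (!is.null(aw)) {
    in_anx <- t >= aw[1] & t < aw[2]
    sto2[in_anx] <- animal$StO2_pct * exp(-(t[in_anx] - aw[1]) / anoxia_tau_s)
    sto2[t >= aw[2]] <- animal$StO2_pct * exp(-(aw[2] - aw[1]) / anoxia_tau_s)
  }
  dhb <- animal$tHb_uM * (1 - sto2 / 100)
  hbo2 <- animal$tHb_uM - dhb

  lambda <- table$wavelength_nm
  E <- as.matrix(table[c("HbO2", "dHb")])
  static <- table$oxCCO * animal$oxCCO_uM + table$reCCO * animal$reCCO_uM +
    0.80 * water_molarity_M * table$water
  od <- animal$pathlength_cm *
    (E %*% rbind(hbo2, dhb) + static) +
    animal$baseline_a + animal$baseline_b * lambda
  if (noise_sd_od > 0) {
    od <- od + withr::with_seed(seed, matrix(rnorm(length(od), 0,
                                                   noise_sd_od),
                                             nrow(od), ncol(od)))
  }
  out <- tibble::as_tibble(t(od), .name_repair = "minimal")
  names(out) <- paste0("od_", lambda)
  dplyr::bind_cols(tibble::tibble(time_s = t), out)
}

#' Default ASL slice geometry
#'
#' Single axial slice: 128 x 128 matrix, 25.6 x 25.6 mm field of view,
#' 1.5 mm slice thickness.
#'
#' @param matrix_size Image matrix size (square).
#' @param fov_mm Field of view (mm).
#' @param slice_mm Slice thickness (mm).
#' @return Geometry list.
#' @export
asl_geometry <- function(matrix_size = 128, fov_mm = 25.6, slice_mm = 1.5) {
  list(matrix_size = matrix_size, fov_mm = fov_mm, slice_mm = slice_mm)
}

# cortical band ROI: a dorsal strip covering motor/somatosensory cortex
cortex_band_mask <- function(n) {
  mask <- matrix(FALSE, n, n)
  rows <- max(1, round(0.27 * n)):max(2, round(0.43 * n))
  cols <- max(1, round(0.20 * n)):max(2, round(0.81 * n))
  mask[rows, cols] <- TRUE
  mask
}

# smooth mean-zero spatial field (coarse Gaussian grid, bilinear upsample),
# rescaled to unit SD over the mask
smooth_field <- function(n, mask, coarse = 8) {
  g <- matrix(rnorm(coarse^2), coarse, coarse)
  xi <- seq(1, coarse, length.out = n)
  i0 <- pmin(floor(xi), coarse - 1); fx <- xi - i0
  up_rows <- g[i0, , drop = FALSE] * (1 - fx) + g[i0 + 1, , drop = FALSE] * fx
  up <- up_rows[, i0, drop = FALSE] * rep(1 - fx, each = n) +
    up_rows[, i0 + 1, drop = FALSE] * rep(fx, each = n)
  v <- up[mask]
  up <- (up - mean(v)) / sd(v)
  up
}

#' Simulate an ASL image stack
#'
#' Builds the single-slice digital phantom for one animal: a cortical
#' band ROI at the animal's true CBF (plus a mean-zero smooth
#' heterogeneity field, so the ROI mean equals the true CBF exactly),
#' background at 60% of cortical CBF, control/tag pairs from the same
#' single-compartment CASL forward model the quantification inverts, and
#' the five-TR saturation-recovery series. Gaussian image noise is
#' scaled by `1/sqrt(n_averages)` for the stated 16 signal averages.
#' Deterministic per seed.
#'
#' @param animal One-row tibble from [sample_animal()].
#' @param geometry An [asl_geometry()].
#' @param params An [asl_params()] (the forward model uses the same
#'   constants the inversion assumes).
#' @param noise_sd Single-average image noise SD in signal units
#'   (default 20 on `m0 = 1000`).
#' @param seed Integer seed.
#' @param t1_cortex_s,t1_background_s,m0 Tissue constants.
#' @param het_cv Coefficient of variation of the in-ROI heterogeneity
#'   field (fraction of true CBF; default 0.05).
#' @param n_averages Signal averages (default 16).
#' @param tr_asl_ms Repetition time of the perfusion acquisition (ms).
#' @param tr_ms Variable-TR grid (ms).
#' @return ASL stack list: `controls`, `tags`, `tr_series`, `tr_ms`,
#'   `geometry`, `mask`.
#' @export
simulate_asl_stack <- function(animal, geometry = asl_geometry(),
                               params = asl_params(), noise_sd = 20,
                               seed = 1, t1_cortex_s = 1.9,
                               t1_background_s = 1.6, m0 = 1000,
                               het_cv = 0.05, n_averages = 16,
                               tr_asl_ms = 3000,
                               tr_ms = c(100, 500, 1000, 3000, 7500)) {
  n <- geometry$matrix_size
  mask <- cortex_band_mask(n)
  if (!any(mask)) abort("ROI mask empty under this geometry",
                        class = "oxymetr_preset_error")
  withr::with_seed(seed, {
    cbf_map <- matrix(0.6 * animal$CBF, n, n)
    cbf_map[mask] <- animal$CBF
    if (het_cv > 0) {
      cbf_map[mask] <- cbf_map[mask] +
        smooth_field(n, mask)[mask] * het_cv * animal$CBF
    }
    t1_map <- matrix(t1_background_s, n, n)
    t1_map[mask] <- t1_cortex_s

    ctrl <- m0 * (1 - exp(-tr_asl_ms / 1000 / t1_map))
    dM <- ctrl * cbf_map * 2 * params$alpha_label * t1_map /
      (params$unit_scale * params$lambda_partition)
    tag <- ctrl - dM
    sigma <- noise_sd / sqrt(n_averages)
    noisy <- function(img) img + matrix(rnorm(n * n, 0, sigma), n, n)
    list(
      controls = list(noisy(ctrl), noisy(ctrl)),
      tags = list(noisy(tag), noisy(tag)),
      tr_series = lapply(tr_ms, function(tr)
        noisy(m0 * (1 - exp(-tr / 1000 / t1_map)))),
      tr_ms = tr_ms, geometry = geometry, mask = mask
    )
  })
}

decompose_score <- function(total) {
  tail <- min(2L, total)
  rem <- total - tail
  limbs <- integer(4)
  for (i in 1:4) {
    limbs[i] <- min(3L, rem)
    rem <- rem - limbs[i]
  }
  c(tail = tail, limb1 = limbs[1], limb2 = limbs[2], limb3 = limbs[3],
    limb4 = limbs[4])
}

#' Simulate one animal's daily disease-score course
#'
#' EAE animals are symptom-free until a per-animal onset day, ramp
#' linearly to a per-animal plateau level (drawn from the preset plateau
#' distribution, truncated to `[0, 14]`) reached on the plateau day, and
#' hold it through the scoring period. Scores are decomposed into the
#' 15-point scale components (tail 0-2, four limbs 0-3 each) that re-sum
#' to the daily total. Symptom-free groups return all-zero courses.
#'
#' @param preset A [cohort_preset()].
#' @param seed Integer seed.
#' @return Tibble: `day`, `tail`, `limb1`..`limb4`, `total` (integer,
#'   <= 14).
#' @export
simulate_disease_course <- function(preset, seed) {
  dz <- preset$disease
  n_days <- if (is.null(dz)) 17 else dz$n_days
  days <- seq_len(n_days)
  if (is.null(dz)) {
    total <- integer(n_days)
  } else {
    total <- withr::with_seed(seed, {
      onset <- sample(dz$onset_days, 1)
      plateau <- rnorm_trunc(1, dz$plateau_mean, dz$plateau_sd, 0, 14)
      v <- numeric(n_days)
      ramp <- days > onset & days < dz$plateau_day
      v[ramp] <- plateau * (days[ramp] - onset) / (dz$plateau_day - onset)
      v[days >= dz$plateau_day] <- plateau
      as.integer(pmin(14, round(v)))
    })
  }
  comp <- t(vapply(total, decompose_score, integer(5)))
  tibble::tibble(day = days, tail = comp[, "tail"],
                 limb1 = comp[, "limb1"], limb2 = comp[, "limb2"],
                 limb3 = comp[, "limb3"], limb4 = comp[, "limb4"],
                 total = total)
}

#' Generate a complete on-disk synthetic cohort
#'
#' Writes the full per-animal raw-data tree --
#' `cohort/<group>/<animal_id>/spectra.csv`, ASL NIfTI stack +
#' `sidecar.json`, `scores.csv` -- plus the root `manifest.csv` of all
#' ground-truth values (for recovery testing only; the analysis pipeline
#' never reads it) and `presets.json`. Fully reproducible from
#' `(presets, seed)`.
#'
#' @param dir Target directory.
#' @param presets Named list of [cohort_preset()]s.
#' @param seed Master seed; per-animal sub-seeds are drawn from it.
#' @param protocol A [nirs_protocol()].
#' @param table Extinction tibble.
#' @param noise_sd_od NIRS frame noise (OD).
#' @param asl_noise_sd ASL single-average image noise (signal units).
#' @param frame_stride NIRS frame thinning factor (see
#'   [simulate_nirs_timeseries()]).
#' @param geometry An [asl_geometry()].
#' @return The ground-truth manifest tibble, invisibly.
#' @export
generate_cohort <- function(dir, presets = builtin_presets(), seed = 1,
                            protocol = nirs_protocol(),
                            table = builtin_extinction_table(),
                            noise_sd_od = 1e-3, asl_noise_sd = 20,
                            frame_stride = 1, geometry = asl_geometry()) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(paste0("cannot create dataset directory: ", dir),
          class = "oxymetr_io_error")
  }
  sim <- simulate_cohort_data(presets, seed, protocol, table, noise_sd_od,
                              asl_noise_sd, frame_stride, geometry)
  scores_all <- list()
  for (i in seq_len(nrow(sim$manifest))) {
    an <- sim$manifest[i, ]
    adir <- file.path(dir, "cohort", an$group, an$animal_id)
    dir.create(adir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(sim$data[[i]]$nirs, file.path(adir, "spectra.csv"))
    write_asl_stack(sim$data[[i]]$asl, file.path(adir, "asl"))
    readr::write_csv(sim$data[[i]]$scores, file.path(adir, "scores.csv"))
    scores_all[[i]] <- dplyr::mutate(sim$data[[i]]$scores,
                                     animal_id = an$animal_id,
                                     group = an$group, .before = 1)
  }
  readr::write_csv(dplyr::bind_rows(scores_all),
                   file.path(dir, "scores.csv"))
  readr::write_csv(sim$manifest, file.path(dir, "manifest.csv"))
  jsonlite::write_json(lapply(presets, unclass),
                       file.path(dir, "presets.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim$manifest)
}

# In-memory cohort simulation shared by generate_cohort and the
# recovery/acceptance protocols. Returns manifest + per-animal raw data.
simulate_cohort_data <- function(presets, seed,
                                 protocol = nirs_protocol(),
                                 table = builtin_extinction_table(),
                                 noise_sd_od = 1e-3, asl_noise_sd = 20,
                                 frame_stride = 1,
                                 geometry = asl_geometry()) {
  if (inherits(presets, "cohort_preset")) {
    presets <- setNames(list(presets), presets$name)
  }
  n_total <- sum(vapply(presets, function(p) p$n, numeric(1)))
  sub_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max, 3 * n_total))
  manifest <- list(); data <- list(); k <- 0
  for (p in presets) {
    for (j in seq_len(p$n)) {
      k <- k + 1
      id <- sprintf("%s_%02d", p$name, j)
      an <- sample_animal(p, sub_seeds[3 * k - 2], animal_id = id)
      data[[k]] <- list(
        nirs = simulate_nirs_timeseries(an, protocol, table, noise_sd_od,
                                        seed = sub_seeds[3 * k - 1],
                                        frame_stride = frame_stride),
        asl = simulate_asl_stack(an, geometry, noise_sd = asl_noise_sd,
                                 seed = sub_seeds[3 * k]),
        scores = simulate_disease_course(p, sub_seeds[3 * k - 2])
      )
      manifest[[k]] <- an
    }
  }
  list(manifest = dplyr::bind_rows(manifest), data = data)
}
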