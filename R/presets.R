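#' Cohort preset
#'
#' Group-level generative parameters of the synthetic study: sample size
#' and truncated-normal distributions for the per-animal physiology
#' (CBF, StO2, totCCO, oxidized CCO fraction, tHb), the fixed arterial
#' saturation, the CBF-StO2 correlation and the disease-course shape.
#'
#' @param name Group label.
#' @param n Animals in the group.
#' @param cbf,sto2,totcco,oxidized_fraction,thb,pathlength Length-2
#'   `c(mean, sd)` vectors. Units: ml 100g^-1 min^-1, %, uM,
#'   dimensionless fraction, uM, cm.
#' @param sao2 Fixed arterial saturation (%).
#' @param rho_cbf_sto2 Correlation between CBF and StO2 draws.
#' @param disease List: `plateau_mean`, `plateau_sd` (score points),
#'   `onset_days` (integer candidates for symptom onset),
#'   `plateau_day` (day the ramp reaches plateau), `n_days`. `NULL` for
#'   symptom-free groups.
#' @return Object of class `cohort_preset`.
#' @export
cohort_preset <- function(name, n, cbf, sto2, totcco, oxidized_fraction,
                          thb = c(100, 10), sao2 = 98, rho_cbf_sto2 = 0,
                          pathlength = c(1.8, 0.15), disease = NULL) {
  for (p in list(cbf, sto2, totcco, oxidized_fraction, thb, pathlength)) {
    if (length(p) != 2 || p[2] < 0) {
      abort("distribution parameters must be c(mean, sd) with sd >= 0",
            class = "oxymetr_preset_error")
    }
  }
  if (n < 1) abort("n must be >= 1", class = "oxymetr_preset_error")
  if (abs(rho_cbf_sto2) >= 1) {
    abort("rho_cbf_sto2 must lie in (-1, 1)", class = "oxymetr_preset_error")
  }
  structure(list(name = name, n = n, cbf = cbf, sto2 = sto2,
                 totcco = totcco, oxidized_fraction = oxidized_fraction,
                 thb = thb, sao2 = sao2, rho_cbf_sto2 = rho_cbf_sto2,
                 pathlength = pathlength, disease = disease),
            class = "cohort_preset")
}

#' Built-in group presets
#'
#' The three study groups with their reported cortical group statistics:
#' naive (n = 15), adjuvant-only CFA/PTX controls (n = 14) and EAE mice
#' at peak disease (n = 13). CBF, StO2, totCCO and oxidized-fraction
#' means/SDs are the published group values; arterial saturation is fixed
#' at 98% and tHb at 100 +/- 10 uM (typical rodent cortex scale; the
#' study does not print either). CBF and StO2 are drawn jointly with a
#' positive correlation in the inflamed groups (low flow co-occurring
#' with low oxygenation) and independently in naive animals. The EAE
#' disease course ramps from a day 10-12 onset to a plateau of
#' 7.9 +/- 0.7 score points over days 15-17.
#'
#' @return Named list of [cohort_preset()] objects: `naive`, `cfa_ptx`,
#'   `eae`.
#' @export
builtin_presets <- function() {
  list(
    naive = cohort_preset("naive", 15, cbf = c(252.6, 24.6),
                          sto2 = c(82.7, 4.1), totcco = c(4.6, 0.3),
                          oxidized_fraction = c(0.74, 0.01),
                          rho_cbf_sto2 = 0),
    cfa_ptx = cohort_preset("cfa_ptx", 14, cbf = c(207.7, 35.5),
                            sto2 = c(74.5, 7.8), totcco = c(4.4, 0.6),
                            oxidized_fraction = c(0.84, 0.01),
                            rho_cbf_sto2 = 0.5),
    eae = cohort_preset("eae", 13, cbf = c(166.4, 63.3),
                        sto2 = c(63.8, 14.8), totcco = c(3.9, 0.5),
                        oxidized_fraction = c(0.85, 0.01),
                        rho_cbf_sto2 = 0.5,
                        disease = list(plateau_mean = 7.9, plateau_sd = 0.7,
                                       onset_days = 10:12, plateau_day = 15,
                                       n_days = 17))
  )
}

# truncated-normal draw by rejection; cap guards degenerate bounds
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf,
                        max_tries = 10000) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      abort("degenerate truncated normal: mean outside bounds",
            class = "oxymetr_preset_error")
    }
    return(rep(mean, n))
  }
  out <- numeric(0)
  tries <- 0
  while (length(out) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      abort("truncation rejection cap exceeded",
            class = "oxymetr_preset_error")
    }
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

#' Draw one animal's ground-truth physiology
#'
#' Deterministic per `(preset, seed)`: (CBF, StO2) from a truncated
#' bivariate normal with the preset correlation, independent truncated
#' normals for tHb, totCCO, oxidized fraction and pathlength, and a
#' random linear scattering baseline. Derived fields are consistent by
#' construction: `dHb = tHb (1 - StO2/100)`, `oxCCO = totCCO * oxidized
#' fraction`, `reCCO = totCCO - oxCCO`.
#'
#' @param preset A [cohort_preset()].
#' @param seed Integer seed.
#' @param animal_id Identifier string (default derived from group/seed).
#' @return One-row tibble of ground-truth physiology.
#' @export
sample_animal <- function(preset, seed,
                          animal_id = paste0(preset$name, "_", seed)) {
  stopifnot(inherits(preset, "cohort_preset"))
  withr::with_seed(seed, {
    rho <- preset$rho_cbf_sto2
    ok <- FALSE; tries <- 0
    while (!ok) {
      tries <- tries + 1
      if (tries > 10000) {
        abort("truncation rejection cap exceeded",
              class = "oxymetr_preset_error")
      }
      z1 <- rnorm(1); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1)
      cbf <- preset$cbf[1] + preset$cbf[2] * z1
      sto2 <- preset$sto2[1] + preset$sto2[2] * z2
      ok <- cbf > 0 && sto2 > 0 && sto2 < 100
    }
    thb <- rnorm_trunc(1, preset$thb[1], preset$thb[2], lower = 30)
    totcco <- rnorm_trunc(1, preset$totcco[1], preset$totcco[2], lower = 0)
    oxfrac <- rnorm_trunc(1, preset$oxidized_fraction[1],
                          preset$oxidized_fraction[2], 0, 1)
    pl <- rnorm_trunc(1, preset$pathlength[1], preset$pathlength[2],
                      lower = 0.5)
    a <- runif(1, 0.1, 0.5); b <- runif(1, -5e-4, 5e-4)
    dhb <- thb * (1 - sto2 / 100)
    tibble::tibble(
      animal_id = animal_id, group = preset$name, seed = as.integer(seed),
      CBF = cbf, StO2_pct = sto2, tHb_uM = thb, totCCO_uM = totcco,
      oxidized_fraction = oxfrac, oxCCO_uM = totcco * oxfrac,
      reCCO_uM = totcco * (1 - oxfrac), dHb_uM = dhb,
      HbO2_uM = thb - dhb, pathlength_cm = pl,
      baseline_a = a, baseline_b = b, SaO2_pct = preset$sao2
    )
  })
}
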