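#' Oximetry parameters
#'
#' Constants of the modified Fick oximetry chain. `arterial_fraction` is
#' the arterial share of the tissue microvascular hemoglobin pool (the
#' 0.25/0.75 arterial/venous partition). `k_O2` is the arterial oxygen
#' carrying capacity at full saturation in ml O2 per ml blood; the
#' default 0.107 is a calibration constant chosen so that the Fick chain
#' maps typical healthy-mouse cortical perfusion and extraction onto the
#' expected CMRO2 scale -- it is exposed here precisely because it is a
#' calibration, not a measured physiological constant.
#'
#' @param arterial_fraction Arterial fraction of tissue Hb (0-1,
#'   default 0.25).
#' @param k_O2 Arterial O2 carrying capacity, ml O2 / ml blood
#'   (default 0.107).
#' @param SaO2_default Default arterial saturation (%) when no
#'   pulse-oximeter trace is available (default 98).
#' @return Object of class `oximetry_params`.
#' @export
oximetry_params <- function(arterial_fraction = 0.25, k_O2 = 0.107,
                            SaO2_default = 98) {
  if (arterial_fraction <= 0 || arterial_fraction >= 1) {
    abort("arterial_fraction must lie strictly between 0 and 1",
          class = "oxymetr_params_error")
  }
  if (k_O2 <= 0) abort("k_O2 must be positive", class = "oxymetr_params_error")
  structure(list(arterial_fraction = arterial_fraction, k_O2 = k_O2,
                 SaO2_default = SaO2_default),
            class = "oximetry_params")
}

#' Venous oxygen saturation from tissue and arterial saturation
#'
#' Tissue saturation is modeled as a weighted mixture of arterial and
#' venous blood, `StO2 = f_a * SaO2 + (1 - f_a) * SvO2`, so
#' `SvO2 = (StO2 - f_a * SaO2) / (1 - f_a)` with `f_a` the arterial
#' fraction (default 0.25). A negative result is physiologically
#' inconsistent and is flagged, never silently clipped.
#'
#' @param StO2 Tissue saturation (%), vectorised.
#' @param SaO2 Arterial saturation (%), in (0, 100].
#' @param params An [oximetry_params()].
#' @return Tibble with `SvO2_pct` and logical `inconsistent`.
#' @export
compute_SvO2 <- function(StO2, SaO2, params = oximetry_params()) {
  if (any(SaO2 <= 0 | SaO2 > 100)) {
    abort("SaO2 must lie in (0, 100]", class = "oxymetr_params_error")
  }
  fa <- params$arterial_fraction
  sv <- (StO2 - fa * SaO2) / (1 - fa)
  tibble::tibble(SvO2_pct = sv, inconsistent = sv < 0)
}

#' Oxygen extraction fraction
#'
#' `OEF = (SaO2 - SvO2) / SaO2`, the arteriovenous saturation difference
#' relative to arterial saturation.
#'
#' @param SaO2 Arterial saturation (%), > 0.
#' @param SvO2 Venous saturation (%).
#' @return Numeric OEF (fraction), vectorised.
#' @export
compute_OEF <- function(SaO2, SvO2) {
  if (any(SaO2 <= 0)) {
    abort("SaO2 must be positive", class = "oxymetr_params_error")
  }
  (SaO2 - SvO2) / SaO2
}

#' Cerebral metabolic rate of oxygen via the modified Fick principle
#'
#' `CMRO2 = CBF * OEF * (SaO2/100) * k_O2`: perfusion times the extracted
#' fraction of the delivered arterial oxygen content.
#'
#' @param CBF Cerebral blood flow, ml 100g^-1 min^-1 (>= 0).
#' @param OEF Oxygen extraction fraction.
#' @param SaO2 Arterial saturation (%).
#' @param params An [oximetry_params()] supplying `k_O2`.
#' @return CMRO2 in ml O2 100g^-1 min^-1, vectorised.
#' @export
compute_CMRO2 <- function(CBF, OEF, SaO2, params = oximetry_params()) {
  if (any(CBF < 0)) abort("CBF must be non-negative",
                          class = "oxymetr_params_error")
  CBF * OEF * (SaO2 / 100) * params$k_O2
}

#' Two-standard-deviation hypoxia classifier
#'
#' Flags tissue-saturation values at least two reference standard
#' deviations below the healthy-control reference mean
#' (`value <= mean - 2 * sd`, boundary inclusive).
#'
#' @param values Numeric StO2 values (%).
#' @param reference_mean,reference_sd Healthy-control reference mean and
#'   SD (%); `reference_sd` must be positive.
#' @return List with `flags` (logical), `fraction` flagged, and the
#'   `threshold` used.
#' @export
classify_hypoxia <- function(values, reference_mean, reference_sd) {
  if (length(values) == 0) {
    abort("no values to classify", class = "oxymetr_params_error")
  }
  if (reference_sd <= 0) {
    abort("reference_sd must be positive", class = "oxymetr_params_error")
  }
  thr <- reference_mean - 2 * reference_sd
  flags <- values <= thr
  list(flags = flags, fraction = mean(flags), threshold = thr)
}

#' Per-animal oximetry chain
#'
#' Applies the partition, extraction and Fick operations to recovered
#' per-animal StO2 and CBF, extending the cohort table.
#'
#' @param data Tibble with columns `StO2_pct` and `CBF` (and optionally
#'   `SaO2_pct`; otherwise the parameter default is used).
#' @param params An [oximetry_params()].
#' @return `data` with `SaO2_pct`, `SvO2_pct`, `svo2_inconsistent`,
#'   `OEF`, `CMRO2_mlO2_100g_min` columns appended.
#' @export
compute_oximetry <- function(data, params = oximetry_params()) {
  sao2 <- if ("SaO2_pct" %in% names(data)) data$SaO2_pct
          else rep(params$SaO2_default, nrow(data))
  sv <- compute_SvO2(data$StO2_pct, sao2, params)
  oef <- compute_OEF(sao2, sv$SvO2_pct)
  dplyr::mutate(data,
                SaO2_pct = sao2,
                SvO2_pct = sv$SvO2_pct,
                svo2_inconsistent = sv$inconsistent,
                OEF = oef,
                CMRO2_mlO2_100g_min = compute_CMRO2(data$CBF, oef, sao2,
                                                    params))
}
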