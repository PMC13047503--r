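#' Construct a tissue state
#'
#' Ground-truth optical state of a tissue volume: chromophore
#' concentrations, tissue water volume fraction, mean optical pathlength
#' and a linear scattering baseline `S(lambda) = a + b * lambda`. The
#' quantification model assumes scattering and water content are constant
#' over a measurement, which is why the baseline enters as a static linear
#' offset that the second-derivative operator annihilates.
#'
#' @param concentrations Named numeric vector of chromophore
#'   concentrations in uM; names among `HbO2`, `dHb`, `oxCCO`, `reCCO`.
#' @param water_fraction Tissue water volume fraction in `[0, 1]`
#'   (default 0.80, rodent brain).
#' @param pathlength_cm Mean optical pathlength in cm (> 0).
#' @param baseline Length-2 numeric `c(a, b)`: offset (OD) and slope
#'   (OD/nm) of the scattering baseline.
#' @return An object of class `tissue_state`.
#' @export
#' @examples
#' st <- tissue_state(c(dHb = 17.3, HbO2 = 82.7, oxCCO = 3.4, reCCO = 1.2),
#'                    pathlength_cm = 1.8)
tissue_state <- function(concentrations, water_fraction = 0.80,
                         pathlength_cm = 1.8, baseline = c(0, 0)) {
  if (is.null(names(concentrations)) ||
      !all(names(concentrations) %in% setdiff(OXY_CHROMOPHORES, "water"))) {
    abort("concentrations must be named with chromophores among HbO2, dHb, oxCCO, reCCO",
          class = "oxymetr_state_error")
  }
  if (any(concentrations < 0)) {
    abort("concentrations must be non-negative", class = "oxymetr_state_error")
  }
  if (water_fraction < 0 || water_fraction > 1) {
    abort("water_fraction must lie in [0, 1]", class = "oxymetr_state_error")
  }
  if (pathlength_cm <= 0) {
    abort("pathlength_cm must be positive", class = "oxymetr_state_error")
  }
  stopifnot(length(baseline) == 2, all(is.finite(baseline)))
  structure(
    list(concentrations = concentrations, water_fraction = water_fraction,
         pathlength_cm = pathlength_cm, baseline = as.numeric(baseline)),
    class = "tissue_state"
  )
}

#' Forward attenuation model (modified Beer-Lambert)
#'
#' Computes the attenuation spectrum
#' `A(lambda) = L * (sum_i eps_i(lambda) c_i + f_w * M_w * eps_water(lambda)) + a + b * lambda`
#' where `L` is the mean optical pathlength, `c_i` the micromolar
#' chromophore concentrations, `f_w` the water volume fraction and `M_w`
#' the molarity of pure water. Deterministic and linear in the
#' concentrations.
#'
#' @param state A [tissue_state()].
#' @param table Extinction tibble (see [builtin_extinction_table()]).
#' @return Tibble with columns `wavelength_nm`, `attenuation_od`.
#' @export
attenuation_forward <- function(state, table) {
  stopifnot(inherits(state, "tissue_state"))
  conc <- state$concentrations
  absent <- setdiff(names(conc), names(table))
  if (length(absent) > 0) {
    abort(paste0("chromophore(s) absent from extinction table: ",
                 paste(absent, collapse = ", ")),
          class = "oxymetr_schema_error")
  }
  lambda <- table$wavelength_nm
  mu <- rep(0, length(lambda))
  for (ch in names(conc)) mu <- mu + table[[ch]] * conc[[ch]]
  mu <- mu + state$water_fraction * water_molarity_M * table$water
  a <- state$baseline[1]; b <- state$baseline[2]
  tibble::tibble(
    wavelength_nm = lambda,
    attenuation_od = state$pathlength_cm * mu + a + b * lambda
  )
}

# Savitzky-Golay second-derivative of a vector sampled on a regular grid
# with spacing h. Edge policy: the off-center Savitzky-Golay rows are used
# at the boundaries (no padding), so any polynomial up to the fit order --
# in particular a linear scattering baseline -- is differentiated exactly
# over the whole grid, edges included.
sg_second_derivative <- function(y, h, window = 11, order = 3) {
  n <- length(y)
  if (window %% 2 == 0 || window <= order) {
    abort("smoothing window must be odd and greater than the polynomial order",
          class = "oxymetr_format_error")
  }
  if (n < window) {
    abort("spectrum shorter than the smoothing window",
          class = "oxymetr_format_error")
  }
  signal::sgolayfilt(y, p = order, n = window, m = 2, ts = h)
}

# Dense linear operator equivalent to sg_second_derivative, for applying
# the derivative to many spectra at once (columns of a matrix).
sg_d2_operator <- function(n, h, window = 11, order = 3) {
  D <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    D[, j] <- sg_second_derivative(e, h, window, order)
  }
  D
}

#' Smoothed second derivative of a spectrum
#'
#' Savitzky-Golay local-polynomial second derivative with respect to
#' wavelength, on a regular grid. At the boundaries the off-center
#' Savitzky-Golay fits are used (no padding), so the output has the same
#' length as the input and any polynomial up to the fit order -- in
#' particular a linear scattering baseline -- is differentiated exactly
#' over the whole grid. That exact baseline removal is the core
#' assumption that makes concentration fitting insensitive to scattering.
#'
#' @param spectrum Tibble with `wavelength_nm` and one value column
#'   (`attenuation_od` or the first non-wavelength numeric column).
#' @param window Odd window length in samples (default 11).
#' @param order Local polynomial order (default 3; must be < window and
#'   >= 2).
#' @return Tibble with `wavelength_nm` and `d2_od_nm2` (OD/nm^2).
#' @export
second_derivative <- function(spectrum, window = 11, order = 3) {
  lambda <- spectrum$wavelength_nm
  h <- diff(lambda)
  if (length(h) < 1 || any(abs(h - h[1]) > 1e-9 * h[1])) {
    abort("wavelength grid must be regular", class = "oxymetr_format_error")
  }
  vcol <- setdiff(names(spectrum), "wavelength_nm")[1]
  tibble::tibble(
    wavelength_nm = lambda,
    d2_od_nm2 = sg_second_derivative(spectrum[[vcol]], h[1], window, order)
  )
}
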