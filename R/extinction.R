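#' @importFrom rlang abort warn %||%
#' @importFrom stats approx sd qnorm pnorm rnorm runif setNames
NULL

# Chromophores required by the quantification model. Hemoglobin and
# cytochrome-c-oxidase coefficients are specific absorption coefficients in
# OD * uM^-1 * cm^-1; the water column is in OD * M^-1 * cm^-1 and the
# molarity of tissue water is handled explicitly (see `water_molarity_M`).
OXY_CHROMOPHORES <- c("HbO2", "dHb", "oxCCO", "reCCO", "water")

#' Molar concentration of pure water
#'
#' Used to convert the tissue water volume fraction into a molar
#' concentration when combining the water extinction column (tabulated per
#' molar) with the micromolar hemoglobin/CCO columns.
#' @keywords internal
water_molarity_M <- 55.5

#' Default working wavelength grid (nm)
#'
#' 705-960 nm at 1 nm spacing, the broadband acquisition range of the
#' continuous-wave NIRS system.
#' @return Numeric vector of wavelengths in nm.
#' @export
default_wavelengths <- function() seq(705, 960, by = 1)

gauss_band <- function(lambda, center, width) {
  exp(-(lambda - center)^2 / (2 * width^2))
}

#' Built-in specific absorption coefficient table
#'
#' Constructs the bundled extinction-coefficient table on a wavelength grid.
#' The curves are synthetic, literature-shaped surrogates -- the
#' deoxyhemoglobin band near 760 nm, the broad oxidized-CCO band near
#' 830 nm, and the water feature in the 800-850 nm range rising to the
#' 970 nm shoulder -- not a redistribution of any published tabulation.
#' Because the simulator and the fitter share this table, forward/inverse
#' round trips are exact by construction.
#'
#' @param wavelengths Wavelength grid in nm (strictly increasing).
#' @return A tibble with columns `wavelength_nm`, `HbO2`, `dHb`, `oxCCO`,
#'   `reCCO` (OD uM^-1 cm^-1) and `water` (OD M^-1 cm^-1), with a
#'   `provenance` attribute.
#' @export
#' @examples
#' tbl <- builtin_extinction_table()
#' dplyr::filter(tbl, wavelength_nm == 760)
builtin_extinction_table <- function(wavelengths = default_wavelengths()) {
  l <- wavelengths
  tbl <- tibble::tibble(
    wavelength_nm = l,
    HbO2  = 3.0e-4 + 9.0e-4 * gauss_band(l, 925, 30),
    dHb   = 2.0e-4 + 1.10e-3 * gauss_band(l, 758, 18) +
      4.0e-4 * gauss_band(l, 910, 45),
    oxCCO = 5.0e-4 + 2.6e-3 * gauss_band(l, 845, 22),
    reCCO = 4.0e-4 + 1.4e-3 * gauss_band(l, 740, 45) +
      1.6e-3 * gauss_band(l, 868, 18),
    water = 2.0e-5 + 2.5e-4 * gauss_band(l, 825, 10) +
      9.0e-3 * gauss_band(l, 975, 45)
  )
  attr(tbl, "provenance") <-
    "synthetic literature-shaped surrogate curves (built in code)"
  validate_extinction_table(tbl)
}

#' Validate an extinction table
#'
#' Checks the schema contract: a strictly increasing wavelength grid,
#' exactly the required chromophore columns, non-negative coefficients and
#' equal column lengths.
#'
#' @param tbl A data frame in the extinction-table schema.
#' @return The validated table (invisibly classed), or an error of class
#'   `oxymetr_schema_error` / `oxymetr_format_error`.
#' @export
validate_extinction_table <- function(tbl) {
  nm <- names(tbl)
  if (!"wavelength_nm" %in% nm) {
    abort("extinction table must have a `wavelength_nm` column",
          class = "oxymetr_schema_error")
  }
  missing <- setdiff(OXY_CHROMOPHORES, nm)
  if (length(missing) > 0) {
    abort(paste0("extinction table missing required chromophore(s): ",
                 paste(missing, collapse = ", ")),
          class = "oxymetr_schema_error")
  }
  extra <- setdiff(nm, c("wavelength_nm", OXY_CHROMOPHORES))
  if (length(extra) > 0) {
    abort(paste0("unknown chromophore column(s) rejected: ",
                 paste(extra, collapse = ", ")),
          class = "oxymetr_schema_error")
  }
  w <- tbl$wavelength_nm
  if (any(!is.finite(w)) || any(diff(w) <= 0)) {
    abort("wavelength grid must be finite and strictly increasing",
          class = "oxymetr_format_error")
  }
  eps <- as.matrix(tbl[OXY_CHROMOPHORES])
  if (any(!is.finite(eps)) || any(eps < 0)) {
    abort("extinction coefficients must be finite and non-negative",
          class = "oxymetr_format_error")
  }
  tibble::as_tibble(tbl)
}

#' Load an extinction table from a file or the bundled fixture
#'
#' @param source `"builtin"` for the bundled synthetic table, or a path to
#'   a CSV file with header `wavelength_nm,HbO2,dHb,oxCCO,reCCO,water`.
#' @param wavelengths Working grid the table is resampled to (linear
#'   interpolation). The source table must cover this grid.
#' @return A validated extinction tibble on the working grid.
#' @export
load_extinction_table <- function(source = "builtin",
                                  wavelengths = default_wavelengths()) {
  if (identical(source, "builtin")) {
    return(builtin_extinction_table(wavelengths))
  }
  if (!file.exists(source)) {
    abort(paste0("extinction table file not found: ", source),
          class = "oxymetr_format_error")
  }
  raw <- readr::read_csv(source, show_col_types = FALSE)
  raw <- validate_extinction_table(raw)
  resample_extinction(raw, wavelengths)
}

#' Resample an extinction table to a new wavelength grid
#'
#' Linear interpolation; resampling to the table's own grid is the
#' identity. Extrapolation outside the tabulated range is an error.
#'
#' @param tbl Validated extinction tibble.
#' @param wavelengths Target grid (nm).
#' @return Extinction tibble on `wavelengths`.
#' @export
resample_extinction <- function(tbl, wavelengths) {
  rng <- range(tbl$wavelength_nm)
  if (min(wavelengths) < rng[1] || max(wavelengths) > rng[2]) {
    abort("target grid extends outside the tabulated wavelength range",
          class = "oxymetr_format_error")
  }
  out <- tibble::tibble(wavelength_nm = wavelengths)
  for (ch in OXY_CHROMOPHORES) {
    out[[ch]] <- approx(tbl$wavelength_nm, tbl[[ch]], xout = wavelengths,
                        method = "linear", ties = "ordered")$y
  }
  attr(out, "provenance") <- attr(tbl, "provenance")
  out
}

#' Look up extinction coefficients at arbitrary wavelengths
#'
#' Returns the tabulated value at grid points and linear interpolation
#' between them.
#'
#' @param tbl Validated extinction tibble.
#' @param chromophore One of `HbO2`, `dHb`, `oxCCO`, `reCCO`, `water`.
#' @param wavelength Numeric vector of wavelengths (nm).
#' @return Numeric vector of coefficients.
#' @export
extinction_at <- function(tbl, chromophore, wavelength) {
  chromophore <- match.arg(chromophore, OXY_CHROMOPHORES)
  approx(tbl$wavelength_nm, tbl[[chromophore]], xout = wavelength,
         method = "linear", ties = "ordered")$y
}
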