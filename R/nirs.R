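#' NIRS acquisition protocol
#'
#' Timing contract of the broadband NIRS measurement: continuous spectra
#' at `sampling_rate` Hz for `total_duration` seconds, a terminal anoxia
#' pulse (100% N2) during `anoxia_window`, and an `averaging_window`
#' aligned to the ASL acquisition over which chromophore concentrations
#' are averaged.
#'
#' Defaults follow the study protocol: 25 minutes at 6 Hz, a 50-second
#' anoxia pulse in the last minute, and a 14-minute ASL-aligned averaging
#' window starting after a 1-minute settling period.
#'
#' @param sampling_rate Frames per second (Hz).
#' @param total_duration Total measurement duration (s).
#' @param anoxia_window Length-2 `c(start_s, end_s)` of the anoxia pulse,
#'   or `NULL` for desaturation-free protocols.
#' @param averaging_window Length-2 `c(start_s, end_s)` over which
#'   estimates are averaged.
#' @return Object of class `nirs_protocol`.
#' @export
nirs_protocol <- function(sampling_rate = 6, total_duration = 1500,
                          anoxia_window = c(1440, 1490),
                          averaging_window = c(60, 900)) {
  if (sampling_rate <= 0) {
    abort("sampling_rate must be positive", class = "oxymetr_protocol_error")
  }
  chk <- function(w, nm) {
    if (is.null(w)) return(invisible())
    if (length(w) != 2 || w[2] <= w[1] || w[1] < 0 || w[2] > total_duration) {
      abort(paste0(nm, " must be a non-empty window within the measurement"),
            class = "oxymetr_protocol_error")
    }
  }
  chk(anoxia_window, "anoxia_window")
  chk(averaging_window, "averaging_window")
  structure(list(sampling_rate = sampling_rate,
                 total_duration = total_duration,
                 anoxia_window = anoxia_window,
                 averaging_window = averaging_window),
            class = "nirs_protocol")
}

#' Spectral fitting configuration
#'
#' Per-chromophore wavelength windows and derivative smoothing used by the
#' second-derivative inversion. Defaults: deoxyhemoglobin fitted in
#' second-derivative space over 720-800 nm (the 760 nm band), optical
#' pathlength from the water feature over 800-850 nm, and the CCO redox
#' couple over 780-900 nm on baseline-augmented attenuation.
#'
#' @param dhb_window,water_window,cco_window Length-2 nm ranges.
#' @param sg_window,sg_order Savitzky-Golay window length (odd) and
#'   polynomial order for the second derivative.
#' @param water_fraction Assumed tissue water volume fraction.
#' @param plateau_smooth_s Running-mean width (s) applied to the
#'   frame-wise dHb trace before the anoxia plateau statistic.
#' @param plateau_quantile The plateau statistic is the mean of the values
#'   above this quantile within the anoxia window (default top quartile).
#' @return Object of class `nirs_fit_config`.
#' @export
nirs_fit_config <- function(dhb_window = c(720, 800),
                            water_window = c(800, 850),
                            cco_window = c(780, 900),
                            sg_window = 11, sg_order = 3,
                            water_fraction = 0.80,
                            plateau_smooth_s = 10,
                            plateau_quantile = 0.75) {
  structure(list(dhb_window = dhb_window, water_window = water_window,
                 cco_window = cco_window, sg_window = sg_window,
                 sg_order = sg_order, water_fraction = water_fraction,
                 plateau_smooth_s = plateau_smooth_s,
                 plateau_quantile = plateau_quantile),
            class = "nirs_fit_config")
}

in_window <- function(lambda, window) {
  lambda >= window[1] & lambda <= window[2]
}

#' Estimate the mean optical pathlength from the water feature
#'
#' Least-squares match of the measured second-derivative spectrum to the
#' second derivative of the tissue-water absorption template over the
#' water window (default 800-850 nm), with the hemoglobin and CCO curves
#' as nuisance regressors so their in-window curvature cannot bias the
#' water scale. The water template is
#' `water_fraction * M_water * eps_water(lambda)`, so the fitted scale is
#' the pathlength in cm directly; halving the assumed water fraction
#' exactly doubles the estimate.
#'
#' @param spectrum Attenuation tibble (`wavelength_nm`, `attenuation_od`).
#' @param table Extinction tibble on the same grid.
#' @param water_fraction Assumed water volume fraction (default from
#'   `config`, 0.80).
#' @param config A [nirs_fit_config()] (windows and smoothing).
#' @return Pathlength estimate in cm (positive scalar).
#' @export
estimate_pathlength <- function(spectrum, table,
                                water_fraction = config$water_fraction,
                                config = nirs_fit_config()) {
  lambda <- table$wavelength_nm
  stopifnot(isTRUE(all.equal(spectrum$wavelength_nm, lambda)))
  if (min(lambda) > config$water_window[1] ||
      max(lambda) < config$water_window[2]) {
    abort("spectrum does not cover the water fitting window",
          class = "oxymetr_format_error")
  }
  h <- lambda[2] - lambda[1]
  sel <- in_window(lambda, config$water_window)
  d2 <- function(v) sg_second_derivative(v, h, config$sg_window,
                                         config$sg_order)
  template <- water_fraction * water_molarity_M * table$water
  X <- cbind(water = d2(template),
             HbO2 = d2(table$HbO2), dHb = d2(table$dHb),
             oxCCO = d2(table$oxCCO), reCCO = d2(table$reCCO))[sel, ]
  y <- d2(spectrum$attenuation_od)[sel]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    abort("rank-deficient spectral design over the water window",
          class = "oxymetr_conditioning_error")
  }
  L <- unname(qr.coef(qrX, y)["water"])
  if (!is.finite(L) || L <= 1e-6) {
    abort("degenerate spectrum: fitted water scale is not positive",
          class = "oxymetr_degenerate_error")
  }
  L
}

#' Precompute the spectral-regression projectors
#'
#' Builds, once per extinction table and configuration, the linear maps
#' that turn an attenuation spectrum into chromophore estimates: the
#' second-derivative operator, the dHb-window projector in
#' second-derivative space, and the CCO-window projector on
#' baseline-augmented attenuation. Both designs are built at unit
#' pathlength; fitted concentrations are divided by the animal's
#' pathlength afterwards, so one projector set serves a whole cohort.
#'
#' @param table Extinction tibble.
#' @param config A [nirs_fit_config()].
#' @return Opaque projector list consumed by [fit_chromophores()] and
#'   [analyze_nirs()].
#' @export
chromophore_projectors <- function(table, config = nirs_fit_config()) {
  lambda <- table$wavelength_nm
  h <- lambda[2] - lambda[1]
  chrom <- c("HbO2", "dHb", "oxCCO", "reCCO")
  for (w in list(config$dhb_window, config$cco_window)) {
    if (min(lambda) > w[1] || max(lambda) < w[2]) {
      abort("fitting window outside the spectral grid",
            class = "oxymetr_format_error")
    }
  }
  D <- sg_d2_operator(length(lambda), h, config$sg_window, config$sg_order)
  E <- as.matrix(table[chrom])

  # dHb: second-derivative space over its window
  sel_d <- in_window(lambda, config$dhb_window)
  Xd <- (D %*% E)[sel_d, , drop = FALSE]
  colnames(Xd) <- chrom
  if (qr(Xd)$rank < ncol(Xd)) {
    abort("rank-deficient spectral design over the dHb window",
          class = "oxymetr_conditioning_error")
  }
  Pd <- solve(crossprod(Xd), t(Xd)) %*% D[sel_d, , drop = FALSE]
  rownames(Pd) <- chrom

  # CCO: baseline-augmented raw attenuation over its window
  sel_c <- in_window(lambda, config$cco_window)
  lam_c <- lambda[sel_c]
  Xc <- cbind(E[sel_c, , drop = FALSE], icpt = 1, slope = lam_c - mean(lam_c))
  if (qr(Xc)$rank < ncol(Xc)) {
    abort("rank-deficient spectral design over the CCO window",
          class = "oxymetr_conditioning_error")
  }
  Pc <- solve(crossprod(Xc), t(Xc))
  rownames(Pc) <- c(chrom, "icpt", "slope")

  list(Pd = Pd, Pc = Pc, Xc = Xc, sel_c = sel_c, chrom = chrom,
       water_od_unitL = config$water_fraction * water_molarity_M *
         table$water)
}

#' Fit chromophore concentrations from an attenuation spectrum
#'
#' Multilinear regression of the measured spectrum on the specific
#' absorption coefficients, per chromophore window: deoxyhemoglobin is
#' solved in second-derivative space over its window (any linear
#' scattering baseline is annihilated), while the CCO redox couple is
#' solved on raw attenuation over its window with intercept and slope
#' nuisance regressors absorbing the baseline. Oxyhemoglobin is
#' co-fitted as a nuisance chromophore in both designs; the known water
#' contribution (pathlength x water fraction) is subtracted first.
#' Deterministic, and exact on noise-free forward spectra.
#'
#' @param spectrum Attenuation tibble on the table grid.
#' @param pathlength Mean optical pathlength (cm, > 0).
#' @param table Extinction tibble.
#' @param config A [nirs_fit_config()].
#' @param projectors Optional precomputed [chromophore_projectors()].
#' @return One-row tibble with `dHb_uM`, `oxCCO_uM`, `reCCO_uM`,
#'   `fit_rms_od` (RMS residual of the CCO-window fit).
#' @export
fit_chromophores <- function(spectrum, pathlength, table,
                             config = nirs_fit_config(),
                             projectors = NULL) {
  stopifnot(pathlength > 0)
  pj <- projectors %||% chromophore_projectors(table, config)
  y <- spectrum$attenuation_od - pathlength * pj$water_od_unitL
  beta_d <- drop(pj$Pd %*% y) / pathlength
  yc <- y[pj$sel_c]
  beta_c <- drop(pj$Pc %*% yc)
  fitted_c <- drop(pj$Xc %*% beta_c)
  rms <- sqrt(mean((yc - fitted_c)^2))
  beta_c[pj$chrom] <- beta_c[pj$chrom] / pathlength
  tibble::tibble(dHb_uM = unname(beta_d["dHb"]),
                 oxCCO_uM = unname(beta_c["oxCCO"]),
                 reCCO_uM = unname(beta_c["reCCO"]),
                 fit_rms_od = rms)
}

# Frame-wise dHb estimates for a block of spectra (columns = frames).
fit_dhb_frames <- function(od_matrix, pathlength, projectors) {
  y <- od_matrix - pathlength * projectors$water_od_unitL
  (projectors$Pd %*% y)["dHb", ] / pathlength
}

running_mean <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- floor(k / 2)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Total hemoglobin from the anoxia pulse
#'
#' During the terminal 100% N2 pulse all hemoglobin deoxygenates, so the
#' deoxyhemoglobin plateau equals total hemoglobin (`[tHb] = [dHb]`). The
#' plateau statistic is the mean of the top quartile (configurable) of
#' the lightly time-smoothed dHb trace within the anoxia window, which is
#' robust to the ramp-in at the start of the pulse.
#'
#' @param dhb_series Tibble with `time_s` and `dHb_uM`.
#' @param protocol A [nirs_protocol()] with a non-`NULL` anoxia window.
#' @param config A [nirs_fit_config()] (smoothing width and quantile).
#' @return One-row tibble: `tHb_uM`, `window_start_s`, `window_end_s`,
#'   `n_frames`.
#' @export
estimate_tHb_anoxia <- function(dhb_series, protocol,
                                config = nirs_fit_config()) {
  if (is.null(protocol$anoxia_window)) {
    abort(paste("protocol has no anoxia window: run in desaturation-free",
                "mode and supply tHb externally"),
          class = "oxymetr_protocol_error")
  }
  w <- protocol$anoxia_window
  t <- dhb_series$time_s
  if (max(t) < w[2] - 1 / protocol$sampling_rate - 1e-9 || min(t) > w[1]) {
    abort("dHb series does not cover the anoxia window",
          class = "oxymetr_protocol_error")
  }
  dt <- if (length(t) > 1) min(diff(t)) else 1 / protocol$sampling_rate
  k <- max(1L, round(config$plateau_smooth_s / dt))
  sel <- t >= w[1] & t < w[2]
  smoothed <- running_mean(dhb_series$dHb_uM, k)[sel]
  thr <- stats::quantile(smoothed, config$plateau_quantile, names = FALSE)
  plateau <- smoothed[smoothed >= thr]
  tibble::tibble(tHb_uM = mean(plateau), window_start_s = w[1],
                 window_end_s = w[2], n_frames = sum(sel))
}

#' Tissue oxygen saturation
#'
#' `StO2 = (1 - dHb / tHb) * 100`, the fraction of microvascular
#' hemoglobin that is oxygenated, clipped to `[0, 100]` with a clip flag
#' so that noisy animals near the physiological bounds survive cohort
#' assembly but remain auditable.
#'
#' @param dHb_uM Baseline deoxyhemoglobin concentration (uM).
#' @param tHb_uM Total hemoglobin concentration (uM, > 0).
#' @return Tibble with `StO2_pct` and logical `clipped`.
#' @export
compute_StO2 <- function(dHb_uM, tHb_uM) {
  if (any(tHb_uM <= 0)) {
    abort("tHb must be positive", class = "oxymetr_degenerate_error")
  }
  raw <- (1 - dHb_uM / tHb_uM) * 100
  tibble::tibble(StO2_pct = pmin(pmax(raw, 0), 100),
                 clipped = raw < 0 | raw > 100)
}

#' Average frame-wise estimates over a time window
#'
#' Arithmetic mean of every numeric column over frames with
#' `start_s <= time_s < end_s` (half-open, so a 14-minute window at 6 Hz
#' averages exactly 5040 frames).
#'
#' @param series Tibble with a `time_s` column plus numeric columns.
#' @param window Length-2 `c(start_s, end_s)`.
#' @return One-row tibble of column means plus `n_frames`.
#' @export
average_over_window <- function(series, window) {
  sel <- series$time_s >= window[1] & series$time_s < window[2]
  if (!any(sel)) {
    abort("averaging window contains no frames",
          class = "oxymetr_protocol_error")
  }
  out <- dplyr::summarise(series[sel, ],
                          dplyr::across(-dplyr::any_of("time_s"), mean))
  out$n_frames <- sum(sel)
  out
}

#' Full per-animal NIRS quantification
#'
#' Runs the complete spectral pipeline on one animal's attenuation time
#' series: window-averaged spectrum, pathlength from the water feature,
#' chromophore regression, frame-wise dHb through the anoxia pulse for
#' the tHb calibration, and StO2.
#'
#' @param frames Wide tibble: `time_s` plus one `od_<nm>` column per
#'   wavelength (as produced by [simulate_nirs_timeseries()] or read from
#'   a spectra CSV).
#' @param table Extinction tibble on the matching grid.
#' @param protocol A [nirs_protocol()].
#' @param config A [nirs_fit_config()].
#' @param projectors Optional precomputed [chromophore_projectors()]
#'   (one set serves a whole cohort).
#' @return One-row tibble: `dHb_uM`, `oxCCO_uM`, `reCCO_uM`, `totCCO_uM`,
#'   `tHb_uM`, `StO2_pct`, `sto2_clipped`, `pathlength_cm`, `fit_rms_od`.
#' @export
analyze_nirs <- function(frames, table, protocol = nirs_protocol(),
                         config = nirs_fit_config(), projectors = NULL) {
  od_cols <- grep("^od_", names(frames), value = TRUE)
  lambda <- as.numeric(sub("^od_", "", od_cols))
  stopifnot(isTRUE(all.equal(lambda, table$wavelength_nm)))
  tvec <- frames$time_s

  avg_sel <- tvec >= protocol$averaging_window[1] &
    tvec < protocol$averaging_window[2]
  if (!any(avg_sel)) {
    abort("averaging window contains no frames",
          class = "oxymetr_protocol_error")
  }
  od_mat <- t(as.matrix(frames[od_cols]))  # wavelengths x frames
  avg_spec <- tibble::tibble(
    wavelength_nm = lambda,
    attenuation_od = rowMeans(od_mat[, avg_sel, drop = FALSE])
  )
  pj <- projectors %||% chromophore_projectors(table, config)
  L <- estimate_pathlength(avg_spec, table, config = config)
  est <- fit_chromophores(avg_spec, L, table, config, projectors = pj)

  dhb_series <- tibble::tibble(time_s = tvec,
                               dHb_uM = fit_dhb_frames(od_mat, L, pj))
  thb <- estimate_tHb_anoxia(dhb_series, protocol, config)
  sto2 <- compute_StO2(est$dHb_uM, thb$tHb_uM)

  tibble::tibble(
    dHb_uM = est$dHb_uM, oxCCO_uM = est$oxCCO_uM, reCCO_uM = est$reCCO_uM,
    totCCO_uM = est$oxCCO_uM + est$reCCO_uM,
    tHb_uM = thb$tHb_uM, StO2_pct = sto2$StO2_pct,
    sto2_clipped = sto2$clipped, pathlength_cm = L,
    fit_rms_od = est$fit_rms_od
  )
}
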