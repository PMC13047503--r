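noise_free_spectrum <- function(state = ref_state()) {
  attenuation_forward(state, oxy_table)
}

test_that("pathlength round trip recovers the true pathlength", {
  spec <- noise_free_spectrum(ref_state(pathlength = 1.8))
  expect_equal(estimate_pathlength(spec, oxy_table), 1.8, tolerance = 1e-3)
})

test_that("pathlength is inversely proportional to the assumed water fraction", {
  spec <- noise_free_spectrum()
  L80 <- estimate_pathlength(spec, oxy_table, water_fraction = 0.80)
  L40 <- estimate_pathlength(spec, oxy_table, water_fraction = 0.40)
  expect_equal(L40, 2 * L80)
})

test_that("waterless spectrum raises a degenerate-spectrum error", {
  dry <- tissue_state(c(dHb = 17.3, HbO2 = 82.7), water_fraction = 0,
                      pathlength_cm = 1.8)
  spec <- attenuation_forward(dry, oxy_table)
  expect_error(estimate_pathlength(spec, oxy_table),
               class = "oxymetr_degenerate_error")
})

test_that("chromophore fit recovers noise-free concentrations exactly", {
  st <- tissue_state(c(dHb = 20, HbO2 = 80, oxCCO = 3.4, reCCO = 1.2),
                     pathlength_cm = 1.8, baseline = c(0, 0))
  est <- fit_chromophores(attenuation_forward(st, oxy_table), 1.8, oxy_table)
  expect_equal(est$dHb_uM, 20, tolerance = 1e-6)
  expect_equal(est$oxCCO_uM, 3.4, tolerance = 1e-6)
  expect_equal(est$reCCO_uM, 1.2, tolerance = 1e-6)
})

test_that("chromophore fit is invariant to the scattering baseline", {
  conc <- c(dHb = 20, HbO2 = 80, oxCCO = 3.4, reCCO = 1.2)
  s0 <- tissue_state(conc, pathlength_cm = 1.8, baseline = c(0, 0))
  s1 <- tissue_state(conc, pathlength_cm = 1.8, baseline = c(0.45, 3e-4))
  e0 <- fit_chromophores(attenuation_forward(s0, oxy_table), 1.8, oxy_table)
  e1 <- fit_chromophores(attenuation_forward(s1, oxy_table), 1.8, oxy_table)
  expect_equal(e0$dHb_uM, e1$dHb_uM, tolerance = 1e-6)
  expect_equal(e0$oxCCO_uM, e1$oxCCO_uM, tolerance = 1e-6)
  expect_equal(e0$reCCO_uM, e1$reCCO_uM, tolerance = 1e-6)
})

test_that("totCCO recovered from the healthy-group preset means is 4.6 uM", {
  # oxCCO = 0.74 * 4.6, reCCO = 0.26 * 4.6 as in the naive preset
  st <- tissue_state(c(dHb = 17.3, HbO2 = 82.7,
                       oxCCO = 0.74 * 4.6, reCCO = 0.26 * 4.6),
                     pathlength_cm = 1.8)
  est <- fit_chromophores(attenuation_forward(st, oxy_table), 1.8, oxy_table)
  expect_equal(est$oxCCO_uM + est$reCCO_uM, 4.6, tolerance = 1e-6)
})

test_that("anoxia plateau statistic recovers total hemoglobin", {
  proto <- short_protocol()
  t <- seq(0, proto$total_duration - 1 / 6, by = 1 / 6)
  w <- proto$anoxia_window
  dhb <- rep(17, length(t))
  ramp <- t >= w[1] & t < w[1] + 20
  dhb[ramp] <- 17 + (100 - 17) * (t[ramp] - w[1]) / 20
  dhb[t >= w[1] + 20] <- 100
  est <- estimate_tHb_anoxia(tibble::tibble(time_s = t, dHb_uM = dhb), proto)
  expect_equal(est$tHb_uM, 100, tolerance = 0.01)

  # constant series is returned unchanged
  est50 <- estimate_tHb_anoxia(tibble::tibble(time_s = t,
                                              dHb_uM = rep(50, length(t))),
                               proto)
  expect_equal(est50$tHb_uM, 50)
})

test_that("anoxia estimation fails when the series misses the window", {
  proto <- short_protocol()
  t <- seq(0, 200, by = 1 / 6)
  expect_error(estimate_tHb_anoxia(tibble::tibble(time_s = t,
                                                  dHb_uM = rep(17, length(t))),
                                   proto),
               class = "oxymetr_protocol_error")
  no_anx <- nirs_protocol(total_duration = 300, anoxia_window = NULL,
                          averaging_window = c(10, 230))
  expect_error(estimate_tHb_anoxia(tibble::tibble(time_s = t, dHb_uM = 17),
                                   no_anx),
               class = "oxymetr_protocol_error")
})

test_that("StO2 covers the saturation extremes and the healthy-group value", {
  expect_equal(compute_StO2(100, 100)$StO2_pct, 0)
  expect_equal(compute_StO2(0, 100)$StO2_pct, 100)
  expect_equal(compute_StO2(17.3, 100)$StO2_pct, 82.7)
  clipped <- compute_StO2(120, 100)
  expect_equal(clipped$StO2_pct, 0)
  expect_true(clipped$clipped)
  expect_error(compute_StO2(10, 0), class = "oxymetr_degenerate_error")
})

test_that("window averaging uses half-open frames and reports counts", {
  s <- tibble::tibble(time_s = c(0, 1, 2, 3), x = c(4, 4, 6, 9))
  out <- average_over_window(s, c(1, 3))
  expect_equal(out$x, 5)
  expect_equal(out$n_frames, 2L)
  expect_error(average_over_window(s, c(10, 20)),
               class = "oxymetr_protocol_error")
  # a 14-minute window at 6 Hz averages exactly 5040 frames
  t6 <- tibble::tibble(time_s = seq(0, 1500 - 1 / 6, by = 1 / 6), x = 1)
  expect_equal(average_over_window(t6, c(60, 900))$n_frames, 5040L)
})

test_that("full NIRS pipeline inverts noise-free simulated series", {
  proto <- short_protocol()
  an <- sample_animal(builtin_presets()$naive, 7)
  frames <- simulate_nirs_timeseries(an, proto, oxy_table, noise_sd_od = 0,
                                     seed = 1)
  est <- analyze_nirs(frames, oxy_table, proto)
  expect_equal(est$dHb_uM, an$dHb_uM, tolerance = 5e-3)
  expect_equal(est$totCCO_uM, an$totCCO_uM, tolerance = 5e-3)
  expect_equal(est$tHb_uM, an$tHb_uM, tolerance = 5e-3)
  expect_equal(est$StO2_pct, an$StO2_pct, tolerance = 5e-3)
  expect_equal(est$pathlength_cm, an$pathlength_cm, tolerance = 1e-3)
})

test_that("noisy estimates are unbiased within standard error over seeds", {
  proto <- short_protocol()
  an <- sample_animal(builtin_presets()$naive, 3)
  ests <- purrr::map_dfr(1:60, function(s)
    analyze_nirs(simulate_nirs_timeseries(an, proto, oxy_table,
                                          noise_sd_od = 1e-3, seed = s),
                 oxy_table, proto))
  for (col in c("dHb_uM", "totCCO_uM")) {
    bias <- mean(ests[[col]]) - an[[col]]
    se <- sd(ests[[col]]) / sqrt(nrow(ests))
    expect_lt(abs(bias), 4 * se + 0.01 * an[[col]])
  }
})

test_that("estimated dHb is monotone in true dHb", {
  prev <- -Inf
  for (dhb in c(5, 15, 25, 40, 60)) {
    st <- tissue_state(c(dHb = dhb, HbO2 = 100 - dhb, oxCCO = 3.4,
                         reCCO = 1.2), pathlength_cm = 1.8)
    est <- fit_chromophores(attenuation_forward(st, oxy_table), 1.8,
                            oxy_table)
    expect_gt(est$dHb_uM, prev)
    prev <- est$dHb_uM
  }
})

test_that("totCCO always equals oxCCO + reCCO in pipeline output", {
  proto <- short_protocol()
  an <- sample_animal(builtin_presets()$eae, 11)
  frames <- simulate_nirs_timeseries(an, proto, oxy_table,
                                     noise_sd_od = 1e-3, seed = 2)
  est <- analyze_nirs(frames, oxy_table, proto)
  expect_equal(est$totCCO_uM, est$oxCCO_uM + est$reCCO_uM, tolerance = 1e-9)
})
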