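test_that("bundled extinction table contains exactly the required chromophores", {
  expect_setequal(setdiff(names(oxy_table), "wavelength_nm"),
                  c("HbO2", "dHb", "oxCCO", "reCCO", "water"))
  expect_true(all(diff(oxy_table$wavelength_nm) > 0))
  expect_true(all(as.matrix(oxy_table[-1]) >= 0))
  expect_equal(range(oxy_table$wavelength_nm), c(705, 960))
})

test_that("table validation rejects bad schemas", {
  expect_error(validate_extinction_table(oxy_table[-2]),
               class = "oxymetr_schema_error")
  extra <- oxy_table; extra$melanin <- 1
  expect_error(validate_extinction_table(extra),
               class = "oxymetr_schema_error")
  bad <- oxy_table; bad$wavelength_nm <- rev(bad$wavelength_nm)
  expect_error(validate_extinction_table(bad),
               class = "oxymetr_format_error")
})

test_that("loading a CSV table resamples it onto the working grid", {
  path <- withr::local_tempfile(fileext = ".csv")
  coarse <- builtin_extinction_table(seq(705, 960, by = 5))
  readr::write_csv(coarse, path)
  tbl <- load_extinction_table(path)
  expect_equal(tbl$wavelength_nm, 705:960)
  # identity at the source grid points
  expect_equal(tbl$dHb[tbl$wavelength_nm %in% coarse$wavelength_nm],
               coarse$dHb)
})

test_that("extinction lookup is exact at grid points and linear between them", {
  coarse <- builtin_extinction_table(seq(706, 960, by = 2))
  expect_equal(extinction_at(coarse, "dHb", 758),
               coarse$dHb[coarse$wavelength_nm == 758])
  # midpoint oracle on an even grid: (eps(l1) + eps(l2)) / 2
  mid <- (coarse$dHb[coarse$wavelength_nm == 758] +
            coarse$dHb[coarse$wavelength_nm == 760]) / 2
  expect_equal(extinction_at(coarse, "dHb", 759), mid)
})

test_that("resampling a table to its own grid is the identity", {
  out <- resample_extinction(oxy_table, oxy_table$wavelength_nm)
  expect_equal(as.data.frame(out), as.data.frame(oxy_table))
})

test_that("forward model: absorption-free, linearity and scalar oracle", {
  flat <- tissue_state(c(dHb = 0), water_fraction = 0,
                       pathlength_cm = 1, baseline = c(0.3, 0))
  expect_equal(attenuation_forward(flat, oxy_table)$attenuation_od,
               rep(0.3, nrow(oxy_table)))

  st1 <- ref_state(baseline = c(0, 0))
  st2 <- tissue_state(st1$concentrations * 2, water_fraction = 0,
                      pathlength_cm = st1$pathlength_cm)
  st1b <- tissue_state(st1$concentrations, water_fraction = 0,
                       pathlength_cm = st1$pathlength_cm)
  expect_equal(attenuation_forward(st2, oxy_table)$attenuation_od,
               2 * attenuation_forward(st1b, oxy_table)$attenuation_od)

  # single chromophore: A(lambda) = 10 * eps_dHb(lambda), hand product
  solo <- tissue_state(c(dHb = 10), water_fraction = 0, pathlength_cm = 1)
  A <- attenuation_forward(solo, oxy_table)
  for (wl in c(720, 758, 900)) {
    expect_equal(A$attenuation_od[A$wavelength_nm == wl],
                 10 * oxy_table$dHb[oxy_table$wavelength_nm == wl])
  }
})

test_that("forward model rejects chromophores missing from the table", {
  # tissue_state itself refuses unknown chromophore names
  expect_error(tissue_state(c(melanin = 1), pathlength_cm = 1),
               class = "oxymetr_state_error")
  # and the forward model refuses a table lacking a state's chromophore
  st <- ref_state()
  crippled <- oxy_table[setdiff(names(oxy_table), "reCCO")]
  expect_error(attenuation_forward(st, crippled),
               class = "oxymetr_schema_error")
})

test_that("second derivative annihilates linear input and is exact on quadratics", {
  l <- 705:960
  lin <- tibble::tibble(wavelength_nm = l, attenuation_od = 0.2 + 1e-3 * l)
  expect_lt(max(abs(second_derivative(lin)$d2_od_nm2)), 1e-10)

  cc <- 3.7e-4
  quad <- tibble::tibble(wavelength_nm = l, attenuation_od = cc * l^2)
  expect_equal(second_derivative(quad)$d2_od_nm2, rep(2 * cc, length(l)),
               tolerance = 1e-8)
})

test_that("second derivative matches a central finite-difference oracle", {
  l <- 705:960
  y <- 0.5 * exp(-(l - 830)^2 / (2 * 30^2))
  d2 <- second_derivative(tibble::tibble(wavelength_nm = l,
                                         attenuation_od = y))$d2_od_nm2
  fd <- (y[1:254] - 2 * y[2:255] + y[3:256])  # h = 1 nm
  interior <- 10:245
  expect_lt(max(abs(d2[interior + 1] - fd[interior]) / max(abs(fd))), 0.01)
})

test_that("second derivative enforces its preconditions", {
  short <- tibble::tibble(wavelength_nm = 705:710,
                          attenuation_od = rnorm(6))
  expect_error(second_derivative(short), class = "oxymetr_format_error")
  irr <- tibble::tibble(wavelength_nm = c(705:750, 752),
                        attenuation_od = rnorm(47))
  expect_error(second_derivative(irr), class = "oxymetr_format_error")
  expect_error(second_derivative(
    tibble::tibble(wavelength_nm = 705:760, attenuation_od = 0),
    window = 10), class = "oxymetr_format_error")
})

test_that("second derivative of the forward model is baseline invariant", {
  set.seed(42)
  for (i in 1:5) {
    conc <- c(dHb = runif(1, 5, 40), HbO2 = runif(1, 40, 120),
              oxCCO = runif(1, 1, 5), reCCO = runif(1, 0.2, 2))
    L <- runif(1, 1, 2.5)
    s0 <- tissue_state(conc, pathlength_cm = L, baseline = c(0, 0))
    s1 <- tissue_state(conc, pathlength_cm = L,
                       baseline = c(runif(1, -1, 1), runif(1, -5e-3, 5e-3)))
    d0 <- second_derivative(attenuation_forward(s0, oxy_table))$d2_od_nm2
    d1 <- second_derivative(attenuation_forward(s1, oxy_table))$d2_od_nm2
    expect_lt(max(abs(d0 - d1)), 1e-8)
  }
})
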