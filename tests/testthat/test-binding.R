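test_that("speciate matches the mass-action bisection oracle and conserves mass", {
  # frozen oracle value: G = H = 1e-3 M, K = 1000 1/M
  sp <- speciate(1e-3, 1e-3, 1000)
  expect_equal(sp$complex, 3.8197e-4, tolerance = 1e-4)
  expect_equal(sp$complex, oracle_complex(1e-3, 1e-3, 1000), tolerance = 1e-12)

  Ks <- 10^seq(0, 8, length.out = 9)
  Gs <- 10^seq(-6, -2, length.out = 5)
  Hs <- 10^seq(-6, -2, length.out = 5)
  for (K in Ks) for (G in Gs) for (H in Hs) {
    sp <- speciate(G, H, K)
    expect_equal(sp$complex, oracle_complex(G, H, K),
                 tolerance = 1e-10)
    expect_equal(sp$free_guest + sp$complex, G, tolerance = 1e-12)
    expect_equal(sp$free_host + sp$complex, H, tolerance = 1e-12)
    expect_lte(sp$complex, min(G, H) * (1 + 1e-12))
  }
})

test_that("speciate handles the limits: no binding, saturation, zero concentrations", {
  expect_equal(speciate(1e-3, 5e-3, 0)$complex, 0)
  expect_equal(speciate(0, 1e-3, 1e4)$complex, 0)
  # essentially irreversible binding with 10x host: all guest complexed
  G <- 4e-4
  expect_equal(speciate(G, 10 * G, 1e12)$complex / G, 1, tolerance = 1e-6)
  expect_error(speciate(-1e-3, 1e-3, 10), "non-negative")
})

test_that("speciate is monotone in K, host and guest totals", {
  base <- speciate(4e-4, 2e-3, 10^seq(0, 8, by = 0.5))$complex
  expect_true(all(diff(base) >= 0))
  inH <- speciate(4e-4, seq(0, 1e-2, length.out = 30), 1e3)$complex
  expect_true(all(diff(inH) >= 0))
  inG <- speciate(seq(1e-5, 1e-2, length.out = 30), 2e-3, 1e3)$complex
  expect_true(all(diff(inG) >= 0))
})

test_that("icd_response obeys Beer-Lambert proportionality to the complex", {
  deps <- new_spectrum(c(280, 281), c(1, 1), unit = "delta_epsilon")
  sp <- tibble::tibble(free_guest = 0, free_host = 0, complex = 1e-3)
  out <- icd_response(deps, sp, pathlength_cm = 1)
  expect_equal(out$value, c(1e-3, 1e-3))
  expect_identical(spectrum_unit(out), "delta_absorbance")

  expect_equal(icd_response(deps, tibble::tibble(complex = 0), 1)$value, c(0, 0))
  # halving the cell from the 0.2 cm cuvette to 0.1 cm halves the signal
  a <- icd_response(deps, sp, 0.2)$value
  b <- icd_response(deps, sp, 0.1)$value
  expect_equal(a, 2 * b)
})

test_that("uv_mixture interpolates between the free and complex spectra", {
  grid <- seq(250, 300, by = 0.5)
  ef <- gaussian_spectrum(270.6, 6, 1400, grid, unit = "molar_absorption")
  ec <- gaussian_spectrum(273.6, 6, 1400, grid, unit = "molar_absorption")
  G <- 4e-4

  free_only <- uv_mixture(ef, ec, speciate(G, 0, 1e3), 1)
  expect_equal(free_only$value, ef$value * G)

  sat <- uv_mixture(ef, ec, tibble::tibble(free_guest = 0, free_host = 0, complex = G), 1)
  expect_equal(sat$value, ec$value * G)

  # equal free/complex -> apparent maximum strictly between the components
  half <- uv_mixture(ef, ec, tibble::tibble(free_guest = G / 2, complex = G / 2), 1)
  lam <- as.numeric(find_lambda_max(half))
  expect_gt(lam, 270.6)
  expect_lt(lam, 273.6)

  bad <- gaussian_spectrum(270, 6, 1, seq(250, 299, by = 0.5), unit = "molar_absorption")
  expect_error(uv_mixture(ef, bad, speciate(G, 0, 1e3), 1), "grid")
})

test_that("shift_curve is monotone toward the complex band and flat for identical bands", {
  grid <- seq(250, 300, by = 0.5)
  ef <- gaussian_spectrum(270.6, 6, 1400, grid, unit = "molar_absorption")
  red <- gaussian_spectrum(273.6, 6, 1750, grid, unit = "molar_absorption")
  G <- 4e-4
  hosts <- c(0, 5, 25) * G
  sc <- shift_curve(ef, red, G, hosts, K = 10^3.06)
  expect_true(all(diff(sc$lambda_max) > 0))

  blue <- gaussian_spectrum(267.6, 6, 1750, grid, unit = "molar_absorption")
  sc_blue <- shift_curve(ef, blue, G, hosts, K = 10^3.06)
  expect_true(all(diff(sc_blue$lambda_max) < 0))

  sc_same <- shift_curve(ef, ef, G, hosts, K = 10^3.06)
  expect_equal(diff(sc_same$lambda_max), c(0, 0), tolerance = 1e-9)
})

test_that("single-wavelength fitter recovers K from noiseless titrations", {
  for (lk in c(2.0, 2.5, 3.0, 3.5)) {
    sim <- generate_titration(scenario(true_logK = lk))
    fit <- fit_k_single_wavelength(sim$cd, 280.6)
    expect_equal(fit$logK, lk, tolerance = 1e-3)
    expect_false(fit$ill_conditioned)
    expect_true(fit$converged)
  }
})

test_that("single-wavelength fitter enforces its preconditions and flags flat curves", {
  sim <- generate_titration(scenario())
  two_pt <- titration_series(sim$cd$spectrum[1:2], sim$cd$guest_M[1:2],
                             sim$cd$host_M[1:2], sim$cd$pathlength_cm[1:2])
  expect_error(fit_k_single_wavelength(two_pt, 280.6), "3 titration points")

  zero <- titration_series(
    purrr::map(1:4, ~ new_spectrum(c(280, 281), c(0, 0), unit = "delta_absorbance")),
    guest_M = 4e-4, host_M = c(0, 1, 2, 3) * 4e-4)
  expect_error(fit_k_single_wavelength(zero, 280), "no binding signal")

  # every point saturated: flat curve carries no information on K
  sat <- generate_titration(scenario(true_logK = 9, host_ratios = c(5, 10, 15, 20)))
  fit <- fit_k_single_wavelength(sat$cd, 280.6)
  expect_true(fit$ill_conditioned)
})

test_that("global variable-projection fit recovers K and the complex CD band", {
  sc <- scenario(true_logK = 3.0)
  sim <- generate_titration(sc)
  fit <- fit_k_global(sim$cd)
  expect_equal(fit$logK, 3.0, tolerance = 1e-3)
  # fitted per-molar band matches the generating band
  truth <- icdbind:::band_profile(sc$grid, sc$cd_complex_bands)
  expect_lt(max(abs(fit$fitted_response$delta_eps - truth)), 1e-6)
})

test_that("global fit reduces to the single-wavelength fit on a one-point grid", {
  sc <- scenario(grid = c(280.6), cd_complex_bands = band(280.6, 4, 1.5))
  sim <- generate_titration(sc)
  # pad to 2 wavelengths for spectrum validity, then restrict readout
  f_single <- fit_k_single_wavelength(sim$cd, 280.6)
  f_global <- fit_k_global(sim$cd)
  expect_equal(f_global$logK, f_single$logK, tolerance = 1e-9)
})

test_that("noisy replicate fits are unbiased within the simulation tolerance", {
  errs <- purrr::map_dbl(1:100, function(i) {
    sim <- generate_titration(scenario(true_logK = 3.06, noise_frac = 0.02, seed = i))
    fit_k_global(sim$cd)$logK - 3.06
  })
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("tidy and glance summarise a binding fit broom-style", {
  sim <- generate_titration(scenario())
  fit <- fit_k_global(sim$cd)
  td <- tidy(fit)
  expect_identical(td$term, c("K", "logK"))
  expect_equal(td$estimate[2], log10(td$estimate[1]))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_gte(gl$residual_rms, 0)
})
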