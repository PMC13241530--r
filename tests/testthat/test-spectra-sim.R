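test_that("wavelength grid is evenly spaced and defaults to 141 points", {
  g <- wavelength_grid()
  expect_length(g, 141)
  expect_equal(range(g), c(210, 350))
  expect_true(all(abs(diff(g) - 1) < 1e-12))
  expect_error(wavelength_grid(350, 210), "invalid")
  expect_error(wavelength_grid(210, 350, 0), "invalid")
  expect_error(wavelength_grid(210, 211.5, 1), "integer multiple")
})

test_that("pure spectra evaluate the Gaussian band library exactly", {
  pure <- build_pure_spectra()
  expect_equal(nrow(pure), 141)
  expect_true(all(pure$CFPM >= 0) && all(pure$TAZO >= 0))

  # single band evaluated at its own center equals the peak absorptivity
  one <- build_pure_spectra(
    list(X = tibble::tibble(center_nm = 260, width_nm = 9, peak = 0.07)))
  expect_equal(one$X[one$wavelength_nm == 260], 0.07)

  # hand evaluation of the Gaussian: band (211, 8, 0.12) at 227 nm
  tz <- build_pure_spectra(
    list(TAZO = tibble::tibble(center_nm = 211, width_nm = 8, peak = 0.12)))
  expect_equal(tz$TAZO[tz$wavelength_nm == 227],
               0.12 * exp(-16^2 / (2 * 8^2)), tolerance = 1e-12)
  expect_equal(round(tz$TAZO[tz$wavelength_nm == 227], 4), 0.0162)

  expect_error(build_pure_spectra(list(A = tibble::tibble())), "at least one")
  expect_error(
    build_pure_spectra(list(A = tibble::tibble(center_nm = 1, width_nm = 0,
                                               peak = 1))),
    "widths")
})

test_that("mixtures obey Beer-Lambert additivity and linearity", {
  pure <- tiny_pure()
  E <- as.matrix(pure[, c("A", "B")])
  conc <- tibble::tibble(sample_id = c("a", "b"), A = c(5, 2), B = c(10, 3))
  quiet <- noise_model(0, seed = 1)

  zero <- simulate_mixtures(dplyr::mutate(conc, A = 0, B = 0), pure, quiet)
  expect_true(all(abs(as.matrix(zero[, -1])) == 0))

  sp <- simulate_mixtures(conc, pure, quiet)
  expect_equal(unname(as.numeric(sp[1, -1])),
               unname(drop(5 * E[, "A"] + 10 * E[, "B"])), tolerance = 1e-14)

  dbl <- simulate_mixtures(dplyr::mutate(conc, A = 2 * A, B = 2 * B),
                           pure, quiet)
  expect_equal(as.matrix(dbl[, -1]), 2 * as.matrix(sp[, -1]),
               tolerance = 1e-12, ignore_attr = TRUE)

  # mixture spectrum = sum of the single-analyte spectra
  only_a <- simulate_mixtures(dplyr::mutate(conc, B = 0), pure, quiet)
  only_b <- simulate_mixtures(dplyr::mutate(conc, A = 0), pure, quiet)
  expect_equal(as.matrix(sp[, -1]),
               as.matrix(only_a[, -1]) + as.matrix(only_b[, -1]),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(simulate_mixtures(dplyr::mutate(conc, A = -1), pure, quiet),
               "non-negative")
})

test_that("noise realizations are seeded and calibrated", {
  pure <- build_pure_spectra()
  conc <- random_conc(80, seed = 5, analytes = c("CFPM", "TAZO"))
  s1 <- simulate_mixtures(conc, pure, noise_model(0.002, seed = 7))
  s2 <- simulate_mixtures(conc, pure, noise_model(0.002, seed = 7))
  s3 <- simulate_mixtures(conc, pure, noise_model(0.002, seed = 8))
  expect_identical(s1, s2)
  expect_false(isTRUE(all.equal(s1, s3)))

  clean <- simulate_mixtures(conc, pure, noise_model(0, seed = 7))
  resid <- as.matrix(s1[, -1]) - as.matrix(clean[, -1])
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 0.002) / 0.002, 0.05)

  # baseline drift adds a bounded smooth component
  sb <- simulate_mixtures(conc, pure,
                          noise_model(0, baseline_amplitude = 0.01, seed = 1))
  base <- as.matrix(sb[, -1]) - as.matrix(clean[, -1])
  expect_lte(max(abs(base)), 0.01 + 1e-12)
})

test_that("default band library gives severe overlap and no free wavelength", {
  pure <- build_pure_spectra()
  sub <- pure$wavelength_nm >= 210 & pure$wavelength_nm <= 250
  expect_gt(cosine_sim(pure$CFPM[sub], pure$TAZO[sub]), 0.7)
  # no isoabsorptive-free channel: nowhere is one analyte on and the other off
  expect_false(any((pure$CFPM > 0) != (pure$TAZO > 0)))
})

test_that("plasma simulation applies suppression and reports true matrix factors", {
  pure <- tiny_pure()
  conc <- random_conc(6, seed = 2)
  quiet <- noise_model(0, seed = 3)

  none <- simulate_plasma_set(conc, pure, quiet,
                              matrix_effect_spec(c(A = 0, B = 0),
                                                 background_amplitude = 0))
  expect_equal(none$spectra, simulate_mixtures(conc, pure, quiet))
  expect_equal(none$mf, c(A = 1, B = 1))

  sup <- simulate_plasma_set(conc, pure, quiet,
                             matrix_effect_spec(c(A = 0.0235, B = 0.05),
                                                background_amplitude = 0))
  expect_equal(unname(sup$mf["A"]), 0.9765)
  expect_error(matrix_effect_spec(c(A = 1.0)), "\\[0, 1\\)")

  # a model trained on neat standards sees the suppressed concentrations
  cal <- random_conc(12, seed = 4)
  m <- fit_mcrals(simulate_mixtures(cal, pure, quiet), cal, rank = 2)
  pred <- predict(m, sup$spectra)
  expect_equal(pred$A / conc$A, rep(0.9765, 6), tolerance = 1e-6)
  expect_equal(pred$B / conc$B, rep(0.95, 6), tolerance = 1e-6)
})
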