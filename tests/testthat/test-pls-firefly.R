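test_that("NIPALS PLS agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(11, {
    X <- matrix(rnorm(15 * 9), 15, 9,
                dimnames = list(NULL, paste0("w", 1:9)))
    y <- drop(X %*% rnorm(9)) + rnorm(15, sd = 0.1)
    Xn <- matrix(rnorm(5 * 9), 5, 9,
                 dimnames = list(NULL, paste0("w", 1:9)))
  })
  fit <- chemocal:::nipals_pls1(X, y, 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
  ref_pred <- predict(ref, Xn)$predict[, 1, 3]
  expect_equal(unname(chemocal:::pls1_predict(fit, Xn, 3)),
               unname(ref_pred), tolerance = 1e-8)
})

test_that("full-spectrum PLS nails noiseless rank-2 data", {
  pure <- tiny_pure()
  cal <- random_conc(14, seed = 21)
  spc <- simulate_mixtures(cal, pure, noise_model(0, seed = 1))
  m <- fit_fapls(spc, cal, max_k = 4, select = FALSE)
  expect_equal(m$models$A$k, 2)
  expect_equal(m$models$B$k, 2)
  expect_lt(max(m$models$A$rmsec, m$models$B$rmsec), 1e-8)
})

test_that("firefly selection is deterministic under a fixed seed", {
  pure <- tiny_pure()
  cal <- random_conc(12, seed = 22)
  spc <- simulate_mixtures(cal, pure, noise_model(0.002, seed = 5))
  p <- firefly_params(population = 6, generations = 4, seed = 99)
  a <- firefly_select_wavelengths(spc, cal, "A", p)
  b <- firefly_select_wavelengths(spc, cal, "A", p)
  expect_identical(a$mask, b$mask)
  expect_identical(a$history, b$history)
  c2 <- firefly_select_wavelengths(spc, cal, "A",
                                   firefly_params(population = 6,
                                                  generations = 4, seed = 100))
  expect_false(identical(a$history, c2$history))
})

test_that("best-so-far swarm fitness never increases", {
  pure <- tiny_pure()
  cal <- random_conc(12, seed = 23)
  spc <- simulate_mixtures(cal, pure, noise_model(0.003, seed = 2))
  sw <- firefly_select_wavelengths(
    spc, cal, "B", firefly_params(population = 8, generations = 10, seed = 4))
  expect_true(all(diff(sw$history$best_fitness) <= 1e-12))
  expect_gte(sum(sw$mask), 4)   # min_wavelengths repair respected
})

test_that("the swarm keeps informative wavelengths and beats full spectrum", {
  # only channels 10..20 of 40 carry signal, the rest is pure noise
  n <- 16; p <- 40
  withr::with_seed(31, {
    conc <- random_conc(n, seed = 31, analytes = "A")
    X <- matrix(rnorm(n * p, sd = 0.05), n, p)
    shape <- exp(-((10:20) - 15)^2 / 8)
    X[, 10:20] <- X[, 10:20] + outer(conc$A, 0.1 * shape)
  })
  spc <- chemocal:::matrix_to_spectra(X, wavelength_grid(210, 249, 1),
                                      conc$sample_id)
  sw <- firefly_select_wavelengths(
    spc, conc, "A",
    firefly_params(population = 12, generations = 15, seed = 6))
  expect_gt(sum(which(sw$mask) %in% 10:20), 0)
  full_rmsecv <- chemocal:::pls_cv_rmse(X, conc$A, rep(TRUE, p),
                                        sw$fold_id, 2)
  expect_lte(sw$fitness, full_rmsecv + 1e-12)
})

test_that("with alpha = 0 a preset optimal firefly pins the exhaustive optimum", {
  # 8 wavelengths: enumerate all 255 masks as the brute-force oracle
  n <- 12; p <- 8
  withr::with_seed(41, {
    conc <- random_conc(n, seed = 41, analytes = "A")
    X <- matrix(rnorm(n * p, sd = 0.2), n, p)
    X[, 3] <- X[, 3] + 0.15 * conc$A
    X[, 6] <- X[, 6] + 0.08 * conc$A
  })
  params <- firefly_params(population = 6, generations = 5, alpha = 0,
                           seed = 13, min_wavelengths = 1)
  probe <- chemocal:::ff_search(X, conc$A, params, inner_folds = 4,
                                inner_k = 2)
  masks <- lapply(1:255, function(i) as.logical(intToBits(i)[1:p]))
  fits <- vapply(masks, function(m) {
    chemocal:::pls_cv_rmse(X, conc$A, m, probe$fold_id, 2)
  }, numeric(1))
  best_mask <- masks[[which.min(fits)]]
  init <- matrix(runif(6 * p), 6, p)
  init[1, ] <- ifelse(best_mask, 0.9, 0.1)
  seeded <- chemocal:::ff_search(X, conc$A, params, inner_folds = 4,
                                 inner_k = 2, init_positions = init)
  expect_equal(seeded$fitness, min(fits), tolerance = 1e-12)
  expect_identical(seeded$mask, best_mask)
})

test_that("firefly-PLS on noisy spectra selects a strict wavelength subset", {
  pure <- build_pure_spectra()
  cal <- study_designs$cal
  spc <- simulate_mixtures(cal, pure, noise_model(0.002, seed = 9))
  m <- fit_fapls(spc, cal,
                 params = firefly_params(population = 10, generations = 10,
                                         seed = 2),
                 max_k = 4)
  for (a in m$analytes) {
    expect_lt(sum(m$models[[a]]$mask), 141)
    expect_gte(sum(m$models[[a]]$mask), 4)
  }
  # reloadable prediction path stays consistent
  vs <- simulate_mixtures(study_designs$val, pure, noise_model(0.002, seed = 10))
  pv <- predict(m, vs)
  expect_equal(dim(pv), c(13, 3))
  expect_lt(max(abs(pv$CFPM - study_designs$val$CFPM)), 0.2)
})
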