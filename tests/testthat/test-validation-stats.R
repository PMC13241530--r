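test_that("error metrics reproduce hand-computed oracles", {
  perfect <- compute_metrics(tibble::tibble(y = 1:3, y_hat = 1:3))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$bias, 0)
  expect_equal(perfect$sec, 0)

  off <- compute_metrics(tibble::tibble(y = 1:3, y_hat = 2:4))
  expect_equal(off$rmse, 1)
  expect_equal(off$bias, -1)
  expect_equal(off$sec, 0)
  expect_equal(off$bcrmsep, 0)

  mix <- compute_metrics(tibble::tibble(y = c(1, 2, 3), y_hat = c(1, 2, 4)))
  expect_equal(mix$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(mix$bias, -1 / 3, tolerance = 1e-12)
  expect_equal(mix$sec, sqrt(((1 / 3)^2 + (1 / 3)^2 + (2 / 3)^2) / 2),
               tolerance = 1e-12)

  expect_error(compute_metrics(tibble::tibble(y = 1, y_hat = 1)), "at least 2")
})

test_that("metric identities hold on random prediction sets", {
  withr::with_seed(77, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      d <- tibble::tibble(y = runif(n, 1, 20),
                          y_hat = runif(n, 1, 20))
      m <- compute_metrics(d)
      # RMSE^2 = bias^2 + ((n-1)/n) SEC^2
      expect_equal(m$rmse^2, m$bias^2 + (n - 1) / n * m$sec^2,
                   tolerance = 1e-9)
      expect_gte(m$rmse, abs(m$bias))
      # the typeset relative error equals the standard one over sqrt(n)
      expect_equal(m$rrmsep_printed, m$rrmsep_standard / sqrt(n),
                   tolerance = 1e-9)
    }
  })
})

test_that("NAS figures of merit follow the orthogonal-projection definition", {
  wl <- wavelength_grid(210, 219, 1)
  orth <- tibble::tibble(wavelength_nm = wl,
                         A = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),
                         B = c(0, 0, 2, 1, 0, 0, 0, 0, 0, 0))
  f <- nas_figures_of_merit(orth, "A", noise_sd = 0.01)
  expect_equal(f$nas[[1]], orth$A, tolerance = 1e-12)
  expect_equal(f$sen, sqrt(2), tolerance = 1e-12)

  # noiseless limit and the fixed 3.3/10 convention
  f0 <- nas_figures_of_merit(orth, "A", noise_sd = 0)
  expect_equal(f0$lod, 0)
  expect_equal(f0$loq, 0)
  withr::with_seed(5, {
    for (i in 1:5) {
      d <- runif(1, 1e-4, 1e-2)
      fx <- nas_figures_of_merit(orth, "B", noise_sd = d)
      expect_equal(fx$loq / fx$lod, 10 / 3.3, tolerance = 1e-12)
    }
  })

  coll <- tibble::tibble(wavelength_nm = wl, A = seq_len(10) / 10,
                         B = 2 * seq_len(10) / 10)
  expect_error(nas_figures_of_merit(coll, "A", 0.01), "no net analyte signal")
})

test_that("recovery t-test matches tabulated critical values", {
  t0 <- recovery_ttest(rep(100, 6))
  expect_equal(t0$t, 0)

  tt <- recovery_ttest(rnorm(13, 100, 1))
  expect_equal(tt$df, 12)
  expect_equal(round(tt$crit_0.025, 3), 2.179)
  expect_equal(round(tt$crit_0.01, 3), 2.681)

  degen <- recovery_ttest(rep(99, 5))
  expect_true(is.infinite(degen$t))
})

test_that("t-test type-I error sits near its nominal level", {
  withr::with_seed(123, {
    rejections <- vapply(seq_len(10000), function(i) {
      r <- rnorm(13, mean = 100, sd = 2)
      recovery_ttest(r)$t > 2.179
    }, logical(1))
  })
  expect_equal(mean(rejections), 0.05, tolerance = 0.15)  # 5% +/- 0.75 points
})

test_that("one-way ANOVA reproduces the classical decomposition", {
  same <- oneway_anova(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(same$f, 0)

  h <- oneway_anova(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(3, 4, 5)))
  expect_equal(h$f, 3, tolerance = 1e-12)      # between MS 3 / within MS 1
  expect_equal(h$df_between, 2)
  expect_equal(h$df_within, 6)

  shifted <- oneway_anova(list(g1 = c(1, 2, 3) + 7, g2 = c(2, 3, 4) + 7,
                               g3 = c(3, 4, 5) + 7))
  expect_equal(shifted$f, h$f, tolerance = 1e-9)

  df <- tibble::tibble(value = c(1, 2, 2, 3), group = c("a", "a", "b", "b"))
  expect_equal(oneway_anova(df)$df_within, 2)
  expect_error(oneway_anova(list(a = 1, b = c(1, 2))), ">= 2")
})

test_that("EJCR geometry and ideal-point membership behave as defined", {
  y <- seq(1, 13)
  perfect <- ejcr(tibble::tibble(y = y, y_hat = y))
  expect_true(perfect$contains_ideal)
  expect_true(perfect$zero_area)
  expect_equal(perfect$slope, 1, tolerance = 1e-10)
  expect_equal(perfect$intercept, 0, tolerance = 1e-10)

  withr::with_seed(9, e <- rnorm(13, sd = 0.05))
  offset <- ejcr(tibble::tibble(y = y, y_hat = y + 10 + e))
  expect_false(offset$contains_ideal)

  noisy1 <- ejcr(tibble::tibble(y = y, y_hat = y + e))
  noisy2 <- ejcr(tibble::tibble(y = y, y_hat = y + e / 2))
  expect_lt(noisy2$area, noisy1$area)
  expect_true(noisy1$contains_ideal)

  # the boundary outline satisfies the defining quadratic form
  ol <- ejcr_outline(noisy1, 50)
  q <- apply(as.matrix(ol), 1, function(b) {
    d <- b - c(noisy1$intercept, noisy1$slope)
    drop(t(d) %*% noisy1$xtx %*% d)
  })
  expect_equal(q, rep(2 * noisy1$s2 * noisy1$f_crit, 50), tolerance = 1e-8)

  expect_error(ejcr(tibble::tibble(y = rep(2, 5), y_hat = rnorm(5))),
               "degenerate")
})

test_that("matrix factors convert to matrix-effect percentages exactly", {
  d <- tibble::tibble(analyte = c("CFPM", "TAZO"), level = c(5, 5),
                      neat = c(5, 5), plasma = c(5, 5))
  eq <- matrix_effect(d)
  expect_equal(eq$mf, c(1, 1))
  expect_equal(eq$me_percent, c(0, 0))

  d2 <- tibble::tibble(analyte = "x", level = 1, neat = 1,
                       plasma = c(0.9765, 0.9873))
  me <- matrix_effect(d2)
  expect_equal(round(me$me_percent, 2), c(-2.35, -1.27))

  expect_error(matrix_effect(tibble::tibble(neat = 0, plasma = 1)),
               "undefined")
})
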