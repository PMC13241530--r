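test_that("Brereton generator populates the five-level grid", {
  cal <- study_designs$cal
  expect_equal(nrow(cal), 25)
  expect_setequal(unique(cal$CFPM), c(1, 5, 9, 13, 17))
  expect_setequal(unique(cal$TAZO), c(1, 3, 5, 7, 9))
  # level 0 sits at the domain centers
  expect_equal(sort(unique(cal$CFPM))[3], 9)
  expect_equal(sort(unique(cal$TAZO))[3], 5)
  # full factorial: every combination appears exactly once
  expect_equal(nrow(dplyr::distinct(cal[, c("CFPM", "TAZO")])), 25)

  expect_error(generate_brereton(levels = 4), "odd")
  g3 <- generate_brereton(conc_domain(CFPM = c(1, 9), TAZO = c(1, 9)),
                          levels = 3)
  expect_equal(nrow(g3), 9)
  expect_equal(range(g3$CFPM), c(1, 9))
  expect_equal(range(g3$TAZO), c(1, 9))
})

test_that("candidate enumeration counts lattice points and excludes calibration", {
  full <- enumerate_candidates(conc_domain(), step = 1)
  expect_equal(nrow(full), 17 * 9)
  expect_equal(nrow(study_designs$candidates), 153 - 25)
  # disjointness is structural
  key <- function(df) paste(df$CFPM, df$TAZO)
  expect_length(intersect(key(study_designs$candidates),
                          key(study_designs$cal)), 0)
  expect_warning(enumerate_candidates(conc_domain(), step = 100),
                 "degenerate")
  # excluding the entire lattice empties the pool
  all9 <- enumerate_candidates(conc_domain(CFPM = c(1, 3), TAZO = c(1, 3)))
  expect_error(enumerate_candidates(conc_domain(CFPM = c(1, 3),
                                                TAZO = c(1, 3)),
                                    exclude = all9),
               "empty")
})

test_that("Fedorov exchange matches exhaustive search on small candidate sets", {
  # 4 corners + center + interior point of the unit square, linear model
  toy <- tibble::tibble(x1 = c(0, 0, 1, 1, 0.5, 0.3),
                        x2 = c(0, 1, 0, 1, 0.5, 0.7))
  det_of <- function(idx) {
    X <- chemocal:::design_model_matrix(toy[idx, ], "linear", scale_from = toy)
    det(crossprod(X))
  }
  best_exhaustive <- max(apply(combn(6, 3), 2, det_of))
  fed <- fedorov_select(toy, 3, model = "linear", seed = 1, restarts = 5)
  expect_equal(fed$det, best_exhaustive, tolerance = 1e-9)

  # random small pools: the exchange attains the exhaustive optimum
  hits <- vapply(1:12, function(s) {
    pool <- random_conc(10, seed = 200 + s, analytes = c("x1", "x2"),
                        lo = 0, hi = 1)[, -1]
    opt <- max(apply(combn(10, 4), 2, function(idx) {
      X <- chemocal:::design_model_matrix(pool[idx, ], "linear",
                                          scale_from = pool)
      det(crossprod(X))
    }))
    fs <- fedorov_select(pool, 4, model = "linear", seed = s, restarts = 5)
    abs(fs$det - opt) < 1e-9 * max(opt, 1)
  }, logical(1))
  expect_true(all(hits))
})

test_that("Fedorov selection is monotone, disjoint and scale invariant", {
  fed <- study_designs$fedorov
  expect_equal(nrow(fed$points), 13)
  # determinant history never decreases within a restart
  by_restart <- split(fed$trace$det, fed$trace$restart)
  for (d in by_restart) expect_true(all(diff(d) >= -1e-9 * abs(d[-1])))
  # validation points never collide with the calibration set
  key <- function(df) paste(df$CFPM, df$TAZO)
  expect_length(intersect(key(fed$points), key(study_designs$cal)), 0)

  # selecting everything leaves nothing to exchange
  small <- study_designs$candidates[1:8, ]
  all_sel <- fedorov_select(small, 8, model = "linear", seed = 1, restarts = 2)
  Xall <- chemocal:::design_model_matrix(small, "linear", scale_from = small)
  expect_equal(all_sel$det, det(crossprod(Xall)), tolerance = 1e-9)
  expect_equal(nrow(all_sel$trace), 0)

  # affine rescaling of the domain leaves the selected points unchanged
  scaled <- dplyr::mutate(study_designs$candidates,
                          CFPM = 10 * CFPM + 3, TAZO = 0.5 * TAZO - 0.1)
  fed2 <- fedorov_select(scaled, 13, seed = 42, restarts = 10)
  orig_idx <- match(paste(fed$points$CFPM, fed$points$TAZO),
                    paste(study_designs$candidates$CFPM,
                          study_designs$candidates$TAZO))
  new_idx <- match(paste(fed2$points$CFPM, fed2$points$TAZO),
                   paste(scaled$CFPM, scaled$TAZO))
  expect_setequal(orig_idx, new_idx)

  expect_error(fedorov_select(study_designs$candidates, 4), "model terms")
  expect_error(fedorov_select(small, 20, model = "linear"), "pool")
})

test_that("leverage diagnostics satisfy the trace identity", {
  lv <- leverage_diagnostics(study_designs$val)
  expect_equal(sum(lv$.leverage), 6, tolerance = 1e-9)   # quadratic: 6 terms
  lv_lin <- leverage_diagnostics(study_designs$val, model = "linear")
  expect_equal(sum(lv_lin$.leverage), 3, tolerance = 1e-9)
  expect_true(is.finite(attr(lv, "max_pairwise_distance")))

  # a saturated design has unit leverage everywhere
  corners <- tibble::tibble(x1 = c(0, 0, 1), x2 = c(0, 1, 0))
  expect_equal(leverage_diagnostics(corners, "linear")$.leverage,
               rep(1, 3), tolerance = 1e-9)

  # duplicated points share the same leverage
  dup <- tibble::tibble(x1 = c(0, 0, 1, 0.5), x2 = c(0, 0, 1, 0.2))
  h <- leverage_diagnostics(dup, "linear")$.leverage
  expect_equal(h[1], h[2], tolerance = 1e-12)

  one_pt <- tibble::tibble(x1 = rep(1, 4), x2 = rep(1, 4))
  expect_error(leverage_diagnostics(one_pt, "linear"), "singular")
})
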