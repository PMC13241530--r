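#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end workflow with the study defaults:
#' 5-level Brereton calibration over CFPM 1--17 / TAZO 1--9 ug/mL (25
#' mixtures), a 13-point D-optimal validation set on a 1 ug/mL candidate
#' lattice under a quadratic information model, photometric noise of
#' 0.002 AU, and per-analyte firefly parameters (population 25, 100
#' generations, beta0 = 1, alpha/gamma = 0.25/0.9 for CFPM and 0.20/0.8 for
#' TAZO). Every stochastic stage draws its seed from `seed` by a fixed
#' offset, so a run is fully reproducible from the config alone.
#'
#' @param seed Master integer seed.
#' @param domain [conc_domain()] of working ranges.
#' @param levels Brereton levels per factor.
#' @param n_validation Validation-set size for the Fedorov exchange.
#' @param candidate_step Candidate lattice step (ug/mL).
#' @param fedorov_model,fedorov_restarts Information model and restarts of
#'   [fedorov_select()].
#' @param band_library,grid Pure-spectra parameters for the simulator.
#' @param noise_sd,baseline_amplitude Photometric noise model (AU).
#' @param firefly Named list of [firefly_params()] per analyte (seeds are
#'   overridden from `seed`); or a single [firefly_params()] reused.
#' @param inner_folds,inner_k Swarm fitness cross-validation settings.
#' @param pcr_max_k,pcr_scale PCR settings (mean-centering only by default;
#'   see [fit_pcr()] on autoscaling).
#' @param pls_max_k Largest PLS latent-variable count examined.
#' @param mcr_max_iter,mcr_lof_tol MCR-ALS convergence controls.
#' @param select_wavelengths `FALSE` skips the firefly swarm (full-spectrum
#'   PLS), useful for quick runs.
#' @param plasma_conc Concentration tibble of the plasma spike levels
#'   (`NULL` disables the matrix-effect stage).
#' @param matrix_effect [matrix_effect_spec()] used for the plasma stage.
#' @param alpha Significance level for EJCR and ANOVA.
#' @param cf_inventory Inventory list for [carbon_footprint()].
#' @param score_panel Optional sub-score vector for [aggregate_scores()].
#' @return List of class `chemo_config`.
#' @export
chemo_config <- function(seed = 20260605,
                         domain = conc_domain(),
                         levels = 5,
                         n_validation = 13,
                         candidate_step = 1,
                         fedorov_model = "quadratic",
                         fedorov_restarts = 20,
                         band_library = default_band_library(),
                         grid = wavelength_grid(),
                         noise_sd = 0.002,
                         baseline_amplitude = 0,
                         firefly = list(
                           CFPM = firefly_params(alpha = 0.25, gamma = 0.9),
                           TAZO = firefly_params(alpha = 0.20, gamma = 0.8)
                         ),
                         inner_folds = 5,
                         inner_k = 2,
                         pcr_max_k = 8,
                         pcr_scale = FALSE,
                         pls_max_k = 6,
                         mcr_max_iter = 50,
                         mcr_lof_tol = 1e-3,
                         select_wavelengths = TRUE,
                         plasma_conc = tibble::tibble(
                           sample_id = c("P1", "P2", "P3"),
                           CFPM = c(5, 10, 15),
                           TAZO = c(3, 5, 7)
                         ),
                         matrix_effect = matrix_effect_spec(),
                         alpha = 0.05,
                         cf_inventory = example_cf_inventory(),
                         score_panel = NULL) {
  seed <- as.integer(seed)
  analytes <- names(domain)
  if (inherits(firefly, "chemo_firefly_params")) {
    firefly <- setNames(rep(list(firefly), length(analytes)), analytes)
  }
  for (i in seq_along(analytes)) {
    firefly[[analytes[i]]]$seed <- seed + 3L + i
  }
  structure(
    list(seed = seed, domain = domain, levels = levels,
         n_validation = n_validation, candidate_step = candidate_step,
         fedorov_model = fedorov_model, fedorov_restarts = fedorov_restarts,
         band_library = band_library, grid = grid,
         noise_sd = noise_sd, baseline_amplitude = baseline_amplitude,
         firefly = firefly, inner_folds = inner_folds, inner_k = inner_k,
         pcr_max_k = pcr_max_k, pcr_scale = pcr_scale,
         pls_max_k = pls_max_k,
         mcr_max_iter = mcr_max_iter, mcr_lof_tol = mcr_lof_tol,
         select_wavelengths = select_wavelengths,
         plasma_conc = plasma_conc, matrix_effect = matrix_effect,
         alpha = alpha, cf_inventory = cf_inventory,
         score_panel = score_panel,
         seeds = list(design = seed + 1L, cal_noise = seed + 2L,
                      val_noise = seed + 3L,
                      neat_noise = seed + 10L, plasma_noise = seed + 11L)),
    class = "chemo_config"
  )
}

# RMS of the spectral reconstruction residual of a fitted model on its
# calibration spectra; the default delta_r for NAS detection limits
spectral_residual_rms <- function(model, spectra) {
  X <- spectra_to_matrix(spectra)
  if (inherits(model, "chemo_pcr")) {
    Z <- apply_preprocessor(model$preproc, X)
    Zh <- (Z %*% model$loadings) %*% t(model$loadings)
    sqrt(mean((X - invert_preprocessor(model$preproc, Zh))^2))
  } else if (inherits(model, "chemo_pls")) {
    res <- vapply(model$analytes, function(a) {
      m <- model$models[[a]]
      if (is.null(m$fit$W)) return(NA_real_)
      Xm <- X[, m$mask, drop = FALSE]
      Xc <- sweep(Xm, 2, m$fit$xbar)
      R <- m$fit$W %*% solve(crossprod(m$fit$P, m$fit$W))
      Tt <- Xc %*% R[, seq_len(m$k), drop = FALSE]
      mean((Xc - Tt %*% t(m$fit$P[, seq_len(m$k), drop = FALSE]))^2)
    }, numeric(1))
    sqrt(mean(res, na.rm = TRUE))
  } else if (inherits(model, "chemo_mcr")) {
    Cn <- if (model$constraints$nonneg_C) nnls_rows(model$S, X) else
      t(solve(crossprod(model$S), crossprod(model$S, t(X))))
    sqrt(mean((X - Cn %*% t(model$S))^2))
  } else {
    stop("unsupported model class", call. = FALSE)
  }
}

# component spectra used for NAS: resolved spectra for MCR, classical
# least-squares estimates from the known calibration concentrations otherwise
nas_component_spectra <- function(model, cal_spectra, cal_conc) {
  if (inherits(model, "chemo_mcr")) {
    S <- model$S[, model$assignment, drop = FALSE]
    colnames(S) <- model$analytes
    dplyr::bind_cols(tibble::tibble(wavelength_nm = model$wavelength),
                     tibble::as_tibble(S))
  } else {
    X <- spectra_to_matrix(cal_spectra)
    Y <- conc_to_matrix(cal_conc)
    S <- t(solve(crossprod(Y), crossprod(Y, X)))
    colnames(S) <- colnames(Y)
    dplyr::bind_cols(tibble::tibble(wavelength_nm = attr(X, "wavelength")),
                     tibble::as_tibble(S))
  }
}

#' Validate a fitted model on an external set
#'
#' Predicts the validation spectra and assembles the full per-analyte
#' statistics: error metrics ([compute_metrics()]), recovery t-test against
#' 100%, EJCR of predicted-vs-reference, and NAS detection limits with
#' `delta_r` defaulting to the model's spectral reconstruction RMS on the
#' calibration data.
#'
#' @param model A fitted `chemo_pcr`, `chemo_pls` or `chemo_mcr`.
#' @param val_spectra,val_conc External validation set.
#' @param cal_spectra,cal_conc Calibration set (for `delta_r` and the NAS
#'   component spectra).
#' @param alpha Significance level for the EJCR.
#' @param noise_sd Optional override of `delta_r` (AU).
#' @return List of class `chemo_validation`: `metrics` (per-analyte tibble
#'   incl. calibration RMSEC), `ttest`, `nas`, `ejcr` (named list),
#'   `predictions`, `recoveries`.
#' @export
validate_model <- function(model, val_spectra, val_conc,
                           cal_spectra, cal_conc,
                           alpha = 0.05, noise_sd = NULL) {
  pred <- predict(model, val_spectra)
  pred_cal <- predict(model, cal_spectra)
  analytes <- setdiff(names(val_conc), "sample_id")
  dr <- noise_sd %||% spectral_residual_rms(model, cal_spectra)
  pure_est <- nas_component_spectra(model, cal_spectra, cal_conc)

  metrics <- purrr::map_dfr(analytes, function(a) {
    ps <- tibble::tibble(y = val_conc[[a]], y_hat = pred[[a]])
    cal_e <- cal_conc[[a]] - pred_cal[[a]]
    dplyr::mutate(compute_metrics(ps),
                  analyte = a,
                  rmsec = sqrt(mean(cal_e^2)),
                  .before = 1)
  })
  ttest <- purrr::map_dfr(analytes, function(a) {
    rec <- pred[[a]] / val_conc[[a]] * 100
    dplyr::mutate(recovery_ttest(rec), analyte = a, .before = 1)
  })
  nas <- purrr::map_dfr(analytes,
                        function(a) nas_figures_of_merit(pure_est, a, dr))
  ej <- purrr::map(setNames(analytes, analytes), function(a) {
    ejcr(tibble::tibble(y = val_conc[[a]], y_hat = pred[[a]]), alpha = alpha)
  })
  recov <- purrr::map(setNames(analytes, analytes), function(a) {
    pred[[a]] / val_conc[[a]] * 100
  })
  structure(list(metrics = metrics, ttest = ttest, nas = nas, ejcr = ej,
                 predictions = pred, recoveries = recov,
                 delta_r = dr, alpha = alpha),
            class = "chemo_validation")
}

#' @export
print.chemo_validation <- function(x, ...) {
  cat("Validation report\n")
  print(dplyr::select(x$metrics, dplyr::any_of(c(
    "analyte", "rmsec", "rmse", "bias", "sec",
    "rrmsep_standard", "mean_recovery"))))
  invisible(x)
}

#' Run the full calibration pipeline
#'
#' End-to-end workflow on synthetic spectra: build the pure-component
#' library, generate the Brereton calibration design and the Fedorov
#' D-optimal validation design, simulate both spectra sets, fit PCR,
#' firefly-optimized PLS and MCR-ALS (rank from EFA), validate each model on
#' the external set, compare them (RMSEP ranking, one-way ANOVA of
#' recoveries), run the plasma matrix-effect study with the MCR model, and
#' evaluate the sustainability calculators. Deterministic given the config.
#'
#' @param config A [chemo_config()].
#' @param out_dir Optional directory; when given, designs, spectra, model
#'   archives and JSON reports are written there.
#' @return List of class `chemo_run`; see components in the examples.
#' @export
run_pipeline <- function(config = chemo_config(), out_dir = NULL) {
  stopifnot(inherits(config, "chemo_config"))
  pure <- build_pure_spectra(config$band_library, config$grid)
  cal_design <- generate_brereton(config$domain, config$levels)
  candidates <- enumerate_candidates(config$domain, config$candidate_step,
                                     exclude = cal_design)
  fed <- fedorov_select(candidates, config$n_validation,
                        model = config$fedorov_model,
                        seed = config$seeds$design,
                        restarts = config$fedorov_restarts)
  val_design <- fed$points

  cal_spectra <- simulate_mixtures(
    cal_design, pure,
    noise_model(config$noise_sd, config$baseline_amplitude,
                seed = config$seeds$cal_noise))
  val_spectra <- simulate_mixtures(
    val_design, pure,
    noise_model(config$noise_sd, config$baseline_amplitude,
                seed = config$seeds$val_noise))

  models <- list(
    PCR = fit_pcr(cal_spectra, cal_design, max_k = config$pcr_max_k,
                  scale = config$pcr_scale),
    `FA-PLS` = fit_fapls(cal_spectra, cal_design, params = config$firefly,
                         max_k = config$pls_max_k,
                         inner_folds = config$inner_folds,
                         inner_k = config$inner_k,
                         select = config$select_wavelengths)
  )
  efa <- efa_rank(cal_spectra, noise_sd = config$noise_sd)
  models$`MCR-ALS` <- fit_mcrals(cal_spectra, cal_design, rank = efa$rank,
                                 max_iter = config$mcr_max_iter,
                                 lof_tol = config$mcr_lof_tol)

  validation <- purrr::imap(models, function(m, nm) {
    validate_model(m, val_spectra, val_design, cal_spectra, cal_design,
                   alpha = config$alpha)
  })

  comparison <- purrr::imap_dfr(validation, function(v, nm) {
    dplyr::mutate(v$metrics, model = nm, .before = 1)
  })
  ranking <- comparison |>
    dplyr::summarise(rmsep = mean(.data$rmse), .by = "model") |>
    dplyr::arrange(.data$rmsep)
  anova_tab <- purrr::map_dfr(
    setdiff(names(val_design), "sample_id"),
    function(a) {
      groups <- purrr::map(validation, function(v) v$recoveries[[a]])
      dplyr::mutate(oneway_anova(groups, alpha = config$alpha),
                    analyte = a, .before = 1)
    })

  plasma <- NULL
  if (!is.null(config$plasma_conc)) {
    neat_sp <- simulate_mixtures(
      config$plasma_conc, pure,
      noise_model(config$noise_sd, config$baseline_amplitude,
                  seed = config$seeds$neat_noise))
    plas <- simulate_plasma_set(
      config$plasma_conc, pure,
      noise_model(config$noise_sd, config$baseline_amplitude,
                  seed = config$seeds$plasma_noise),
      matrix_effect = config$matrix_effect)
    best <- models$`MCR-ALS`
    pn <- predict(best, neat_sp)
    pp <- predict(best, plas$spectra)
    analytes <- setdiff(names(config$plasma_conc), "sample_id")
    tab <- purrr::map_dfr(analytes, function(a) {
      tibble::tibble(analyte = a, level = config$plasma_conc[[a]],
                     neat = pn[[a]], plasma = pp[[a]])
    })
    plasma <- list(table = matrix_effect(tab), true_mf = plas$mf)
  }

  sustain <- list(
    carbon_footprint = carbon_footprint(config$cf_inventory$energy,
                                        config$cf_inventory$ef_elec,
                                        config$cf_inventory$consumables),
    whiteness = if (!is.null(config$score_panel)) {
      aggregate_scores(config$score_panel)
    } else NULL
  )

  run <- structure(
    list(config = config, config_hash = rlang::hash(config),
         pure = pure, cal_design = cal_design, val_design = val_design,
         fedorov = fed, efa = efa,
         cal_spectra = cal_spectra, val_spectra = val_spectra,
         models = models, validation = validation,
         comparison = comparison, ranking = ranking, anova = anova_tab,
         plasma = plasma, sustainability = sustain),
    class = "chemo_run"
  )
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(seed = run$config$seed, config_hash = run$config_hash)
  write_conc_csv(run$cal_design, file.path(out_dir, "calibration_design.csv"))
  write_conc_csv(run$val_design, file.path(out_dir, "validation_design.csv"))
  write_spectra_csv(run$cal_spectra, file.path(out_dir, "calibration_spectra.csv"))
  write_spectra_csv(run$val_spectra, file.path(out_dir, "validation_spectra.csv"))
  for (nm in names(run$models)) {
    write_model(run$models[[nm]],
                file.path(out_dir, paste0("model_", gsub("\\W", "", nm))))
  }
  jsonlite::write_json(
    c(prov, list(
      fedorov = list(det = run$fedorov$det, trace = run$fedorov$trace),
      efa_rank = run$efa$rank,
      comparison = run$comparison,
      ranking = run$ranking,
      anova = run$anova,
      plasma = if (!is.null(run$plasma)) run$plasma$table else NULL,
      sustainability = run$sustainability[
        !vapply(run$sustainability, is.null, logical(1))]
    )),
    file.path(out_dir, "comparison.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  log_lines <- c(
    sprintf("chemocal pipeline run  seed=%d  hash=%s", run$config$seed,
            run$config_hash),
    sprintf("calibration mixtures: %d  validation mixtures: %d",
            nrow(run$cal_design), nrow(run$val_design)),
    sprintf("fedorov det(X'X) = %.6g", run$fedorov$det),
    sprintf("EFA rank = %d", run$efa$rank),
    sprintf("model ranking by mean RMSEP: %s",
            paste(run$ranking$model, collapse = " < "))
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.chemo_run <- function(x, ...) {
  cat("chemocal pipeline run (seed", x$config$seed, ")\n")
  cat("  calibration:", nrow(x$cal_design), "mixtures;  validation:",
      nrow(x$val_design), "mixtures;  EFA rank:", x$efa$rank, "\n\n")
  print(dplyr::select(x$comparison, dplyr::any_of(c(
    "model", "analyte", "rmsec", "rmse", "rrmsep_standard",
    "mean_recovery"))), n = Inf)
  cat("\nRanking by mean RMSEP:",
      paste(x$ranking$model, collapse = " < "), "\n")
  invisible(x)
}

#' Comparison table of a pipeline run
#'
#' @param x A `chemo_run`.
#' @param ... Unused.
#' @return The per-model, per-analyte metrics tibble.
#' @exportS3Method
tidy.chemo_run <- function(x, ...) {
  x$comparison
}

#' @exportS3Method
glance.chemo_run <- function(x, ...) {
  tibble::tibble(
    seed = x$config$seed, n_calibration = nrow(x$cal_design),
    n_validation = nrow(x$val_design), efa_rank = x$efa$rank,
    best_model = x$ranking$model[1],
    max_rrmsep = max(x$comparison$rrmsep_standard),
    carbon_footprint = x$sustainability$carbon_footprint
  )
}
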