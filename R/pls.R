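# NIPALS PLS1 with deflation.  Returns mean vectors and the regression
# coefficient vector for every latent-variable count 1..k, so cross-validation
# over k needs a single decomposition per fold.

nipals_pls1 <- function(X, y, k) {
  n <- nrow(X); p <- ncol(X)
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar); yc <- y - ybar
  k <- min(k, n - 1L, p)
  W <- matrix(0, p, k); P <- matrix(0, p, k); q <- numeric(k)
  used <- 0L
  for (a in seq_len(k)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break
    w <- w / nw
    tt <- Xc %*% w
    t2 <- sum(tt^2)
    if (t2 < 1e-28) break
    pv <- crossprod(Xc, tt) / t2
    qa <- sum(yc * tt) / t2
    Xc <- Xc - tt %*% t(pv)
    yc <- yc - qa * tt
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
    used <- a
  }
  coefs <- vector("list", max(used, 1L))
  for (a in seq_len(used)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    coefs[[a]] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
  }
  if (used == 0L) coefs[[1]] <- matrix(0, p, 1)
  list(xbar = xbar, ybar = ybar, coefs = coefs, k_max = max(used, 1L),
       W = W[, seq_len(max(used, 1L)), drop = FALSE],
       P = P[, seq_len(max(used, 1L)), drop = FALSE])
}

pls1_predict <- function(fit, Xnew, k) {
  k <- min(k, fit$k_max)
  drop(fit$ybar + sweep(Xnew, 2, fit$xbar) %*% fit$coefs[[k]])
}

# k-fold RMSECV of PLS1 restricted to the masked wavelengths
pls_cv_rmse <- function(X, y, mask, fold_id, k) {
  Xm <- X[, mask, drop = FALSE]
  press <- 0
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    kf <- min(k, sum(tr) - 1L, ncol(Xm))
    fit <- nipals_pls1(Xm[tr, , drop = FALSE], y[tr], kf)
    press <- press + sum((y[!tr] - pls1_predict(fit, Xm[!tr, , drop = FALSE], kf))^2)
  }
  sqrt(press / length(y))
}

#' Firefly swarm parameters
#'
#' Control parameters of the firefly wavelength-selection metaheuristic:
#' population size, generation count, randomization coefficient `alpha`,
#' initial attractiveness `beta0` and light-absorption coefficient `gamma`.
#' Defaults follow the tuned values for this problem: 25 fireflies over 100
#' generations, `beta0 = 1`; `alpha`/`gamma` are set per analyte by the
#' pipeline (0.25/0.9 for CFPM, 0.20/0.8 for TAZO).
#'
#' @param population Number of fireflies (>= 2).
#' @param generations Number of generations.
#' @param alpha Randomization coefficient in `[0, 1]`.
#' @param beta0 Attractiveness at zero distance (> 0).
#' @param gamma Light-absorption coefficient (> 0); applied to the
#'   mean-squared position distance so its scale is independent of the number
#'   of wavelengths.
#' @param seed Integer seed; the swarm is fully deterministic given it.
#' @param min_wavelengths Masks with fewer active variables are repaired by
#'   activating the highest-position variables.
#' @return A `chemo_firefly_params` list.
#' @export
firefly_params <- function(population = 25, generations = 100, alpha = 0.25,
                           beta0 = 1, gamma = 0.9, seed = 1L,
                           min_wavelengths = 4L) {
  stopifnot(population >= 2, generations >= 1, alpha >= 0, alpha <= 1,
            beta0 > 0, gamma > 0, min_wavelengths >= 1)
  structure(list(population = population, generations = generations,
                 alpha = alpha, beta0 = beta0, gamma = gamma,
                 seed = as.integer(seed),
                 min_wavelengths = as.integer(min_wavelengths)),
            class = "chemo_firefly_params")
}

ff_repair <- function(mask, pos, min_wavelengths) {
  if (sum(mask) < min_wavelengths) {
    mask[order(pos, decreasing = TRUE)[seq_len(min_wavelengths)]] <- TRUE
  }
  mask
}

ff_search <- function(X, y, params, inner_folds = 5, inner_k = 2,
                      init_positions = NULL) {
  n <- nrow(X); p <- ncol(X)
  pop <- params$population
  cache <- new.env(parent = emptyenv())
  fitness_of <- function(mask, fold_id) {
    key <- paste(as.integer(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- pls_cv_rmse(X, y, mask, fold_id, inner_k)
    cache[[key]] <- val
    val
  }
  withr::with_seed(params$seed, {
    fold_id <- sample(rep(seq_len(inner_folds), length.out = n))
    P <- if (is.null(init_positions)) {
      matrix(runif(pop * p), pop, p)
    } else init_positions
    masks <- lapply(seq_len(pop), function(i) {
      ff_repair(P[i, ] > 0.5, P[i, ], params$min_wavelengths)
    })
    fit <- vapply(masks, fitness_of, numeric(1), fold_id = fold_id)
    best_i <- which.min(fit)
    best <- list(mask = masks[[best_i]], fitness = fit[best_i])
    history <- numeric(params$generations + 1L)
    history[1] <- best$fitness
    for (g in seq_len(params$generations)) {
      elite <- which.min(fit)
      for (i in seq_len(pop)) {
        if (i == elite) next           # elitism: global best unmodified
        moved <- FALSE
        for (j in seq_len(pop)) {
          if (fit[j] < fit[i]) {
            r2 <- mean((P[i, ] - P[j, ])^2)
            beta <- params$beta0 * exp(-params$gamma * r2)
            P[i, ] <- P[i, ] + beta * (P[j, ] - P[i, ]) +
              params$alpha * (runif(p) - 0.5)
            P[i, ] <- pmin(pmax(P[i, ], 0), 1)
            moved <- TRUE
          }
        }
        if (moved) {
          masks[[i]] <- ff_repair(P[i, ] > 0.5, P[i, ], params$min_wavelengths)
          if (!any(masks[[i]])) {
            stop("firefly mask empty after repair", call. = FALSE)
          }
          fit[i] <- fitness_of(masks[[i]], fold_id)
        }
      }
      gi <- which.min(fit)
      if (fit[gi] < best$fitness) {
        best <- list(mask = masks[[gi]], fitness = fit[gi])
      }
      history[g + 1L] <- best$fitness
    }
    list(mask = best$mask, fitness = best$fitness,
         history = tibble::tibble(generation = 0:params$generations,
                                  best_fitness = history),
         fold_id = fold_id, n_evaluated = length(ls(cache)))
  })
}

#' Firefly wavelength selection
#'
#' Binary wavelength selection by a continuous-position firefly swarm: each
#' firefly's position in `[0, 1]^p` is thresholded at 0.5 into a wavelength
#' mask; its brightness is the (inverse) k-fold cross-validated RMSECV of a
#' PLS model restricted to the masked wavelengths. Fireflies move toward every
#' brighter one with attractiveness `beta0 * exp(-gamma * r^2)` (`r^2` the
#' mean squared position difference) plus a uniform perturbation scaled by
#' `alpha`; the global best is preserved unmodified each generation, so the
#' best-so-far fitness is non-increasing.
#'
#' @param spectra Spectra tibble.
#' @param conc Concentration tibble, row-aligned.
#' @param analyte Analyte column of `conc` to optimize for.
#' @param params A [firefly_params()].
#' @param inner_folds Folds of the inner cross-validation (default 5).
#' @param inner_k Latent variables used inside the fitness evaluation.
#' @return List of class `chemo_firefly`: logical `mask` (length = number of
#'   wavelengths), `fitness` (RMSECV of the best mask, ug/mL), `history`
#'   tibble of best-so-far fitness per generation, `params`.
#' @export
firefly_select_wavelengths <- function(spectra, conc, analyte,
                                       params = firefly_params(),
                                       inner_folds = 5, inner_k = 2) {
  check_aligned(spectra, conc)
  X <- spectra_to_matrix(spectra)
  y <- conc[[analyte]]
  if (is.null(y)) stop("no column `", analyte, "` in conc", call. = FALSE)
  res <- ff_search(X, y, params, inner_folds, inner_k)
  structure(c(res[c("mask", "fitness", "history", "fold_id")],
              list(analyte = analyte, params = params,
                   wavelength = attr(X, "wavelength"))),
            class = "chemo_firefly")
}

#' Firefly-optimized PLS calibration
#'
#' Per-analyte pipeline: a firefly swarm selects a wavelength subset
#' ([firefly_select_wavelengths()]), then a NIPALS PLS model is fitted on the
#' masked variables with the latent-variable count chosen by leave-one-out
#' RMSECV.
#'
#' @param spectra Spectra tibble.
#' @param conc Concentration tibble, row-aligned.
#' @param params A single [firefly_params()] (reused for every analyte with a
#'   per-analyte seed offset) or a named list with one element per analyte.
#' @param max_k Largest latent-variable count examined.
#' @param inner_folds,inner_k Inner-CV settings of the swarm fitness.
#' @param select Logical; `FALSE` skips the swarm and fits full-spectrum PLS.
#' @return Object of class `chemo_pls`: per-analyte submodels (mask,
#'   coefficients, `k`, `cv_curve`, swarm history) plus the wavelength grid.
#' @export
fit_fapls <- function(spectra, conc, params = firefly_params(), max_k = 6,
                      inner_folds = 5, inner_k = 2, select = TRUE) {
  check_aligned(spectra, conc)
  X <- spectra_to_matrix(spectra)
  wl <- attr(X, "wavelength")
  Y <- conc_to_matrix(conc)
  n <- nrow(X)
  analytes <- colnames(Y)
  if (inherits(params, "chemo_firefly_params")) {
    params <- setNames(lapply(seq_along(analytes), function(i) {
      p <- params; p$seed <- p$seed + i - 1L; p
    }), analytes)
  }

  models <- list()
  for (a in analytes) {
    y <- Y[, a]
    if (select) {
      sw <- ff_search(X, y, params[[a]], inner_folds, inner_k)
      mask <- sw$mask
    } else {
      sw <- NULL
      mask <- rep(TRUE, ncol(X))
    }
    Xm <- X[, mask, drop = FALSE]
    kmax <- min(max_k, n - 2L, ncol(Xm))
    press <- numeric(kmax)
    for (i in seq_len(n)) {
      fit <- nipals_pls1(Xm[-i, , drop = FALSE], y[-i], kmax)
      for (k in seq_len(kmax)) {
        press[k] <- press[k] +
          (y[i] - pls1_predict(fit, Xm[i, , drop = FALSE], k))^2
      }
    }
    rmsecv <- sqrt(press / n)
    k <- which.min(rmsecv)
    fit <- nipals_pls1(Xm, y, k)
    rmsec <- sqrt(mean((y - pls1_predict(fit, Xm, k))^2))
    models[[a]] <- list(mask = mask, fit = fit, k = k,
                        cv_curve = tibble::tibble(k = seq_len(kmax),
                                                  rmsecv = rmsecv),
                        rmsec = rmsec,
                        swarm = sw)
  }
  structure(list(models = models, analytes = analytes, wavelength = wl, n = n),
            class = "chemo_pls")
}

#' @export
predict.chemo_pls <- function(object, new_spectra, ...) {
  Xn <- spectra_to_matrix(new_spectra)
  check_same_grid(object$wavelength, attr(Xn, "wavelength"))
  pred <- vapply(object$analytes, function(a) {
    m <- object$models[[a]]
    pls1_predict(m$fit, Xn[, m$mask, drop = FALSE], m$k)
  }, numeric(nrow(Xn)))
  pred <- matrix(pred, nrow = nrow(Xn),
                 dimnames = list(NULL, object$analytes))
  matrix_to_conc(pred, object$analytes,
                 sample_id = new_spectra$sample_id %||% NULL)
}

#' @export
print.chemo_pls <- function(x, ...) {
  cat("Firefly-optimized PLS (NIPALS)\n")
  for (a in x$analytes) {
    m <- x$models[[a]]
    cat(sprintf("  %s: %d/%d wavelengths, k = %d, RMSEC = %.4g ug/mL\n",
                a, sum(m$mask), length(m$mask), m$k, m$rmsec))
  }
  invisible(x)
}

#' @exportS3Method
glance.chemo_pls <- function(x, ...) {
  purrr::map_dfr(x$analytes, function(a) {
    m <- x$models[[a]]
    tibble::tibble(model = "FA-PLS", analyte = a, k = m$k,
                   n_wavelengths = sum(m$mask), rmsec = m$rmsec)
  })
}

#' @exportS3Method
tidy.chemo_pls <- function(x, ...) {
  purrr::map_dfr(x$analytes, function(a) {
    dplyr::mutate(x$models[[a]]$cv_curve, analyte = a, .before = 1)
  })
}
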