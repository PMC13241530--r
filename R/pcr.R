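#' Principal component regression
#'
#' Fits PCR on a spectra/concentration pair: the preprocessed spectral matrix
#' is decomposed by SVD and the reference concentrations are regressed on the
#' first `k` score vectors. `k` is chosen by leave-one-out cross-validation
#' (preprocessing refit inside each fold), minimizing the pooled RMSECV over
#' all analytes; with `parsimony_tol > 0` the smallest `k` whose RMSECV is
#' within `(1 + parsimony_tol)` of the minimum is taken instead.
#'
#' @param spectra Spectra tibble (`sample_id` + wavelength columns).
#' @param conc Concentration tibble, row-aligned with `spectra`.
#' @param max_k Largest component count examined; default
#'   `min(n - 2, p, 10)`.
#' @param center,scale Preprocessing flags. The default is mean-centering
#'   only; `scale = TRUE` adds per-wavelength variance scaling (autoscaling).
#'   Autoscaling is inadvisable when parts of the window carry no analyte
#'   signal, since it amplifies noise-only channels to unit variance -- see
#'   the methods vignette.
#' @param parsimony_tol Relative tolerance for the parsimony tie-break
#'   (0 = plain minimum).
#' @return Object of class `chemo_pcr` with elements `loadings`, `coef`,
#'   `intercept`, `k`, `cv_curve` (tibble `k`, `analyte`, `rmsecv`),
#'   `rmsec` per analyte, the frozen preprocessor and wavelength grid.
#' @export
fit_pcr <- function(spectra, conc, max_k = NULL, center = TRUE, scale = FALSE,
                    parsimony_tol = 0) {
  check_aligned(spectra, conc)
  X <- spectra_to_matrix(spectra)
  wl <- attr(X, "wavelength")
  Y <- conc_to_matrix(conc)
  n <- nrow(X)
  if (n < 3) stop("PCR needs at least 3 samples", call. = FALSE)
  max_k <- max_k %||% min(n - 2L, ncol(X), 10L)
  max_k <- min(max_k, n - 2L, ncol(X))

  # leave-one-out CV, preprocessing refit per fold
  press <- matrix(0, max_k, ncol(Y), dimnames = list(NULL, colnames(Y)))
  for (i in seq_len(n)) {
    pp <- fit_preprocessor(X[-i, , drop = FALSE], center, scale, warn = FALSE)
    Zt <- apply_preprocessor(pp, X[-i, , drop = FALSE])
    sv <- svd(Zt, nu = max_k, nv = max_k)
    Tt <- sv$u %*% diag(sv$d[seq_len(max_k)], max_k)
    zi <- apply_preprocessor(pp, X[i, , drop = FALSE])
    ti <- zi %*% sv$v
    ybar <- colMeans(Y[-i, , drop = FALSE])
    Yc <- sweep(Y[-i, , drop = FALSE], 2, ybar)
    for (k in seq_len(max_k)) {
      B <- qr.solve(Tt[, seq_len(k), drop = FALSE], Yc)
      pred <- ybar + ti[, seq_len(k), drop = FALSE] %*% B
      press[k, ] <- press[k, ] + (Y[i, ] - pred)^2
    }
  }
  rmsecv <- sqrt(press / n)
  overall <- sqrt(rowMeans(press / n))
  k_min <- which.min(overall)
  # ties at numerical zero (exact-rank data) resolve to the smallest k
  k <- min(which(overall <= overall[k_min] * (1 + parsimony_tol) + 1e-8))

  pp <- fit_preprocessor(X, center, scale)
  Z <- apply_preprocessor(pp, X)
  sv <- svd(Z)
  V <- sv$v[, seq_len(k), drop = FALSE]
  Tk <- Z %*% V
  ybar <- colMeans(Y)
  B <- qr.solve(Tk, sweep(Y, 2, ybar))
  fitted <- sweep(Tk %*% B, 2, ybar, `+`)
  rmsec <- sqrt(colMeans((Y - fitted)^2))

  structure(
    list(preproc = pp, loadings = V, coef = B, intercept = ybar, k = k,
         singular_values = sv$d,
         cv_curve = tidyr::pivot_longer(
           dplyr::bind_cols(tibble::tibble(k = seq_len(max_k)),
                            tibble::as_tibble(rmsecv)),
           -"k", names_to = "analyte", values_to = "rmsecv"),
         rmsec = rmsec, analytes = colnames(Y), wavelength = wl, n = n),
    class = "chemo_pcr"
  )
}

#' @export
predict.chemo_pcr <- function(object, new_spectra, ...) {
  Xn <- spectra_to_matrix(new_spectra)
  check_same_grid(object$wavelength, attr(Xn, "wavelength"))
  Z <- apply_preprocessor(object$preproc, Xn)
  pred <- sweep((Z %*% object$loadings) %*% object$coef, 2,
                object$intercept, `+`)
  matrix_to_conc(pred, object$analytes,
                 sample_id = new_spectra$sample_id %||% NULL)
}

#' @export
print.chemo_pcr <- function(x, ...) {
  cat("Principal component regression\n")
  cat("  n =", x$n, " wavelengths =", length(x$wavelength),
      " components =", x$k, "\n")
  cat("  RMSEC:", paste(sprintf("%s %.4g", x$analytes, x$rmsec),
                        collapse = ", "), "ug/mL\n")
  invisible(x)
}

#' @exportS3Method
glance.chemo_pcr <- function(x, ...) {
  tibble::tibble(model = "PCR", k = x$k, n = x$n,
                 n_wavelengths = length(x$wavelength),
                 rmsec = list(x$rmsec))
}

#' @exportS3Method
tidy.chemo_pcr <- function(x, ...) {
  x$cv_curve
}
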