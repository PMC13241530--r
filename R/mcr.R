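#' Evolving factor analysis rank estimation
#'
#' Tracks the singular values of growing row windows of the spectral matrix,
#' forward (first `m` rows) and backward (last `m` rows), and estimates the
#' chemical rank as the number of singular values of the full matrix that stay
#' above a noise threshold.
#'
#' The default threshold is `2 * sigma * (sqrt(n) + sqrt(p))` -- twice the
#' upper edge of the singular-value bulk of an `n x p` iid noise matrix with
#' per-cell SD `sigma`. `sigma` is taken from `noise_sd` when supplied,
#' otherwise estimated from the median of the smaller half of the singular
#' values; a machine-precision floor keeps the threshold meaningful on
#' noiseless data.
#'
#' @param spectra Spectra tibble.
#' @param noise_sd Optional known absorbance noise SD (AU).
#' @param threshold Optional explicit singular-value threshold, overriding the
#'   automatic choice.
#' @return Object of class `chemo_efa`: `rank`, `threshold`,
#'   `singular_values` (full matrix), `traces` (tibble `direction`, `window`,
#'   `factor`, `singular_value`).
#' @export
efa_rank <- function(spectra, noise_sd = NULL, threshold = NULL) {
  X <- spectra_to_matrix(spectra)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("EFA needs at least 3 samples", call. = FALSE)
  trace_dir <- function(direction) {
    purrr::map_dfr(seq_len(n), function(m) {
      rows <- if (direction == "forward") seq_len(m) else (n - m + 1L):n
      d <- svd(X[rows, , drop = FALSE], nu = 0, nv = 0)$d
      tibble::tibble(direction = direction, window = m,
                     factor = seq_along(d), singular_value = d)
    })
  }
  traces <- dplyr::bind_rows(trace_dir(direction = "forward"),
                             trace_dir(direction = "backward"))
  s <- traces$singular_value[traces$direction == "forward" &
                               traces$window == n]
  if (is.null(threshold)) {
    sigma <- noise_sd %||% {
      lower <- s[seq(ceiling(length(s) / 2) + 1L, length(s))]
      median(lower) / sqrt(max(n, p))
    }
    threshold <- max(2 * sigma * (sqrt(n) + sqrt(p)),
                     s[1] * max(n, p) * .Machine$double.eps * 10)
  }
  structure(list(rank = sum(s > threshold), threshold = threshold,
                 singular_values = s, traces = traces, n = n, p = p),
            class = "chemo_efa")
}

#' @export
print.chemo_efa <- function(x, ...) {
  cat("Evolving factor analysis: estimated rank", x$rank,
      "(threshold", format(x$threshold, digits = 4), ")\n")
  cat("  leading singular values:",
      paste(format(head(x$singular_values, 5), digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

# rows of B solving min ||A x - b|| with x >= 0, columnwise over B's rows;
# unconstrained solve first, NNLS only where constraints bind
nnls_rows <- function(A, B) {
  AtA <- crossprod(A)
  out <- t(solve(AtA, crossprod(A, t(B))))
  bad <- which(apply(out, 1, function(r) any(r < 0)))
  for (i in bad) {
    res <- tryCatch(pracma::lsqnonneg(A, B[i, ]),
                    error = function(e) {
                      stop("non-negative least squares failed on row ", i,
                           ": ", conditionMessage(e), call. = FALSE)
                    })
    out[i, ] <- res$x
  }
  out
}

# greedy-optimal assignment of resolved components to analytes by profile
# correlation (exact for the small ranks used here)
assign_components <- function(C, Y) {
  K <- ncol(Y)
  cors <- abs(stats::cor(C, Y))
  cors[!is.finite(cors)] <- 0
  perms <- if (K <= 5) {
    do.call(rbind, combinat_perms(seq_len(ncol(C)), K))
  } else NULL
  if (is.null(perms)) {
    # fallback: greedy
    assign <- integer(K)
    used <- integer(0)
    for (a in seq_len(K)) {
      ord <- order(cors[, a], decreasing = TRUE)
      assign[a] <- setdiff(ord, used)[1]
      used <- c(used, assign[a])
    }
    return(assign)
  }
  scores <- apply(perms, 1, function(pr) sum(cors[cbind(pr, seq_len(K))]))
  perms[which.max(scores), ]
}

combinat_perms <- function(v, k) {
  if (k == 1) return(lapply(v, function(x) x))
  out <- list()
  for (i in seq_along(v)) {
    rest <- combinat_perms(v[-i], k - 1)
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}

#' Multivariate curve resolution by alternating least squares
#'
#' Bilinear decomposition `X ~ C S'` of the spectral matrix under chemically
#' meaningful constraints: non-negativity of concentration profiles and
#' spectra (non-negative least squares updates), closure (calibration rows of
#' `C` rescaled so component sums equal the known mixture totals), optional
#' unit-norm spectral normalization (with the compensating scale moved into
#' `C`, leaving `C S'` unchanged), and optional selectivity windows forcing a
#' component's spectrum to zero over stated wavelength ranges. Closure and
#' spectral normalization both fix the decomposition's scale, so they are not
#' applied together; the default uses closure whenever reference
#' concentrations are supplied.
#'
#' Iteration stops when the relative change in the lack of fit (percent
#' residual norm) drops below `lof_tol`, or after `max_iter` cycles. Resolved
#' components are assigned to analytes by maximal correlation between the
#' calibration concentration profiles and the reference concentrations, and a
#' per-analyte affine quantitation map (least-squares line with intercept) is
#' fitted from resolved profile to ug/mL.
#'
#' @param spectra Calibration spectra tibble.
#' @param conc Reference concentration tibble (needed for closure totals and
#'   quantitation maps; may be `NULL` for pure resolution).
#' @param rank Number of components; typically from [efa_rank()].
#' @param nonneg_C,nonneg_S Non-negativity flags (default on).
#' @param closure Rescale calibration rows of `C` to known totals (default on
#'   when `conc` is given).
#' @param normalize_S Renormalize spectra to unit norm each cycle (default the
#'   complement of `closure`).
#' @param selectivity Optional list per component of wavelength windows
#'   (each `c(lo, hi)` nm) where that component's spectrum is forced to zero.
#' @param max_iter,lof_tol Convergence controls (relative lack-of-fit change).
#' @param init `"conc"` (initialize `C` from the reference concentrations,
#'   default when available) or `"svd"` (rectified singular vectors).
#' @return Object of class `chemo_mcr`: `C`, `S`, `lack_of_fit` (%), `rank`,
#'   `iterations`, `assignment`, `quant_maps`, constraint flags, wavelength
#'   grid.
#' @export
fit_mcrals <- function(spectra, conc = NULL, rank = 2,
                       nonneg_C = TRUE, nonneg_S = TRUE,
                       closure = !is.null(conc), normalize_S = !closure,
                       selectivity = NULL,
                       max_iter = 50, lof_tol = 1e-3,
                       init = c("conc", "svd")) {
  init <- match.arg(init)
  X <- spectra_to_matrix(spectra)
  wl <- attr(X, "wavelength")
  n <- nrow(X); p <- ncol(X)
  if (rank < 1 || rank > min(n, p)) {
    stop("rank must be between 1 and min(n, p) = ", min(n, p), call. = FALSE)
  }
  Y <- if (!is.null(conc)) conc_to_matrix(conc) else NULL
  if (closure && is.null(Y)) {
    stop("closure needs reference concentrations for the mixture totals",
         call. = FALSE)
  }
  totals <- if (closure) rowSums(Y) else NULL

  C <- if (init == "conc" && !is.null(Y) && ncol(Y) == rank) {
    unname(Y)
  } else {
    sv <- svd(X, nu = rank, nv = 0)
    abs(sv$u %*% diag(sv$d[seq_len(rank)], rank))
  }

  sel_zero <- NULL
  if (!is.null(selectivity)) {
    sel_zero <- matrix(FALSE, p, rank)
    for (k in seq_along(selectivity)) {
      for (win in selectivity[[k]]) {
        sel_zero[wl >= win[1] & wl <= win[2], k] <- TRUE
      }
    }
  }

  xss <- sum(X^2)
  lof <- Inf
  S <- matrix(0, p, rank)
  for (it in seq_len(max_iter)) {
    S <- if (nonneg_S) nnls_rows(C, t(X)) else
      t(solve(crossprod(C), crossprod(C, X)))
    if (!is.null(sel_zero)) S[sel_zero] <- 0
    if (normalize_S) {
      nrm <- sqrt(colSums(S^2))
      nrm[nrm < 1e-12] <- 1
      S <- sweep(S, 2, nrm, `/`)
      C <- sweep(C, 2, nrm, `*`)
    }
    C <- if (nonneg_C) nnls_rows(S, X) else
      t(solve(crossprod(S), crossprod(S, t(X))))
    if (closure) {
      rs <- rowSums(C)
      ok <- rs > 1e-12
      C[ok, ] <- C[ok, ] * (totals[ok] / rs[ok])
    }
    lof_new <- 100 * sqrt(sum((X - C %*% t(S))^2) / xss)
    if (lof_new < 1e-8 || abs(lof - lof_new) < lof_tol * max(lof_new, 1e-12)) {
      lof <- lof_new
      break
    }
    lof <- lof_new
  }

  assignment <- NULL
  quant_maps <- NULL
  analytes <- NULL
  if (!is.null(Y)) {
    analytes <- colnames(Y)
    assignment <- assign_components(C, Y)
    names(assignment) <- analytes
    quant_maps <- purrr::map(analytes, function(a) {
      cf <- coef(lm(Y[, a] ~ C[, assignment[[a]]]))
      c(intercept = unname(cf[1]), slope = unname(cf[2]))
    })
    names(quant_maps) <- analytes
  }

  structure(
    list(C = C, S = S, rank = rank, lack_of_fit = lof, iterations = it,
         assignment = assignment, quant_maps = quant_maps,
         analytes = analytes, wavelength = wl,
         constraints = list(nonneg_C = nonneg_C, nonneg_S = nonneg_S,
                            closure = closure, normalize_S = normalize_S,
                            selectivity = !is.null(selectivity)),
         n = n),
    class = "chemo_mcr"
  )
}

#' @export
predict.chemo_mcr <- function(object, new_spectra, ...) {
  if (is.null(object$quant_maps)) {
    stop("model was fitted without reference concentrations; no quantitation map",
         call. = FALSE)
  }
  Xn <- spectra_to_matrix(new_spectra)
  check_same_grid(object$wavelength, attr(Xn, "wavelength"))
  Cn <- if (object$constraints$nonneg_C) {
    nnls_rows(object$S, Xn)
  } else {
    t(solve(crossprod(object$S), crossprod(object$S, t(Xn))))
  }
  pred <- vapply(object$analytes, function(a) {
    qm <- object$quant_maps[[a]]
    qm["intercept"] + qm["slope"] * Cn[, object$assignment[[a]]]
  }, numeric(nrow(Xn)))
  pred <- matrix(pred, nrow = nrow(Xn),
                 dimnames = list(NULL, object$analytes))
  matrix_to_conc(pred, object$analytes,
                 sample_id = new_spectra$sample_id %||% NULL)
}

#' @export
print.chemo_mcr <- function(x, ...) {
  cat("MCR-ALS (rank", x$rank, ")\n")
  cat(sprintf("  lack of fit %.4g%% after %d iterations\n",
              x$lack_of_fit, x$iterations))
  fl <- x$constraints
  cat("  constraints:",
      paste(names(fl)[vapply(fl, isTRUE, logical(1))], collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method
glance.chemo_mcr <- function(x, ...) {
  tibble::tibble(model = "MCR-ALS", rank = x$rank,
                 lack_of_fit = x$lack_of_fit, iterations = x$iterations,
                 n = x$n)
}

#' Resolved spectra as a tidy tibble
#'
#' @param x A `chemo_mcr` fit.
#' @param ... Unused.
#' @return Tibble `wavelength_nm`, `component`, `absorptivity`.
#' @exportS3Method
tidy.chemo_mcr <- function(x, ...) {
  comp_names <- if (!is.null(x$assignment)) {
    nm <- paste0("comp", seq_len(x$rank))
    nm[x$assignment] <- names(x$assignment)
    nm
  } else paste0("comp", seq_len(x$rank))
  S <- x$S
  colnames(S) <- comp_names
  tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(wavelength_nm = x$wavelength),
                     tibble::as_tibble(S)),
    -"wavelength_nm", names_to = "component", values_to = "absorptivity"
  )
}
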