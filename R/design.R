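#' Concentration domain
#'
#' Working concentration ranges per analyte (ug/mL). The defaults are the
#' validated linear ranges 1.00--17.00 ug/mL for cefepime and 1.00--9.00 ug/mL
#' for tazobactam.
#'
#' @param CFPM,TAZO Default analyte ranges, each `c(min, max)` in ug/mL.
#' @param ... Further named ranges, each a length-2 numeric `c(min, max)`.
#' @return Named list of ranges, class `chemo_domain`.
#' @export
conc_domain <- function(CFPM = c(1, 17), TAZO = c(1, 9), ...) {
  dom <- c(list(CFPM = CFPM, TAZO = TAZO), list(...))
  for (a in names(dom)) {
    r <- dom[[a]]
    if (length(r) != 2 || r[1] >= r[2] || r[1] <= 0) {
      stop("domain for ", a, " must be c(min, max) with 0 < min < max",
           call. = FALSE)
    }
  }
  structure(dom, class = "chemo_domain")
}

level_values <- function(range, levels) {
  # symmetric integer levels -(L-1)/2 .. +(L-1)/2 mapped affinely onto range
  half <- (levels - 1) / 2
  center <- mean(range)
  step <- diff(range) / (levels - 1)
  center + (-half:half) * step
}

#' Brereton multilevel calibration design
#'
#' Full multilevel grid over a two-analyte concentration domain, with the
#' cyclic-shift run ordering conventional for multilevel calibration designs:
#' within the block at level `l` of the first factor, the second factor's
#' level sequence is cyclically rotated by the block index. For 5 levels and
#' the default domain this yields the 25-mixture calibration set with CFPM
#' levels \{1, 5, 9, 13, 17\} and TAZO levels \{1, 3, 5, 7, 9\} ug/mL
#' (level 0 at 9 and 5 ug/mL respectively).
#'
#' @param domain A [conc_domain()].
#' @param levels Odd number of levels per factor (>= 3).
#' @return Tibble `sample_id` + one concentration column per analyte, with
#'   attributes `levels` (per-analyte level values) and `role = "calibration"`.
#' @export
generate_brereton <- function(domain = conc_domain(), levels = 5) {
  if (levels %% 2 == 0 || levels < 3) {
    stop("`levels` must be an odd integer >= 3", call. = FALSE)
  }
  analytes <- names(domain)
  if (length(analytes) != 2) {
    stop("generate_brereton() is defined for exactly two analytes",
         call. = FALSE)
  }
  lv <- purrr::map(domain, level_values, levels = levels)
  idx1 <- rep(seq_len(levels), each = levels)
  # cyclic shift of the second factor's sequence per block of the first
  idx2 <- unlist(lapply(seq_len(levels) - 1L, function(b) {
    ((seq_len(levels) - 1L + b) %% levels) + 1L
  }))
  pts <- tibble::tibble(
    sample_id = sprintf("C%02d", seq_len(levels^2)),
    !!analytes[1] := lv[[1]][idx1],
    !!analytes[2] := lv[[2]][idx2]
  )
  attr(pts, "levels") <- lv
  attr(pts, "role") <- "calibration"
  pts
}

#' Enumerate candidate validation points
#'
#' Full lattice over the concentration domain at the given step, minus any
#' points already used for calibration (candidate pools for the exchange
#' algorithm must be disjoint from the calibration set).
#'
#' @param domain A [conc_domain()].
#' @param step Lattice step per analyte (ug/mL), recycled.
#' @param exclude Optional design tibble whose coordinates are removed.
#' @return Tibble of candidate coordinates (one column per analyte).
#' @export
enumerate_candidates <- function(domain = conc_domain(), step = 1,
                                 exclude = NULL) {
  if (any(step <= 0)) stop("`step` must be > 0", call. = FALSE)
  step <- rep_len(step, length(domain))
  axes <- purrr::map2(domain, step, function(r, s) seq(r[1], r[2], by = s))
  if (any(lengths(axes) == 1)) {
    warning("degenerate candidate grid: a step exceeds its range", call. = FALSE)
  }
  grid <- rev(expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE))
  names(grid) <- names(domain)
  cand <- tibble::as_tibble(grid)
  if (!is.null(exclude)) {
    key <- function(df) {
      do.call(paste, c(lapply(df[names(domain)], function(x) sprintf("%.9g", x)),
                       sep = "|"))
    }
    cand <- cand[!(key(cand) %in% key(exclude)), , drop = FALSE]
  }
  if (!nrow(cand)) stop("candidate pool is empty after exclusion", call. = FALSE)
  cand
}

# quadratic/linear response-surface expansion on [-1, 1]-scaled factors
design_model_matrix <- function(points, model = c("quadratic", "linear"),
                                scale_from = NULL) {
  model <- match.arg(model)
  pts <- as.matrix(points[, setdiff(names(points), "sample_id"), drop = FALSE])
  ref <- if (is.null(scale_from)) pts else
    as.matrix(scale_from[, colnames(pts), drop = FALSE])
  lo <- apply(ref, 2, min)
  hi <- apply(ref, 2, max)
  span <- pmax(hi - lo, .Machine$double.eps)
  Z <- sweep(sweep(pts, 2, (lo + hi) / 2), 2, span / 2, `/`)
  X <- cbind(1, Z)
  if (model == "quadratic") {
    inter <- do.call(cbind, lapply(utils::combn(ncol(Z), 2, simplify = FALSE),
                                   function(ij) Z[, ij[1]] * Z[, ij[2]]))
    X <- cbind(X, inter, Z^2)
  }
  colnames(X) <- NULL
  X
}

#' D-optimal subset selection by Fedorov exchange
#'
#' Selects `n_select` points from a candidate pool maximizing
#' \eqn{\det(X^\top X)}, the determinant of the Fisher information matrix of a
#' response-surface model on `[-1, 1]`-scaled factors. Uses the classical
#' Fedorov delta rule: for a design point \eqn{x_i} and candidate \eqn{x_j},
#' \eqn{\Delta = d(x_j) - d(x_i) - [d(x_j) d(x_i) - d(x_i, x_j)^2]} with
#' variance function \eqn{d(x) = x^\top (X^\top X)^{-1} x}; the best positive
#' swap is applied until the relative determinant gain falls below `tol`.
#' Several random restarts are run and the best subset kept. Factor scaling is
#' derived from the candidate pool, so an affine rescaling of the domain
#' leaves the selected points unchanged.
#'
#' @param candidates Candidate tibble from [enumerate_candidates()].
#' @param n_select Number of points to select (>= number of model terms).
#' @param model `"quadratic"` (default, 6 terms for two factors) or
#'   `"linear"` (3 terms).
#' @param seed Integer seed for the random initial subsets.
#' @param restarts Number of random restarts.
#' @param tol Relative determinant improvement below which a restart stops.
#' @return List of class `chemo_fedorov`: `points` (selected tibble with
#'   `sample_id`), `det`, `trace` (per-iteration tibble of swaps and
#'   determinants), `model`, `seed`, `restarts`.
#' @export
fedorov_select <- function(candidates, n_select = 13,
                           model = c("quadratic", "linear"),
                           seed = 1L, restarts = 20, tol = 1e-9) {
  model <- match.arg(model)
  Xall <- design_model_matrix(candidates, model)
  p <- ncol(Xall)
  N <- nrow(Xall)
  if (n_select < p) {
    stop("n_select (", n_select, ") must be >= the number of model terms (",
         p, ")", call. = FALSE)
  }
  if (n_select > N) {
    stop("n_select exceeds the candidate pool size", call. = FALSE)
  }

  best <- NULL
  trace <- list()
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(restarts)) {
      sel <- NULL
      for (attempt in 1:25) {
        cand_sel <- sort(sample.int(N, n_select))
        M <- crossprod(Xall[cand_sel, , drop = FALSE])
        if (is.finite(determinant(M)$modulus) &&
            rcond(M) > .Machine$double.eps * 10) {
          sel <- cand_sel
          break
        }
      }
      if (is.null(sel)) next
      det_cur <- det(crossprod(Xall[sel, , drop = FALSE]))
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        Xd <- Xall[sel, , drop = FALSE]
        Minv <- solve(crossprod(Xd))
        pool <- setdiff(seq_len(N), sel)
        if (!length(pool)) break
        Xp <- Xall[pool, , drop = FALSE]
        dd <- rowSums((Xd %*% Minv) * Xd)          # d(x_i), design
        dp <- rowSums((Xp %*% Minv) * Xp)          # d(x_j), pool
        cr <- Xd %*% Minv %*% t(Xp)                # d(x_i, x_j)
        delta <- outer(-dd, dp, `+`) - (outer(dd, dp) - cr^2)
        m <- which(delta == max(delta), arr.ind = TRUE)
        # ties: lowest candidate index, then lowest design index
        m <- m[order(pool[m[, 2]], sel[m[, 1]]), , drop = FALSE][1, ]
        dmax <- delta[m[1], m[2]]
        if (dmax > tol) {
          out_idx <- sel[m[1]]
          in_idx <- pool[m[2]]
          sel <- sort(c(setdiff(sel, out_idx), in_idx))
          det_cur <- det_cur * (1 + dmax)
          trace[[length(trace) + 1]] <- tibble::tibble(
            restart = r, swap_out = out_idx, swap_in = in_idx,
            det = det(crossprod(Xall[sel, , drop = FALSE]))
          )
          improved <- TRUE
        }
      }
      det_final <- det(crossprod(Xall[sel, , drop = FALSE]))
      if (is.null(best) || det_final > best$det + 1e-12 * abs(best$det)) {
        best <- list(sel = sel, det = det_final)
      }
    }
  })
  if (is.null(best)) {
    stop("could not initialize a non-singular information matrix; ",
         "increase restarts or the candidate pool", call. = FALSE)
  }
  pts <- candidates[best$sel, , drop = FALSE]
  pts <- dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("V%02d", seq_len(nrow(pts)))), pts
  )
  attr(pts, "role") <- "validation"
  structure(
    list(points = pts, det = best$det,
         trace = if (length(trace)) dplyr::bind_rows(trace) else
           tibble::tibble(restart = integer(), swap_out = integer(),
                          swap_in = integer(), det = double()),
         model = model, seed = as.integer(seed), restarts = restarts),
    class = "chemo_fedorov"
  )
}

#' @export
print.chemo_fedorov <- function(x, ...) {
  cat("D-optimal design (Fedorov exchange)\n")
  cat("  points:", nrow(x$points), " model:", x$model,
      " det(X'X):", format(x$det, digits = 6),
      " restarts:", x$restarts, "\n")
  invisible(x)
}

#' Leverage diagnostics for a design
#'
#' Hat-matrix leverages \eqn{h_i = x_i^\top (X^\top X)^{-1} x_i} of each
#' design point under the response-surface model, plus a pairwise-distance
#' summary of spatial spread. Leverages sum to the number of model terms.
#'
#' @param points Design tibble (analyte columns, optional `sample_id`).
#' @param model `"quadratic"` or `"linear"`.
#' @return Tibble of the points with a `.leverage` column; attributes
#'   `max_pairwise_distance` and `min_pairwise_distance` (in scaled factor
#'   space).
#' @export
leverage_diagnostics <- function(points, model = c("quadratic", "linear")) {
  model <- match.arg(model)
  X <- design_model_matrix(points, model)
  M <- crossprod(X)
  if (rcond(M) < .Machine$double.eps * 100) {
    stop("singular information matrix: design does not support this model",
         call. = FALSE)
  }
  h <- rowSums((X %*% solve(M)) * X)
  out <- dplyr::mutate(tibble::as_tibble(points), .leverage = h)
  Z <- X[, 2:3, drop = FALSE]  # scaled factor coordinates
  d <- stats::dist(Z)
  attr(out, "max_pairwise_distance") <- max(d)
  attr(out, "min_pairwise_distance") <- min(d)
  out
}
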