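resolve_pred <- function(data, truth, estimate) {
  y <- rlang::eval_tidy(rlang::enquo(truth), data)
  yh <- rlang::eval_tidy(rlang::enquo(estimate), data)
  if (length(y) != length(yh)) {
    stop("truth and estimate must have equal length", call. = FALSE)
  }
  list(y = as.numeric(y), y_hat = as.numeric(yh))
}

#' Calibration and prediction error metrics
#'
#' Computes the standard multivariate-calibration error suite from reference
#' (`truth`) and predicted (`estimate`) concentrations:
#' \itemize{
#'   \item `rmse`: \eqn{\sqrt{\sum (y_i - \hat y_i)^2 / n}}
#'   \item `bias`: \eqn{\sum (y_i - \hat y_i) / n}
#'   \item `sec`: \eqn{\sqrt{\sum (y_i - \hat y_i - bias)^2 / (n - 1)}}
#'   \item `bcrmsep`: the same bias-removed spread computed on a prediction
#'     set (numerically equal to `sec`)
#'   \item `rrmsep_standard`: `rmse / mean(y) * 100` (%), the conventional
#'     relative RMSEP
#'   \item `rrmsep_printed`: \eqn{(1/n)\sqrt{\sum (y_i - \hat y_i)^2} / \bar y
#'     \times 100}, i.e. the root sum of squares divided by `n` rather than
#'     `sqrt(n)` -- reported alongside the standard form so the two
#'     conventions can be compared (`rrmsep_printed = rrmsep_standard /
#'     sqrt(n)`)
#'   \item `mean_recovery` (%) and `rsd` (%) of per-sample recoveries
#' }
#'
#' @param data Data frame holding the prediction set.
#' @param truth,estimate Columns of `data` with reference and predicted
#'   concentrations (ug/mL); defaults `y` and `y_hat`.
#' @return One-row tibble with the metrics above plus `n`.
#' @export
compute_metrics <- function(data, truth = y, estimate = y_hat) {
  pr <- resolve_pred(data, {{ truth }}, {{ estimate }})
  y <- pr$y; yh <- pr$y_hat
  n <- length(y)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  e <- y - yh
  rmse <- sqrt(sum(e^2) / n)
  bias <- sum(e) / n
  sec <- sqrt(sum((e - bias)^2) / (n - 1))
  ybar <- mean(y)
  if (abs(ybar) < 1e-12) {
    warning("mean reference concentration is zero; relative metrics undefined",
            call. = FALSE)
    rrmsep_std <- rrmsep_printed <- NA_real_
  } else {
    rrmsep_std <- rmse / ybar * 100
    rrmsep_printed <- sqrt(sum(e^2)) / n / ybar * 100
  }
  rec <- ifelse(abs(y) < 1e-12, NA_real_, yh / y * 100)
  tibble::tibble(
    n = n, rmse = rmse, bias = bias, sec = sec, bcrmsep = sec,
    rrmsep_standard = rrmsep_std, rrmsep_printed = rrmsep_printed,
    mean_recovery = mean(rec, na.rm = TRUE),
    rsd = sd(rec, na.rm = TRUE) / mean(rec, na.rm = TRUE) * 100
  )
}

#' Net analyte signal figures of merit
#'
#' The net analyte signal (NAS) of analyte `k` is the part of its
#' unit-concentration spectrum orthogonal to the space spanned by all other
#' components: \eqn{nas_k = (I - S_{-k} S_{-k}^+) s_k}. Its norm is the
#' multivariate sensitivity SEN, and detection limits follow the usual
#' 3.3/10 convention: `LOD = 3.3 * delta_r / SEN`,
#' `LOQ = 10 * delta_r / SEN`, with `delta_r` the spectral residual noise
#' (AU).
#'
#' @param pure Pure (or resolved) spectra tibble: `wavelength_nm` + one
#'   column per component.
#' @param analyte Component column the figures of merit are computed for.
#' @param noise_sd Spectral noise SD `delta_r` (AU).
#' @return One-row tibble `analyte`, `sen`, `noise_sd`, `lod`, `loq`, and the
#'   NAS vector as a list column `nas`.
#' @export
nas_figures_of_merit <- function(pure, analyte, noise_sd) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  S <- pure_to_matrix(pure)
  if (ncol(S) < 2) {
    stop("need at least two component spectra", call. = FALSE)
  }
  if (!analyte %in% colnames(S)) {
    stop("no component `", analyte, "` in the spectra", call. = FALSE)
  }
  sk <- S[, analyte]
  Sm <- S[, setdiff(colnames(S), analyte), drop = FALSE]
  proj <- Sm %*% solve(crossprod(Sm), crossprod(Sm, sk))
  nas <- sk - drop(proj)
  sen <- sqrt(sum(nas^2))
  if (sen < 1e-12) {
    stop("no net analyte signal: `", analyte,
         "` is collinear with the other components", call. = FALSE)
  }
  tibble::tibble(analyte = analyte, sen = sen, noise_sd = noise_sd,
                 lod = 3.3 * noise_sd / sen, loq = 10 * noise_sd / sen,
                 nas = list(nas))
}

#' Student's t-test of recoveries against 100%
#'
#' One-sample t statistic `|mean - reference| / (SD / sqrt(n))` for percentage
#' recoveries, with the two upper-tail critical values conventionally quoted
#' (0.025 and 0.01).
#'
#' @param recoveries Numeric vector of recoveries (%).
#' @param reference Null value, default 100.
#' @param tails Upper-tail probabilities for critical values.
#' @return One-row tibble `t`, `df`, `p_value` (two-sided), and one
#'   `crit_<tail>` column per requested tail.
#' @export
recovery_ttest <- function(recoveries, reference = 100,
                           tails = c(0.025, 0.01)) {
  n <- length(recoveries)
  if (n < 2) stop("need at least 2 recoveries", call. = FALSE)
  s <- sd(recoveries)
  m <- mean(recoveries)
  t_stat <- if (s < 1e-12) {
    if (abs(m - reference) < 1e-12) 0 else Inf
  } else {
    abs(m - reference) / (s / sqrt(n))
  }
  df <- n - 1
  out <- tibble::tibble(t = t_stat, df = df,
                        p_value = 2 * pt(t_stat, df, lower.tail = FALSE))
  for (a in tails) {
    out[[sprintf("crit_%g", a)]] <- qt(1 - a, df)
  }
  out
}

#' One-way ANOVA across recovery groups
#'
#' Classical between/within decomposition (via [stats::aov()]) of recoveries
#' grouped e.g. by calibration model, with the critical F value at `alpha`.
#'
#' @param data Data frame with a value and a group column, or a list of
#'   numeric vectors (one per group).
#' @param value,group Columns of `data` (ignored for a list input).
#' @param alpha Significance level for `f_crit`.
#' @return One-row tibble `f`, `df_between`, `df_within`, `p_value`, `f_crit`.
#' @export
oneway_anova <- function(data, value = value, group = group, alpha = 0.05) {
  if (is.list(data) && !is.data.frame(data)) {
    data <- purrr::imap_dfr(data, function(v, nm) {
      tibble::tibble(value = v, group = as.character(nm))
    })
    vals <- data$value; grp <- data$group
  } else {
    vals <- rlang::eval_tidy(rlang::enquo(value), data)
    grp <- rlang::eval_tidy(rlang::enquo(group), data)
  }
  grp <- factor(grp)
  if (nlevels(grp) < 2 || any(table(grp) < 2)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  fit <- aov(vals ~ grp)
  tab <- summary(fit)[[1]]
  f <- tab[1, "F value"]
  if (!is.finite(f)) f <- 0   # all groups identical: no variance anywhere
  tibble::tibble(
    f = f, df_between = tab[1, "Df"], df_within = tab[2, "Df"],
    p_value = if (f == 0) 1 else tab[1, "Pr(>F)"],
    f_crit = qf(1 - alpha, tab[1, "Df"], tab[2, "Df"])
  )
}

#' Elliptical joint confidence region for slope and intercept
#'
#' Fits the straight line `estimate = a + b * truth` and constructs the
#' joint `(1 - alpha)` confidence region of `(a, b)`:
#' \deqn{(\beta - \hat\beta)^\top X^\top X (\beta - \hat\beta) \le
#'       2 s^2 F_{2, n-2, 1-\alpha}}
#' with `X = [1, y]`. The ellipse geometry (center, semi-axes, orientation)
#' comes from the eigendecomposition of `2 s^2 F (X'X)^{-1}`; the method is
#' judged unbiased when the region contains the ideal point `(0, 1)`.
#'
#' @param data Data frame with the prediction set.
#' @param truth,estimate Columns with reference and predicted values.
#' @param alpha Significance level (default 0.05 for a 95% region).
#' @return Object of class `chemo_ejcr` with `intercept`, `slope`, `s2`,
#'   `xtx`, `f_crit`, `center`, `semi_axes`, `angle` (radians), `area`,
#'   `contains_ideal`, `zero_area`, `n`.
#' @export
ejcr <- function(data, truth = y, estimate = y_hat, alpha = 0.05) {
  pr <- resolve_pred(data, {{ truth }}, {{ estimate }})
  y <- pr$y; yh <- pr$y_hat
  n <- length(y)
  if (n < 3) stop("EJCR needs at least 3 samples", call. = FALSE)
  if (var(y) < 1e-12) {
    stop("reference concentrations are all equal: regression is degenerate",
         call. = FALSE)
  }
  X <- cbind(1, y)
  beta <- unname(qr.solve(X, yh))
  resid <- yh - X %*% beta
  s2 <- sum(resid^2) / (n - 2)
  xtx <- crossprod(X)
  f_crit <- qf(1 - alpha, 2, n - 2)
  c2 <- 2 * s2 * f_crit
  zero_area <- c2 < 1e-14 * max(diag(xtx))
  delta0 <- c(0, 1) - beta
  qform <- drop(t(delta0) %*% xtx %*% delta0)
  eg <- eigen(solve(xtx) * c2, symmetric = TRUE)
  semi <- sqrt(pmax(eg$values, 0))
  structure(
    list(intercept = beta[1], slope = beta[2], s2 = s2, xtx = xtx,
         f_crit = f_crit, alpha = alpha,
         center = c(intercept = beta[1], slope = beta[2]),
         semi_axes = semi,
         angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
         area = pi * prod(semi),
         contains_ideal = if (zero_area) qform < 1e-12 else qform <= c2,
         zero_area = zero_area, n = n),
    class = "chemo_ejcr"
  )
}

#' @export
print.chemo_ejcr <- function(x, ...) {
  cat(sprintf("EJCR (%.0f%%): intercept %.4g, slope %.4g, area %.4g\n",
              (1 - x$alpha) * 100, x$intercept, x$slope, x$area))
  cat("  contains ideal point (0, 1):", x$contains_ideal,
      if (x$zero_area) "(zero-area region)" else "", "\n")
  invisible(x)
}

#' @exportS3Method
tidy.chemo_ejcr <- function(x, ...) {
  se <- sqrt(diag(solve(x$xtx)) * x$s2)
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = se)
}

#' @exportS3Method
glance.chemo_ejcr <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, slope = x$slope, area = x$area,
                 contains_ideal = x$contains_ideal, zero_area = x$zero_area,
                 f_crit = x$f_crit, n = x$n)
}

#' Ellipse outline of an EJCR as a tibble
#'
#' @param x A `chemo_ejcr` object.
#' @param n_points Number of outline points.
#' @return Tibble `intercept`, `slope` tracing the region boundary.
#' @export
ejcr_outline <- function(x, n_points = 200) {
  th <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(x$semi_axes[1] * cos(th), x$semi_axes[2] * sin(th))
  rot <- matrix(c(cos(x$angle), sin(x$angle),
                  -sin(x$angle), cos(x$angle)), 2, 2)
  pts <- rot %*% circ + x$center
  tibble::tibble(intercept = pts[1, ], slope = pts[2, ])
}

#' Matrix factors and matrix effect
#'
#' Compares concentrations predicted in post-extraction spiked plasma with
#' those from matched neat aqueous standards: `MF = plasma / neat` per spike
#' level and `ME% = (MF - 1) * 100` (negative = suppression).
#'
#' @param data Data frame with one row per analyte/level.
#' @param neat,plasma Columns with the neat and plasma predicted
#'   concentrations.
#' @return `data` with `mf` and `me_percent` columns appended.
#' @export
matrix_effect <- function(data, neat = neat, plasma = plasma) {
  nv <- rlang::eval_tidy(rlang::enquo(neat), data)
  pv <- rlang::eval_tidy(rlang::enquo(plasma), data)
  if (any(abs(nv) < 1e-12)) {
    stop("neat prediction of zero: matrix factor undefined", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(data),
                mf = pv / nv, me_percent = (pv / nv - 1) * 100)
}
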