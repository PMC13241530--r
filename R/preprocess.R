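# Column-wise centering/scaling frozen on the calibration spectra, then
# applied unchanged to prediction spectra.  Constant columns get their scale
# floored at a small epsilon (with a warning) so autoscaling never divides
# by zero.

fit_preprocessor <- function(X, center = TRUE, scale = TRUE, warn = TRUE) {
  mu <- if (center) colMeans(X) else rep(0, ncol(X))
  sc <- rep(1, ncol(X))
  if (scale) {
    sc <- apply(X, 2, sd)
    bad <- sc < 1e-12
    if (any(bad)) {
      if (warn) warning(sum(bad), " constant wavelength column(s); scale floored at 1e-12",
              call. = FALSE)
      sc[bad] <- 1e-12
    }
  }
  structure(list(center = mu, scale = sc,
                 do_center = center, do_scale = scale),
            class = "chemo_preproc")
}

apply_preprocessor <- function(pp, X) {
  sweep(sweep(X, 2, pp$center), 2, pp$scale, `/`)
}

invert_preprocessor <- function(pp, Z) {
  sweep(sweep(Z, 2, pp$scale, `*`), 2, pp$center, `+`)
}
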