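#' Wavelength grid
#'
#' Build the evenly spaced wavelength grid on which all spectra are evaluated.
#' The default is the working UV window 210--350 nm at 1 nm resolution,
#' i.e. 141 discrete wavelength variables.
#'
#' @param start_nm,end_nm Grid limits in nm.
#' @param step_nm Grid spacing in nm.
#' @return Numeric vector of wavelengths (nm), strictly increasing.
#' @examples
#' length(wavelength_grid())  # 141
#' @export
wavelength_grid <- function(start_nm = 210, end_nm = 350, step_nm = 1) {
  if (end_nm <= start_nm || step_nm <= 0) {
    stop("invalid wavelength grid: need end_nm > start_nm and step_nm > 0",
         call. = FALSE)
  }
  n <- (end_nm - start_nm) / step_nm
  if (abs(n - round(n)) > 1e-8) {
    stop("grid span must be an integer multiple of step_nm", call. = FALSE)
  }
  seq(start_nm, end_nm, by = step_nm)
}

#' Default chromophoric band library
#'
#' Gaussian band parameters for the two analytes. Tazobactam (TAZO) carries a
#' dominant band near 211 nm with a weak subsidiary band near 280 nm; cefepime
#' (CFPM) absorbs mainly around 257--275 nm with a shoulder near 235 nm and
#' the steep mid-UV end absorption (band near 214 nm) typical of beta-lactams,
#' which makes the two spectra severely overlapped below 250 nm.
#' Peak absorptivities are in AU mL ug^-1 at 1 cm path, chosen so that mixture
#' absorbances over the working concentration ranges stay mostly within
#' 0.1--1.5 AU (reaching ~2.5 AU only at the joint upper-range corner). Both analytes absorb everywhere on the 210--350 nm grid, so no
#' interference-free wavelength exists: the overlap that motivates multivariate
#' calibration.
#'
#' @return Named list (one element per analyte) of tibbles with columns
#'   `center_nm`, `width_nm` (Gaussian sigma) and `peak` (peak absorptivity).
#' @export
default_band_library <- function() {
  list(
    CFPM = tibble::tibble(
      center_nm = c(257, 275, 235, 214),
      width_nm  = c(12, 9, 15, 10),
      peak      = c(0.05, 0.07, 0.03, 0.08)
    ),
    TAZO = tibble::tibble(
      center_nm = c(211, 280),
      width_nm  = c(8, 10),
      peak      = c(0.12, 0.02)
    )
  )
}

#' Pure-component spectra from a Gaussian band library
#'
#' Evaluates each analyte's absorptivity spectrum as a sum of Gaussian bands,
#' \eqn{\epsilon(\lambda) = \sum_b p_b \exp(-(\lambda - c_b)^2 / (2 w_b^2))},
#' on a common wavelength grid.
#'
#' @param band_library Named list of per-analyte band tables, each with columns
#'   `center_nm`, `width_nm`, `peak`; see [default_band_library()].
#' @param grid Wavelength grid from [wavelength_grid()].
#' @return Tibble with `wavelength_nm` plus one absorptivity column per analyte
#'   (AU mL ug^-1 at unit path length).
#' @examples
#' pure <- build_pure_spectra()
#' nrow(pure)  # 141
#' @export
build_pure_spectra <- function(band_library = default_band_library(),
                               grid = wavelength_grid()) {
  if (!length(band_library) || is.null(names(band_library))) {
    stop("band_library must be a named, non-empty list", call. = FALSE)
  }
  eps <- purrr::map(band_library, function(bands) {
    bands <- tibble::as_tibble(bands)
    if (!nrow(bands)) {
      stop("each analyte needs at least one band", call. = FALSE)
    }
    if (any(bands$width_nm <= 0) || any(bands$peak < 0)) {
      stop("band widths must be > 0 and peak absorptivities >= 0",
           call. = FALSE)
    }
    Reduce(`+`, purrr::pmap(bands, function(center_nm, width_nm, peak, ...) {
      peak * exp(-(grid - center_nm)^2 / (2 * width_nm^2))
    }))
  })
  dplyr::bind_cols(tibble::tibble(wavelength_nm = grid), tibble::as_tibble(eps))
}

pure_to_matrix <- function(pure) {
  analytes <- setdiff(names(pure), "wavelength_nm")
  m <- as.matrix(pure[, analytes, drop = FALSE])
  attr(m, "wavelength") <- pure$wavelength_nm
  m
}

#' Photometric noise model
#'
#' Homoscedastic Gaussian absorbance noise with an optional slow sinusoidal
#' baseline drift (random phase per sample). The default noise floor of
#' 0.002 AU is typical double-beam photometric noise; the baseline is off by
#' default.
#'
#' @param absorbance_sd Standard deviation of iid absorbance noise (AU).
#' @param baseline_amplitude Amplitude of the sinusoidal baseline (AU).
#' @param baseline_period_nm Period of the baseline oscillation (nm).
#' @param seed Integer seed; identical seed and parameters give a
#'   bit-identical realization.
#' @return A `chemo_noise` list.
#' @export
noise_model <- function(absorbance_sd = 0.002, baseline_amplitude = 0,
                        baseline_period_nm = 60, seed = 1L) {
  if (absorbance_sd < 0 || baseline_amplitude < 0 || baseline_period_nm <= 0) {
    stop("noise parameters must be non-negative (period > 0)", call. = FALSE)
  }
  structure(
    list(absorbance_sd = absorbance_sd,
         baseline_amplitude = baseline_amplitude,
         baseline_period_nm = baseline_period_nm,
         seed = as.integer(seed)),
    class = "chemo_noise"
  )
}

noise_realization <- function(noise, n, wavelength) {
  p <- length(wavelength)
  withr::with_seed(noise$seed, {
    base <- matrix(0, n, p)
    if (noise$baseline_amplitude > 0) {
      phase <- runif(n, 0, 2 * pi)
      for (i in seq_len(n)) {
        base[i, ] <- noise$baseline_amplitude *
          sin(2 * pi * wavelength / noise$baseline_period_nm + phase[i])
      }
    }
    eps <- if (noise$absorbance_sd > 0) {
      matrix(rnorm(n * p, sd = noise$absorbance_sd), n, p)
    } else {
      matrix(0, n, p)
    }
    base + eps
  })
}

#' Simulate Beer--Lambert mixture spectra
#'
#' Mixture absorbances are additive in the components:
#' \eqn{A_{i\lambda} = \sum_k c_{ik} \epsilon_k(\lambda)} plus baseline and
#' noise from the noise model. Unit path length is absorbed into the
#' absorptivities.
#'
#' @param conc Concentration tibble (`sample_id` + one column per analyte,
#'   ug/mL); analyte columns must match the pure spectra.
#' @param pure Pure spectra from [build_pure_spectra()].
#' @param noise A [noise_model()].
#' @return Spectra tibble: `sample_id` plus one absorbance column per
#'   wavelength (AU).
#' @export
simulate_mixtures <- function(conc, pure = build_pure_spectra(),
                              noise = noise_model()) {
  E <- pure_to_matrix(pure)
  analytes <- colnames(E)
  missing <- setdiff(analytes, names(conc))
  if (length(missing)) {
    stop("concentration table lacks analyte column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  C <- conc_to_matrix(conc[, c(intersect(names(conc), "sample_id"), analytes)])
  if (any(C < 0)) stop("concentrations must be non-negative", call. = FALSE)
  A <- C %*% t(E)
  A <- A + noise_realization(noise, nrow(A), attr(E, "wavelength"))
  matrix_to_spectra(A, attr(E, "wavelength"),
                    sample_id = conc$sample_id %||% NULL)
}

#' Plasma matrix-effect specification
#'
#' Post-extraction plasma marginally suppresses the analyte response and adds
#' a small smooth background, modeled as an exponential decay in wavelength.
#'
#' @param suppression Named fraction per analyte in `[0, 1)`; e.g. 0.0235
#'   means a 2.35% signal suppression (matrix factor 0.9765).
#' @param background_amplitude Background absorbance at the first grid point
#'   (AU); default small to mirror a negligible plasma blank.
#' @param background_decay Exponential decay rate of the background per nm.
#' @param variability_sd Per-sample SD of the suppression fraction.
#' @return A `chemo_matrix_effect` list.
#' @export
matrix_effect_spec <- function(suppression = c(CFPM = 0.018, TAZO = 0.02),
                               background_amplitude = 0.005,
                               background_decay = 0.02,
                               variability_sd = 0) {
  if (any(suppression < 0) || any(suppression >= 1)) {
    stop("suppression fractions must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(suppression = suppression,
         background_amplitude = background_amplitude,
         background_decay = background_decay,
         variability_sd = variability_sd),
    class = "chemo_matrix_effect"
  )
}

#' Simulate post-extraction spiked plasma spectra
#'
#' As [simulate_mixtures()], but each analyte's contribution is scaled by
#' `1 - suppression` and a smooth plasma background is added. The true matrix
#' factor (MF) applied per analyte is returned alongside the spectra.
#'
#' @inheritParams simulate_mixtures
#' @param matrix_effect A [matrix_effect_spec()].
#' @return List with `spectra` (tibble) and `mf` (named vector of true matrix
#'   factors, `1 - suppression`).
#' @export
simulate_plasma_set <- function(conc, pure = build_pure_spectra(),
                                noise = noise_model(),
                                matrix_effect = matrix_effect_spec()) {
  E <- pure_to_matrix(pure)
  analytes <- colnames(E)
  supp <- matrix_effect$suppression
  if (is.null(names(supp))) names(supp) <- analytes
  supp <- supp[analytes]
  if (anyNA(supp)) {
    stop("suppression must be named for every analyte", call. = FALSE)
  }
  C <- conc_to_matrix(conc[, c(intersect(names(conc), "sample_id"), analytes)])
  if (any(C < 0)) stop("concentrations must be non-negative", call. = FALSE)
  wl <- attr(E, "wavelength")
  n <- nrow(C)

  smat <- matrix(rep(supp, each = n), n, length(analytes))
  if (matrix_effect$variability_sd > 0) {
    smat <- smat + withr::with_seed(
      noise$seed + 1L,
      matrix(rnorm(n * length(analytes), sd = matrix_effect$variability_sd),
             n, length(analytes))
    )
    smat <- pmin(pmax(smat, 0), 1 - 1e-12)
  }
  A <- (C * (1 - smat)) %*% t(E)
  bg <- matrix_effect$background_amplitude *
    exp(-matrix_effect$background_decay * (wl - wl[1]))
  A <- sweep(A, 2, bg, `+`)
  A <- A + noise_realization(noise, n, wl)
  list(
    spectra = matrix_to_spectra(A, wl, sample_id = conc$sample_id %||% NULL),
    mf = setNames(1 - supp, analytes)
  )
}
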