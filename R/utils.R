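# Shared conversions between the tibble-facing API and the matrix algebra
# used internally.  A spectra tibble has a `sample_id` column plus one numeric
# column per wavelength, named by the wavelength in nm ("210", "211", ...).
# A concentration tibble has `sample_id` plus one numeric column per analyte.

spectra_wavelengths <- function(spectra) {
  cols <- setdiff(names(spectra), "sample_id")
  wl <- suppressWarnings(as.numeric(cols))
  if (anyNA(wl)) {
    stop("spectra columns other than `sample_id` must be named by wavelength (nm); ",
         "offending columns: ", paste(cols[is.na(wl)], collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(wl, strictly = TRUE)) {
    stop("wavelength columns must be strictly increasing", call. = FALSE)
  }
  wl
}

spectra_to_matrix <- function(spectra) {
  wl <- spectra_wavelengths(spectra)
  m <- as.matrix(spectra[, setdiff(names(spectra), "sample_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- if ("sample_id" %in% names(spectra)) spectra$sample_id else NULL
  attr(m, "wavelength") <- wl
  m
}

matrix_to_spectra <- function(m, wavelength, sample_id = NULL) {
  sample_id <- sample_id %||% rownames(m) %||% sprintf("S%02d", seq_len(nrow(m)))
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- as.character(wavelength)
  dplyr::bind_cols(tibble::tibble(sample_id = sample_id), out)
}

conc_to_matrix <- function(conc) {
  cols <- setdiff(names(conc), "sample_id")
  m <- as.matrix(conc[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- if ("sample_id" %in% names(conc)) conc$sample_id else NULL
  m
}

matrix_to_conc <- function(m, analytes = colnames(m), sample_id = NULL) {
  sample_id <- sample_id %||% rownames(m) %||% sprintf("S%02d", seq_len(nrow(m)))
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- analytes
  dplyr::bind_cols(tibble::tibble(sample_id = sample_id), out)
}

check_aligned <- function(spectra, conc) {
  if (nrow(spectra) != nrow(conc)) {
    stop("spectra (", nrow(spectra), " rows) and concentrations (", nrow(conc),
         " rows) must be row-aligned", call. = FALSE)
  }
  invisible(TRUE)
}

check_same_grid <- function(model_wl, new_wl) {
  if (length(model_wl) != length(new_wl) || any(abs(model_wl - new_wl) > 1e-9)) {
    stop("wavelength grid mismatch: model fitted on ",
         length(model_wl), " points [", model_wl[1], "-", model_wl[length(model_wl)],
         " nm], new spectra have ", length(new_wl), " points [",
         new_wl[1], "-", new_wl[length(new_wl)], " nm]", call. = FALSE)
  }
  invisible(TRUE)
}

# round half away from zero at `digits` decimals, as printed reports do
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}
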