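#' Read and write spectra CSV files
#'
#' The on-disk dialect stores wavelengths as rows: first column
#' `wavelength_nm`, then one column per sample. In memory spectra live as a
#' samples-by-wavelengths tibble, so the reader transposes and validates that
#' the wavelength column is strictly increasing.
#'
#' @param spectra Spectra tibble (`sample_id` + wavelength columns).
#' @param path File path.
#' @return `read_spectra_csv()` returns a spectra tibble;
#'   `write_spectra_csv()` returns `path` invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  m <- spectra_to_matrix(spectra)
  out <- dplyr::bind_cols(
    tibble::tibble(wavelength_nm = attr(m, "wavelength")),
    tibble::as_tibble(t(m), .name_repair = "minimal")
  )
  names(out) <- c("wavelength_nm", spectra$sample_id)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (names(df)[1] != "wavelength_nm") {
    stop("first column of a spectra CSV must be `wavelength_nm` (got `",
         names(df)[1], "`) in ", path, call. = FALSE)
  }
  wl <- df$wavelength_nm
  if (anyNA(wl) || is.unsorted(wl, strictly = TRUE)) {
    bad <- which(c(FALSE, diff(wl) <= 0) | is.na(wl))[1]
    stop("wavelength column must be strictly increasing; violation at data line ",
         bad, " of ", path, call. = FALSE)
  }
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  matrix_to_spectra(m, wl, sample_id = colnames(df)[-1])
}

#' Read and write concentration CSV files
#'
#' Dialect: header `sample_id` plus one column per analyte, concentrations in
#' ug/mL.
#'
#' @param conc Concentration tibble.
#' @param path File path.
#' @return `read_conc_csv()` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
write_conc_csv <- function(conc, path) {
  readr::write_csv(conc, path)
  invisible(path)
}

#' @rdname write_conc_csv
#' @export
read_conc_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("first column of a concentration CSV must be `sample_id` in ", path,
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df
}

mat_csv_write <- function(m, path) {
  readr::write_csv(tibble::as_tibble(as.matrix(m), .name_repair = "minimal"),
                   path, col_names = FALSE)
}

mat_csv_read <- function(path) {
  unname(as.matrix(readr::read_csv(path, col_names = FALSE,
                                   show_col_types = FALSE)))
}

#' Save and reload fitted calibration models
#'
#' Fitted models are archived as a directory holding a `model.json` with all
#' scalar metadata plus companion headerless CSV matrices (loadings,
#' coefficients, resolved spectra, ...), so archives stay language-neutral
#' and text-only. Reloaded models predict identically to the originals.
#'
#' @param model A `chemo_pcr`, `chemo_pls` or `chemo_mcr` fit.
#' @param dir Archive directory (created if missing).
#' @return `write_model()` returns `dir` invisibly; `read_model()` the
#'   restored model object.
#' @export
write_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  j <- function(x) jsonlite::write_json(
    x, file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE
  )
  if (inherits(model, "chemo_pcr")) {
    mat_csv_write(model$loadings, file.path(dir, "loadings.csv"))
    mat_csv_write(model$coef, file.path(dir, "coef.csv"))
    j(list(class = "chemo_pcr", k = model$k, n = model$n,
           analytes = model$analytes, wavelength = model$wavelength,
           intercept = model$intercept,
           preproc = model$preproc[c("center", "scale",
                                     "do_center", "do_scale")],
           rmsec = as.list(model$rmsec)))
  } else if (inherits(model, "chemo_pls")) {
    for (a in model$analytes) {
      m <- model$models[[a]]
      mat_csv_write(cbind(m$fit$coefs[[m$k]]), file.path(dir, paste0("coef_", a, ".csv")))
    }
    j(list(class = "chemo_pls", n = model$n, analytes = model$analytes,
           wavelength = model$wavelength,
           models = purrr::map(model$models, function(m) {
             list(mask = m$mask, k = m$k, rmsec = m$rmsec,
                  xbar = m$fit$xbar, ybar = m$fit$ybar)
           })))
  } else if (inherits(model, "chemo_mcr")) {
    mat_csv_write(model$S, file.path(dir, "S.csv"))
    mat_csv_write(model$C, file.path(dir, "C.csv"))
    j(list(class = "chemo_mcr", rank = model$rank, n = model$n,
           lack_of_fit = model$lack_of_fit, iterations = model$iterations,
           analytes = model$analytes, wavelength = model$wavelength,
           assignment = as.list(model$assignment),
           quant_maps = purrr::map(model$quant_maps, as.list),
           constraints = model$constraints))
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"),
         call. = FALSE)
  }
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  if (meta$class == "chemo_pcr") {
    structure(
      list(preproc = structure(
             list(center = meta$preproc$center, scale = meta$preproc$scale,
                  do_center = meta$preproc$do_center,
                  do_scale = meta$preproc$do_scale),
             class = "chemo_preproc"),
           loadings = mat_csv_read(file.path(dir, "loadings.csv")),
           coef = mat_csv_read(file.path(dir, "coef.csv")),
           intercept = setNames(as.numeric(meta$intercept), meta$analytes),
           k = meta$k, analytes = meta$analytes,
           wavelength = meta$wavelength, n = meta$n,
           rmsec = unlist(meta$rmsec)),
      class = "chemo_pcr"
    )
  } else if (meta$class == "chemo_pls") {
    models <- purrr::imap(meta$models, function(m, a) {
      coefv <- mat_csv_read(file.path(dir, paste0("coef_", a, ".csv")))
      coefs <- vector("list", m$k)
      coefs[[m$k]] <- coefv
      list(mask = as.logical(m$mask), k = m$k, rmsec = m$rmsec,
           cv_curve = NULL, swarm = NULL,
           fit = list(xbar = as.numeric(m$xbar), ybar = m$ybar,
                      coefs = coefs, k_max = m$k))
    })
    structure(list(models = models[meta$analytes], analytes = meta$analytes,
                   wavelength = meta$wavelength, n = meta$n),
              class = "chemo_pls")
  } else if (meta$class == "chemo_mcr") {
    structure(
      list(C = mat_csv_read(file.path(dir, "C.csv")),
           S = mat_csv_read(file.path(dir, "S.csv")),
           rank = meta$rank, lack_of_fit = meta$lack_of_fit,
           iterations = meta$iterations,
           assignment = unlist(meta$assignment),
           quant_maps = purrr::map(meta$quant_maps, unlist),
           analytes = meta$analytes, wavelength = meta$wavelength,
           constraints = as.list(meta$constraints), n = meta$n),
      class = "chemo_mcr"
    )
  } else {
    stop("unknown model class in archive: ", meta$class, call. = FALSE)
  }
}
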