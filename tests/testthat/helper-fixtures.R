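# Small in-code fixtures shared across the suite.

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# compact two-component library on a short grid for fast model tests
tiny_grid <- function() wavelength_grid(210, 250, 2)

tiny_library <- function() {
  list(
    A = tibble::tibble(center_nm = c(218, 240), width_nm = c(6, 8),
                       peak = c(0.10, 0.04)),
    B = tibble::tibble(center_nm = c(226, 246), width_nm = c(7, 6),
                       peak = c(0.08, 0.05))
  )
}

tiny_pure <- function() build_pure_spectra(tiny_library(), tiny_grid())

# random concentrations over a rectangular domain
random_conc <- function(n, seed, analytes = c("A", "B"), lo = 1, hi = 10) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * length(analytes), lo, hi), n)
    colnames(m) <- analytes
    dplyr::bind_cols(tibble::tibble(sample_id = sprintf("S%02d", seq_len(n))),
                     tibble::as_tibble(m))
  })
}

# the study's default design pair, shared by several files
study_designs <- local({
  cal <- generate_brereton()
  cand <- enumerate_candidates(exclude = cal)
  fed <- fedorov_select(cand, 13, seed = 42, restarts = 10)
  list(cal = cal, val = fed$points, candidates = cand, fedorov = fed)
})
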