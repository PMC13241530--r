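#' Per-sample carbon footprint
#'
#' Cradle-to-gate carbon footprint of one analysis,
#' \eqn{CF = \sum_i P_i t_i EF_{elec} + \sum_j m_j EF_j}: direct electricity
#' use of each instrument (power in kW times operating hours times the grid
#' emission factor) plus the embodied emissions of consumed materials (mass
#' times cradle-to-gate emission factor).
#'
#' @param energy Data frame of instruments with columns `power_kw` and
#'   `hours` (a `name` column is conventional); may be empty or `NULL`.
#' @param ef_elec Electricity emission factor (kg CO2e per kWh).
#' @param consumables Data frame with columns `mass_kg` and `ef`
#'   (kg CO2e per kg); may be empty or `NULL`.
#' @return Carbon footprint in kg CO2e per sample (scalar).
#' @examples
#' carbon_footprint(
#'   energy = data.frame(name = "spectrophotometer", power_kw = 0.1, hours = 0.5),
#'   ef_elec = 0.5
#' )  # 0.025
#' @export
carbon_footprint <- function(energy = NULL, ef_elec = 0.4, consumables = NULL) {
  if (ef_elec < 0) stop("ef_elec must be >= 0", call. = FALSE)
  e_term <- 0
  if (!is.null(energy) && nrow(energy)) {
    if (any(energy$power_kw < 0) || any(energy$hours < 0)) {
      stop("power and hours must be >= 0", call. = FALSE)
    }
    e_term <- sum(energy$power_kw * energy$hours * ef_elec)
  }
  c_term <- 0
  if (!is.null(consumables) && nrow(consumables)) {
    if (any(consumables$mass_kg < 0) || any(consumables$ef < 0)) {
      stop("masses and emission factors must be >= 0", call. = FALSE)
    }
    c_term <- sum(consumables$mass_kg * consumables$ef)
  }
  e_term + c_term
}

#' Example emission-factor inventory
#'
#' A small editable inventory for [carbon_footprint()]: the instruments of a
#' UV-spectrophotometric assay and generic cradle-to-gate emission factors for
#' common consumables. Values are illustrative defaults, meant to be replaced
#' by the user's own factors.
#'
#' @return List with `energy`, `ef_elec` and `consumables` ready to pass to
#'   [carbon_footprint()].
#' @export
example_cf_inventory <- function() {
  list(
    energy = tibble::tibble(
      name = c("uv_spectrophotometer", "ultrasonic_bath"),
      power_kw = c(0.08, 0.25),
      hours = c(0.25, 0.1)
    ),
    ef_elec = 0.45,
    consumables = tibble::tibble(
      name = c("water_ultrapure", "pvdf_filter", "plastic_tips"),
      mass_kg = c(0.05, 0.002, 0.003),
      ef = c(0.02, 6.0, 3.5)
    )
  )
}

#' Aggregate sustainability sub-scores
#'
#' Weighted arithmetic mean of percentage sub-scores (e.g. the greenness /
#' blueness / redness / violet components of a whiteness assessment), rounded
#' half-up to the requested number of decimals. Equal weights by default.
#'
#' @param panel Data frame with a `score` column (%) and optionally `weight`,
#'   or a plain numeric vector of scores.
#' @param weights Optional weights overriding a `weight` column; must be
#'   non-negative and are normalized to sum to 1.
#' @param digits Decimals in the reported aggregate.
#' @return Aggregate score (%) as a scalar.
#' @examples
#' aggregate_scores(c(90.1, 86.2, 87.9, 70.0))  # 83.6
#' @export
aggregate_scores <- function(panel, weights = NULL, digits = 1) {
  scores <- if (is.data.frame(panel)) panel$score else as.numeric(panel)
  if (!length(scores)) stop("empty score panel", call. = FALSE)
  if (any(scores < 0 | scores > 100)) {
    stop("scores must lie in [0, 100]", call. = FALSE)
  }
  w <- weights %||% (if (is.data.frame(panel)) panel$weight else NULL) %||%
    rep(1, length(scores))
  if (length(w) != length(scores)) {
    stop("weights and scores differ in length", call. = FALSE)
  }
  if (any(w < 0) || sum(w) <= 0) {
    stop("weights must be >= 0 with a positive sum", call. = FALSE)
  }
  round_half_up(sum(scores * w) / sum(w), digits)
}
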