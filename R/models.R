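#' Resting metabolic rate from lean body mass (Cunningham)
#'
#' Estimates resting metabolic rate with the Cunningham equation,
#' RMR = 500 + 22·LBM kcal·day⁻¹, converted to watts (1 kcal = 4184 J,
#' 86 400 s per day) and expressed per kilogram of body mass so it can be
#' added directly to the mass-specific walking model.
#'
#' @param lean_mass Lean body mass, kg. Must satisfy 0 < lean_mass <= body_mass.
#' @param body_mass Body mass, kg (carried load excluded).
#' @return Resting metabolic rate, W·kg⁻¹ of body mass. Vectorized with the
#'   usual recycling.
#' @export
#' @examples
#' resting_metabolic_rate(60, 77) # ~1.145 W/kg
resting_metabolic_rate <- function(lean_mass, body_mass) {
  if (any(!is.finite(lean_mass)) || any(!is.finite(body_mass))) {
    abort("masses must be finite")
  }
  if (any(lean_mass <= 0) || any(body_mass <= 0)) {
    abort("masses must be positive")
  }
  if (any(lean_mass > body_mass + 1e-9)) {
    abort("lean_mass cannot exceed body_mass")
  }
  (500 + 22 * lean_mass) * 4184 / 86400 / body_mass
}

#' Speed-dependent level-walking component
#'
#' The level-walking cost of the backpacking model excluding resting
#' metabolism: `a + b*S^p + d*S^4` in W·kg⁻¹ (S in m·s⁻¹).
#'
#' @param speed Walking speed, m·s⁻¹. Must be non-negative; speeds above
#'   2 m·s⁻¹ lie outside the fitted walking domain and trigger a warning.
#' @param coefficients A [backpack_coefficients()] set; defaults to the
#'   published values.
#' @return Level-walking cost, W·kg⁻¹. Vectorized over `speed`.
#' @export
#' @examples
#' level_walking_terms(1.34)
level_walking_terms <- function(speed, coefficients = lcda_backpacking_coefficients()) {
  check_speed(speed)
  coefficients$a + coefficients$b * speed^coefficients$p +
    coefficients$d * speed^4
}

#' Multiplicative backpack-load factor
#'
#' The nonlinear load multiplier `1 + x*L^y`, where `L` is backpack mass
#' divided by body mass. Equals 1 for unloaded walking; light loads cause
#' small increases while heavy loads incur disproportionately greater costs.
#'
#' @param load_fraction Backpack mass / body mass, dimensionless, >= 0.
#'   Fractions above 1 (loads heavier than the body) are outside the fitted
#'   domain and trigger a warning.
#' @inheritParams level_walking_terms
#' @return Dimensionless multiplier >= 1. Vectorized over `load_fraction`.
#' @export
#' @examples
#' load_multiplier(c(0, 0.22, 0.44, 0.66))
load_multiplier <- function(load_fraction, coefficients = lcda_backpacking_coefficients()) {
  if (any(!is.finite(load_fraction))) abort("load_fraction must be finite")
  if (any(load_fraction < 0)) abort("load_fraction must be non-negative")
  if (any(load_fraction > 1)) {
    warn("load_fraction > 1 is outside the fitted domain (loads up to 100% body mass)")
  }
  1 + coefficients$x * load_fraction^coefficients$y
}

#' Metabolic cost of walking on a grade
#'
#' The graded-walking adjustment expressed with decimal grades (rise/run):
#' \deqn{\dot{M}_{Grade} = 34\,S\,G\,(1 - 1.05^{\,1 - 1.1^{\,100G + 32}})}
#' It is zero on the level or when standing, positive uphill, and negative
#' (an energy saving) on moderate downhills, with the exponential damping
#' factor reproducing the diminishing return of steeper descents.
#'
#' @param speed Walking speed, m·s⁻¹, >= 0.
#' @param grade Decimal grade, rise/run (percent grade / 100). May be
#'   negative. Values with |grade| beyond `max_abs_grade` lie outside the
#'   validity window of the source grade relationship and trigger a warning
#'   rather than an error.
#' @param max_abs_grade Validity window half-width for `grade` (default 0.4).
#' @return Grade cost, W·kg⁻¹. Vectorized over `speed` and `grade`.
#' @export
#' @examples
#' grade_cost(1.34, 0.10)
grade_cost <- function(speed, grade, max_abs_grade = 0.4) {
  check_speed(speed)
  if (any(!is.finite(grade))) abort("grade must be finite")
  if (any(abs(grade) > max_abs_grade)) {
    warn(sprintf("|grade| > %.2g is outside the validity window of the grade model",
                 max_abs_grade))
  }
  34 * speed * grade * (1 - 1.05^(1 - 1.1^(100 * grade + 32)))
}

#' Predict metabolic rate during loaded walking
#'
#' Evaluates the full backpacking model
#' \deqn{\dot{M} = (\dot{M}_{Rest} + a + \eta(b S^p + d S^4) +
#'   \dot{M}_{Grade}) (1 + x L_{Bp}^y)}
#' in W per kg body mass. With `terrain = 1` and `grade = 0` this reduces
#' exactly to `(m_rest + level_walking_terms(speed)) * load_multiplier(load)`.
#' The load multiplier applies to the full bracket including resting
#' metabolism, as the model's parenthesization dictates; setting
#' `net_of_resting = TRUE` applies the multiplier only to the exercise
#' component (a research variant, not the published model).
#'
#' @param m_rest Resting metabolic rate, W·kg⁻¹ (see
#'   [resting_metabolic_rate()]).
#' @param speed Walking speed, m·s⁻¹.
#' @param load_fraction Backpack mass / body mass (default 0).
#' @param grade Decimal grade, rise/run (default 0).
#' @param terrain Terrain coefficient eta (default 1.0, treadmill/pavement).
#' @param net_of_resting If `TRUE`, the load multiplier excludes `m_rest`.
#' @inheritParams level_walking_terms
#' @return Predicted metabolic rate, W·kg⁻¹ of body mass. Vectorized.
#' @export
#' @examples
#' m_rest <- resting_metabolic_rate(60, 77)
#' predict_metabolic_rate(m_rest, speed = 1.34, load_fraction = 0.66)
predict_metabolic_rate <- function(m_rest, speed, load_fraction = 0, grade = 0,
                                   terrain = 1,
                                   coefficients = lcda_backpacking_coefficients(),
                                   net_of_resting = FALSE) {
  if (any(!is.finite(m_rest)) || any(m_rest < 0)) {
    abort("m_rest must be finite and non-negative")
  }
  if (any(!is.finite(terrain)) || any(terrain <= 0)) {
    abort("terrain coefficient must be positive")
  }
  check_speed(speed)
  mult <- load_multiplier(load_fraction, coefficients)
  g <- grade_cost(speed, grade)
  # terrain distributed over the two speed terms so that the neutral case
  # (terrain = 1, grade = 0) reduces bit-identically to level_walking_terms
  exercise <- coefficients$a + terrain * coefficients$b * speed^coefficients$p +
    terrain * coefficients$d * speed^4 + g
  if (net_of_resting) {
    m_rest + exercise * mult
  } else {
    (m_rest + exercise) * mult
  }
}

#' Add model predictions to a trial table
#'
#' Data-frame-first wrapper around [predict_metabolic_rate()]: takes a tibble
#' of trial conditions and appends a `.pred_m_wkg` column. Column names
#' follow the trial CSV schema; missing optional columns default to level
#' treadmill walking.
#'
#' @param data A data frame with columns `m_rest_wkg`, `speed_mps`, and
#'   optionally `load_fraction`, `grade_decimal`, `terrain_coefficient`.
#' @inheritParams level_walking_terms
#' @return `data` as a tibble with a `.pred_m_wkg` column appended.
#' @export
#' @examples
#' tibble::tibble(m_rest_wkg = 1.1, speed_mps = c(0, 1.34), load_fraction = 0.44) |>
#'   add_metabolic_predictions()
add_metabolic_predictions <- function(data, coefficients = lcda_backpacking_coefficients()) {
  need <- c("m_rest_wkg", "speed_mps")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("missing required columns: ", paste(miss, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  lf <- if ("load_fraction" %in% names(data)) data$load_fraction else 0
  gr <- if ("grade_decimal" %in% names(data)) data$grade_decimal else 0
  eta <- if ("terrain_coefficient" %in% names(data)) data$terrain_coefficient else 1
  dplyr::mutate(data, .pred_m_wkg = predict_metabolic_rate(
    m_rest = .data$m_rest_wkg, speed = .data$speed_mps,
    load_fraction = lf, grade = gr, terrain = eta,
    coefficients = coefficients
  ))
}

#' Convert between mass-specific and absolute metabolic rates
#'
#' All model rates are expressed per kilogram of body mass (carried load is
#' excluded from the denominator). These helpers convert to and from
#' absolute watts.
#'
#' @param m_wkg Mass-specific rate, W·kg⁻¹ of body mass.
#' @param watts Absolute rate, W.
#' @param body_mass Body mass, kg.
#' @return A numeric vector of the converted rate.
#' @export
wkg_to_watts <- function(m_wkg, body_mass) {
  if (any(body_mass <= 0)) abort("body_mass must be positive")
  m_wkg * body_mass
}

#' @rdname wkg_to_watts
#' @export
watts_to_wkg <- function(watts, body_mass) {
  if (any(body_mass <= 0)) abort("body_mass must be positive")
  watts / body_mass
}

#' Convert percent grade to decimal grade
#'
#' @param percent Grade in percent (100 × rise/run).
#' @return Decimal grade (rise/run).
#' @export
percent_to_decimal_grade <- function(percent) percent / 100

check_speed <- function(speed) {
  if (any(!is.finite(speed))) abort("speed must be finite")
  if (any(speed < 0)) abort("speed must be non-negative")
  if (any(speed > 2.0)) {
    warn("speed > 2 m/s approaches the walk-run transition, outside the fitted domain")
  }
  invisible(speed)
}
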