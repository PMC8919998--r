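#' Pandolf load-carriage equation
#'
#' Comparator prediction from the classic Pandolf load-carriage model,
#' transcribed from its published form:
#' \deqn{M[W] = 1.5 W + 2.0 (W + L)(L/W)^2 + \eta (W + L)(1.5 V^2 + 0.35 V G)}
#' with body mass `W` (kg), load mass `L` (kg), speed `V` (m·s⁻¹), grade `G`
#' in percent, and terrain factor eta. The result is divided by body mass so
#' it is comparable with the mass-specific backpacking model. The downhill
#' correction of later variants is deliberately excluded: comparisons here
#' are level-walking only.
#'
#' @param body_mass Body mass, kg (> 0).
#' @param load_mass Carried load, kg (>= 0).
#' @param speed Walking speed, m·s⁻¹ (>= 0).
#' @param grade_percent Grade in percent (default 0).
#' @param terrain_factor Terrain factor eta (default 1.0).
#' @return Predicted metabolic rate, W·kg⁻¹ of body mass. Vectorized.
#' @export
#' @examples
#' pandolf_metabolic_rate(70, 35, 1.34)
pandolf_metabolic_rate <- function(body_mass, load_mass, speed,
                                   grade_percent = 0, terrain_factor = 1) {
  if (any(body_mass <= 0)) abort("body_mass must be positive")
  if (any(load_mass < 0)) abort("load_mass must be non-negative")
  if (any(speed < 0)) abort("speed must be non-negative")
  watts <- 1.5 * body_mass +
    2.0 * (body_mass + load_mass) * (load_mass / body_mass)^2 +
    terrain_factor * (body_mass + load_mass) *
      (1.5 * speed^2 + 0.35 * speed * grade_percent)
  watts / body_mass
}

#' Minimum-mechanics load-carriage prediction
#'
#' Comparator embodying the minimum-mechanics premise that body mass and
#' external load mass cause the same linear increase in metabolic energy
#' expenditure: the absolute rate is a level-walking economy curve per
#' kilogram of *total* supported mass, scaled by (body + load). Expressed
#' per kilogram of body mass this becomes
#' \deqn{\dot{M} = (1 + L/W)\,(c_0 + c_2 S^2)}
#'
#' The economy-curve coefficients are a synthetic calibration chosen to
#' match typical treadmill walking economy (gross cost ~3.6 W·kg⁻¹ at
#' 1.34 m·s⁻¹); the cited model's exact published coefficients are not
#' reproduced here, and both coefficients can be overridden. The structural
#' contracts — exact linear scaling with total mass, and monotone increase
#' of the per-kg-body-mass cost with load — hold for any positive
#' calibration.
#'
#' @inheritParams pandolf_metabolic_rate
#' @param economy_intercept Standing/postural term of the economy curve,
#'   W per kg total mass (default 1.25).
#' @param economy_quadratic Quadratic speed coefficient of the economy
#'   curve, W·s²·m⁻² per kg total mass (default 1.30).
#' @return Predicted metabolic rate, W·kg⁻¹ of body mass. Vectorized.
#' @export
#' @examples
#' minimum_mechanics_metabolic_rate(77, 0.66 * 77, 1.34)
minimum_mechanics_metabolic_rate <- function(body_mass, load_mass, speed,
                                             economy_intercept = 1.25,
                                             economy_quadratic = 1.30) {
  if (any(body_mass <= 0)) abort("body_mass must be positive")
  if (any(load_mass < 0)) abort("load_mass must be non-negative")
  if (any(speed < 0)) abort("speed must be non-negative")
  per_kg_total <- economy_intercept + economy_quadratic * speed^2
  (body_mass + load_mass) / body_mass * per_kg_total
}
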