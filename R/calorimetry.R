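# Energy-equivalent coefficients for indirect calorimetry: watts per mL/s
# STPD of O2 uptake and CO2 production, transcribed from the published
# energy-equivalent equation derived from the updated nonprotein respiratory
# quotient table. Single point of verification; never inline these numbers.
calorimetry_energy_equivalents <- c(o2 = 16.58, co2 = 4.51)

#' Respiratory exchange ratio
#'
#' RER = V̇CO₂ / V̇O₂. For valid steady-state aerobic calorimetry the RER
#' must lie within the respiratory quotient range \[0.7, 1.0\] (both ends
#' inclusive).
#'
#' @param vo2 Oxygen uptake, mL·s⁻¹ STPD (> 0).
#' @param vco2 Carbon dioxide production, mL·s⁻¹ STPD (>= 0).
#' @return RER, dimensionless. Vectorized.
#' @export
respiratory_exchange_ratio <- function(vo2, vco2) {
  if (any(vo2 <= 0)) abort("vo2 must be positive")
  if (any(vco2 < 0)) abort("vco2 must be non-negative")
  vco2 / vo2
}

#' Metabolic rate from respiratory gas exchange
#'
#' Computes energy expenditure from steady-state V̇O₂ and V̇CO₂ via the
#' energy-equivalent form `W = 16.58·V̇O₂ + 4.51·V̇CO₂` (flows in mL·s⁻¹
#' STPD) and divides by body mass. The form is linear and homogeneous of
#' degree 1 in the two gas flows. Samples whose RER falls outside
#' \[0.7, 1.0\] are rejected with an error when `check_rer = TRUE`
#' (steady-state aerobic trials outside that range are excluded, not
#' reinterpreted).
#'
#' @inheritParams respiratory_exchange_ratio
#' @param body_mass Body mass, kg (> 0).
#' @param check_rer Reject samples with RER outside \[0.7, 1.0\]?
#' @return Metabolic rate, W·kg⁻¹ of body mass. Vectorized.
#' @export
#' @examples
#' metabolic_rate_from_gas(vo2 = 20, vco2 = 17, body_mass = 77)
metabolic_rate_from_gas <- function(vo2, vco2, body_mass, check_rer = TRUE) {
  if (any(body_mass <= 0)) abort("body_mass must be positive")
  rer <- respiratory_exchange_ratio(vo2, vco2)
  if (check_rer && any(rer < 0.7 | rer > 1.0)) {
    abort("RER outside [0.7, 1.0]: trial fails steady-state aerobic QC")
  }
  watts <- calorimetry_energy_equivalents[["o2"]] * vo2 +
    calorimetry_energy_equivalents[["co2"]] * vco2
  watts / body_mass
}

#' Metabolic rate from V̇O₂ alone under an assumed RER
#'
#' For data sources that report only oxygen uptake, V̇CO₂ is reconstructed
#' as `rer * vo2` (default assumed RER 0.85) and the calculation delegates
#' to [metabolic_rate_from_gas()].
#'
#' @inheritParams metabolic_rate_from_gas
#' @param rer Assumed respiratory exchange ratio, in \[0.7, 1.0\].
#' @return Metabolic rate, W·kg⁻¹. Vectorized.
#' @export
m_from_vo2_assumed_rer <- function(vo2, body_mass, rer = 0.85) {
  if (any(rer < 0.7 | rer > 1.0)) abort("assumed RER must lie in [0.7, 1.0]")
  metabolic_rate_from_gas(vo2, rer * vo2, body_mass)
}

#' Invert the calorimetry equation
#'
#' Given a mass-specific metabolic rate and an RER, recovers the gas flows
#' that produce it. Used by the synthetic-study generator and as an
#' algebraic round-trip oracle.
#'
#' @param m_wkg Metabolic rate, W·kg⁻¹.
#' @param rer Respiratory exchange ratio.
#' @param body_mass Body mass, kg.
#' @return A tibble with columns `vo2` and `vco2` (mL·s⁻¹ STPD).
#' @export
invert_gas <- function(m_wkg, rer, body_mass) {
  if (any(rer < 0)) abort("rer must be non-negative")
  vo2 <- m_wkg * body_mass /
    (calorimetry_energy_equivalents[["o2"]] +
       calorimetry_energy_equivalents[["co2"]] * rer)
  tibble::tibble(vo2 = vo2, vco2 = rer * vo2)
}

#' Steady-state quality control between two 30-s windows
#'
#' Applies the steady-state screens used for treadmill calorimetry trials:
#' the coefficient of variation of each gas between the first and second
#' 30 s of the final minute must be below `cv_limit` (default 10%), and the
#' pooled final-minute RER must lie within `rer_range` (default
#' \[0.7, 1.0\], both ends inclusive). The two-point CV uses the sample
#' (n − 1) standard deviation, |x₁ − x₂|/√2, divided by the window mean.
#'
#' @param vo2_first,vo2_second V̇O₂ means of the two 30-s windows, mL·s⁻¹.
#' @param vco2_first,vco2_second V̇CO₂ means of the two windows, mL·s⁻¹.
#' @param cv_limit CV pass threshold, percent (strict inequality).
#' @param rer_range Inclusive RER bounds for the pooled final minute.
#' @return A tibble with columns `cv_vo2`, `cv_vco2`, `rer`, `passed`,
#'   and `reasons` (semicolon-separated failure labels, `""` when passed).
#' @export
#' @examples
#' steady_state_qc(3.0, 3.5, 2.6, 2.9)
steady_state_qc <- function(vo2_first, vo2_second, vco2_first, vco2_second,
                            cv_limit = 10, rer_range = c(0.7, 1.0)) {
  if (any(c(vo2_first, vo2_second) <= 0)) abort("vo2 windows must be positive")
  if (any(c(vco2_first, vco2_second) < 0)) abort("vco2 windows must be non-negative")
  cv2 <- function(a, b) {
    m <- (a + b) / 2
    if (any(m <= 0)) abort("window means must be positive")
    abs(a - b) / sqrt(2) / m * 100
  }
  cv_vo2 <- cv2(vo2_first, vo2_second)
  cv_vco2 <- cv2(vco2_first, vco2_second)
  rer <- (vco2_first + vco2_second) / (vo2_first + vo2_second)
  n <- length(rer)
  cv_vo2 <- rep_len(cv_vo2, n); cv_vco2 <- rep_len(cv_vco2, n)
  reasons <- purrr::pmap_chr(
    list(cv_vo2, cv_vco2, rer),
    function(cvo, cvc, r) {
      labs <- c(
        if (cvo >= cv_limit) "cv_vo2_exceeded",
        if (cvc >= cv_limit) "cv_vco2_exceeded",
        if (r < rer_range[1] || r > rer_range[2]) "rer_out_of_range"
      )
      paste(labs, collapse = ";")
    }
  )
  tibble::tibble(
    cv_vo2 = cv_vo2, cv_vco2 = cv_vco2, rer = rer,
    passed = reasons == "", reasons = reasons
  )
}

#' Apply steady-state QC to a trial table
#'
#' Runs [steady_state_qc()] over the gas-window columns of a trial table and
#' appends the QC columns (`cv_vo2`, `cv_vco2`, `rer`, `qc_passed`,
#' `qc_reasons`). Rows are flagged, never dropped.
#'
#' @param data A trial table with columns `vo2_first30`, `vo2_second30`,
#'   `vco2_first30`, `vco2_second30` (mL·s⁻¹ STPD).
#' @inheritParams steady_state_qc
#' @return `data` as a tibble with QC columns appended.
#' @export
qc_trials <- function(data, cv_limit = 10, rer_range = c(0.7, 1.0)) {
  need <- c("vo2_first30", "vo2_second30", "vco2_first30", "vco2_second30")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("missing gas-window columns: ", paste(miss, collapse = ", ")))
  }
  qc <- steady_state_qc(data$vo2_first30, data$vo2_second30,
                        data$vco2_first30, data$vco2_second30,
                        cv_limit = cv_limit, rer_range = rer_range)
  dplyr::bind_cols(
    tibble::as_tibble(data),
    dplyr::rename(qc, qc_passed = "passed", qc_reasons = "reasons")
  )
}

#' Convert gas flow from L·min⁻¹ to mL·s⁻¹
#'
#' Gas flows are standardized to mL·s⁻¹ STPD internally; source studies
#' report mixed units, so conversions must be explicit, never guessed.
#'
#' @param l_min Flow in L·min⁻¹.
#' @return Flow in mL·s⁻¹.
#' @export
lmin_to_mls <- function(l_min) l_min * 1000 / 60
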