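#' Study design for a synthetic heavy load-carriage study
#'
#' Captures the protocol emulated by the generator: four backpack loads
#' (0, 22, 44, 66% body mass), and per load one standing trial, three fixed
#' walking speeds (0.45, 0.89, 1.34 m·s⁻¹) and one top speed drawn from the
#' load-specific distribution of highest completed incremental speeds
#' (means 1.96, 1.86, 1.67, 1.48 m·s⁻¹; SDs 0.04, 0.12, 0.16, 0.12), snapped
#' down to the incremental-test grid (1.16 + 0.09·j m·s⁻¹, capped at 1.97).
#'
#' @param load_fractions Backpack loads as fractions of body mass (ascending).
#' @param fixed_speeds Fixed walking speeds, m·s⁻¹.
#' @param incremental_start,incremental_step,incremental_max Incremental-test
#'   speed grid, m·s⁻¹.
#' @param top_speed_means,top_speed_sds Top-speed distribution per load, m·s⁻¹
#'   (same length and order as `load_fractions`).
#' @return A list of class `ruckmet_design`.
#' @export
study_design <- function(load_fractions = c(0, 0.22, 0.44, 0.66),
                         fixed_speeds = c(0.45, 0.89, 1.34),
                         incremental_start = 1.16,
                         incremental_step = 0.09,
                         incremental_max = 1.97,
                         top_speed_means = c(1.96, 1.86, 1.67, 1.48),
                         top_speed_sds = c(0.04, 0.12, 0.16, 0.12)) {
  if (is.unsorted(load_fractions)) abort("load_fractions must be ascending")
  if (length(top_speed_means) != length(load_fractions) ||
      length(top_speed_sds) != length(load_fractions)) {
    abort("top-speed means/SDs must align with load_fractions")
  }
  if (any(fixed_speeds <= 0) || incremental_start <= 0 || incremental_step <= 0) {
    abort("speeds must be positive")
  }
  structure(
    list(load_fractions = load_fractions, fixed_speeds = fixed_speeds,
         incremental_start = incremental_start,
         incremental_step = incremental_step,
         incremental_max = incremental_max,
         top_speed_means = top_speed_means, top_speed_sds = top_speed_sds),
    class = "ruckmet_design"
  )
}

#' Noise model for synthetic trials
#'
#' Observed rates are the model surface plus a participant random intercept
#' `u_i ~ N(0, participant_intercept_sd²)` and residual noise
#' `e_ij ~ N(0, residual_sd²)`. The defaults (0.35 and 0.45 W·kg⁻¹) are a
#' calibration: their pooled SD, sqrt(0.35² + 0.45²) ≈ 0.57 W·kg⁻¹, sits
#' near the ~0.6 W·kg⁻¹ pooled prediction-error SD typical of steady-state
#' load-carriage validation data, which report only the pooled figure, not
#' the two components. `rer_range` bounds the RER sampled when gas traces
#' are back-computed.
#'
#' @param residual_sd Within-participant residual SD, W·kg⁻¹.
#' @param participant_intercept_sd Between-participant intercept SD, W·kg⁻¹.
#' @param rer_range RER sampling range for emitted gas, inside \[0.7, 1.0\].
#' @return A list of class `ruckmet_noise`.
#' @export
noise_model <- function(residual_sd = 0.45,
                        participant_intercept_sd = 0.35,
                        rer_range = c(0.80, 0.95)) {
  if (residual_sd < 0 || participant_intercept_sd < 0) abort("SDs must be >= 0")
  if (rer_range[1] < 0.7 || rer_range[2] > 1.0 || rer_range[1] > rer_range[2]) {
    abort("rer_range must lie within [0.7, 1.0]")
  }
  structure(
    list(residual_sd = residual_sd,
         participant_intercept_sd = participant_intercept_sd,
         rer_range = rer_range),
    class = "ruckmet_noise"
  )
}

#' Generate a synthetic participant cohort
#'
#' Draws anthropometrics from normal distributions matching a healthy,
#' active military-age cohort — age 25 ± 7 yr, height 1.74 ± 0.07 m, body
#' mass 77 ± 15 kg, body fat 21.4% ± 5.0% — truncated to plausibility
#' windows (body mass 48–120 kg, height 1.57–1.90 m, age 18–45 yr, body fat
#' 8–40%). Lean mass is `body_mass * (1 - body_fat_fraction)`, and the
#' resting metabolic rate column is precomputed with
#' [resting_metabolic_rate()]. Deterministic given the seed.
#'
#' @param n Number of participants (default 30).
#' @param n_females Number of females (default 3); the first `n_females`
#'   rows are female. Sex affects only the labels, not the anthropometric
#'   distributions or the metabolic model.
#' @param seed Integer seed.
#' @return A tibble with columns `participant_id`, `sex`, `age`, `height_m`,
#'   `body_mass_kg`, `body_fat_fraction`, `lean_mass_kg`, `m_rest_wkg`.
#' @export
#' @examples
#' generate_participants(n = 5, n_females = 1, seed = 1)
generate_participants <- function(n = 30, n_females = 3, seed = 1L) {
  withr::with_seed(seed, draw_participants(n, n_females))
}

draw_participants <- function(n, n_females) {
  if (n < 1) abort("n must be at least 1")
  if (n_females < 0 || n_females > n) abort("n_females must lie in [0, n]")
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    sex = rep(c("female", "male"), c(n_females, n - n_females)),
    age = rtruncnorm(n, 25, 7, 18, 45),
    height_m = rtruncnorm(n, 1.74, 0.07, 1.57, 1.90),
    body_mass_kg = rtruncnorm(n, 77, 15, 48, 120),
    body_fat_fraction = rtruncnorm(n, 0.214, 0.050, 0.08, 0.40)
  ) |>
    dplyr::mutate(
      lean_mass_kg = .data$body_mass_kg * (1 - .data$body_fat_fraction),
      m_rest_wkg = resting_metabolic_rate(.data$lean_mass_kg, .data$body_mass_kg)
    )
}

# Rejection-sampled truncated normal; bounds are a hard plausibility window.
# mean/sd/lower/upper may be vectors recycled against n.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(lower >= upper)) abort("impossible truncation window")
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] < lower[bad] | out[bad] > upper[bad]]
    guard <- guard + 1
    if (guard > 10000) abort("impossible truncation window: acceptance rate ~ 0")
  }
  out
}

#' Generate one participant's trial conditions
#'
#' For each load: one standing trial (S = 0), the three fixed walking
#' speeds, and one top speed drawn from the load-specific distribution
#' (truncated at ±2 SD), snapped *down* to the incremental speed grid and
#' capped at the grid maximum. Top speeds are forced non-increasing with
#' load within the participant, as heavier packs always terminate the
#' incremental test at or below the lighter-pack speed.
#'
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return A tibble with columns `load_fraction`, `speed_mps`, `trial_type`
#'   (`"standing"`, `"fixed"`, `"top"`); 5 rows per load.
#' @export
generate_protocol <- function(design = study_design(), seed = 1L) {
  withr::with_seed(seed, draw_protocol(design))
}

draw_protocol <- function(design) {
  tops_raw <- rtruncnorm(
    length(design$load_fractions),
    design$top_speed_means, design$top_speed_sds,
    design$top_speed_means - 2 * design$top_speed_sds,
    design$top_speed_means + 2 * design$top_speed_sds
  )
  tops <- snap_to_grid(tops_raw, design)
  tops <- cummin(tops) # non-increasing in load
  purrr::map2_dfr(design$load_fractions, tops, function(lf, top) {
    tibble::tibble(
      load_fraction = lf,
      speed_mps = c(0, design$fixed_speeds, top),
      trial_type = c("standing", rep("fixed", length(design$fixed_speeds)), "top")
    )
  })
}

# Floor to the incremental grid 1.16 + 0.09*j, clamped to [start, max].
snap_to_grid <- function(speed, design) {
  j <- floor((speed - design$incremental_start) / design$incremental_step + 1e-9)
  j <- pmax(j, 0)
  pmin(design$incremental_start + design$incremental_step * j,
       design$incremental_max)
}

#' Simulate a complete synthetic load-carriage study
#'
#' Generates a cohort, each participant's protocol, and observed metabolic
#' rates from a known ground-truth coefficient set:
#' `M_ij = predict_metabolic_rate(m_rest_i, cond_ij, coefficients) + u_i + e_ij`,
#' with the residual draw repeated as needed so every observed rate is
#' positive. When `emit_gas = TRUE` the calorimetry equation is inverted at
#' a sampled RER and the gas trace is split into two 30-s windows with a
#' small multiplicative jitter (±0.5–2%), so that every emitted trial passes
#' [steady_state_qc()] and the pooled final-minute rate reproduces the
#' stored `m_wkg` exactly. The whole study is deterministic given
#' `(seed, design, coefficients, noise)`.
#'
#' @inheritParams generate_participants
#' @param coefficients Ground-truth [backpack_coefficients()] (default: the
#'   published set).
#' @param design A [study_design()].
#' @param noise A [noise_model()].
#' @param emit_gas Back-compute V̇O₂/V̇CO₂ windows?
#' @param exclusion_rate Probability that a top-speed trial is excluded
#'   (emulating RER > 1 terminations; default 0, i.e. keep the full
#'   30 × 4 × 5 = 600-trial design).
#' @return A list of class `ruckmet_study` with `participants`, `trials`
#'   (the trial-schema tibble), `coefficients`, `design`, `noise`, `seed`.
#' @export
#' @examples
#' study <- simulate_study(n = 4, n_females = 1, seed = 42)
#' dplyr::count(study$trials, load_fraction)
simulate_study <- function(n = 30, n_females = 3,
                           coefficients = lcda_backpacking_coefficients(),
                           design = study_design(),
                           noise = noise_model(),
                           seed = 1L,
                           emit_gas = TRUE,
                           exclusion_rate = 0) {
  withr::with_seed(seed, {
    participants <- draw_participants(n, n_females)
    conds <- purrr::map_dfr(seq_len(n), function(i) {
      dplyr::bind_cols(participants[i, ], draw_protocol(design))
    })
    u <- rnorm(n, 0, noise$participant_intercept_sd)
    names(u) <- participants$participant_id
    mu <- predict_metabolic_rate(
      m_rest = conds$m_rest_wkg, speed = conds$speed_mps,
      load_fraction = conds$load_fraction, coefficients = coefficients
    ) + unname(u[conds$participant_id])
    m_obs <- mu + rnorm(nrow(conds), 0, noise$residual_sd)
    bad <- which(m_obs <= 0)
    guard <- 0
    while (length(bad) > 0) { # truncate observed rates to be positive
      m_obs[bad] <- mu[bad] + rnorm(length(bad), 0, noise$residual_sd)
      bad <- bad[m_obs[bad] <= 0]
      guard <- guard + 1
      if (guard > 10000) abort("cannot generate positive rates; check noise model")
    }
    trials <- tibble::tibble(
      participant_id = conds$participant_id,
      sex = conds$sex,
      body_mass_kg = conds$body_mass_kg,
      m_rest_wkg = conds$m_rest_wkg,
      load_fraction = conds$load_fraction,
      speed_mps = conds$speed_mps,
      grade_decimal = 0,
      terrain_coefficient = 1,
      trial_type = conds$trial_type,
      m_wkg = m_obs
    )
    if (emit_gas) {
      rer <- runif(nrow(trials), noise$rer_range[1], noise$rer_range[2])
      gas <- invert_gas(trials$m_wkg, rer, trials$body_mass_kg)
      jitter <- runif(nrow(trials), 0.005, 0.02) *
        sample(c(-1, 1), nrow(trials), replace = TRUE)
      trials$vo2_first30 <- gas$vo2 * (1 + jitter)
      trials$vo2_second30 <- gas$vo2 * (1 - jitter)
      trials$vco2_first30 <- rer * trials$vo2_first30
      trials$vco2_second30 <- rer * trials$vo2_second30
    }
    if (exclusion_rate > 0) {
      drop <- trials$trial_type == "top" &
        runif(nrow(trials)) < exclusion_rate
      trials <- trials[!drop, ]
    }
    structure(
      list(participants = participants, trials = trials,
           coefficients = coefficients, design = design, noise = noise,
           seed = seed),
      class = "ruckmet_study"
    )
  })
}

#' @export
print.ruckmet_study <- function(x, ...) {
  cat("<ruckmet_study> ", nrow(x$participants), " participants, ",
      nrow(x$trials), " trials (seed ", x$seed, ")\n", sep = "")
  cat("ground truth: ")
  print(x$coefficients)
  invisible(x)
}

#' Write the ground truth of a synthetic study as JSON
#'
#' Records the generating coefficients, seed and noise model alongside the
#' emitted trial CSV so recovery can be scored later.
#'
#' @param study A `ruckmet_study`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(study, path) {
  truth <- list(
    coefficients = study$coefficients[c("name", "a", "b", "p", "d", "x", "y")],
    noise = study$noise[c("residual_sd", "participant_intercept_sd")],
    rer_range = study$noise$rer_range,
    seed = study$seed,
    n_participants = nrow(study$participants),
    n_trials = nrow(study$trials)
  )
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
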