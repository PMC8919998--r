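TRIALS_SCHEMA_VERSION <- "ruckmet-trials-v1"

trials_known_columns <- c(
  "participant_id", "sex", "body_mass_kg", "m_rest_wkg",
  "load_fraction", "speed_mps", "grade_decimal", "terrain_coefficient",
  "trial_type",
  "vo2_first30", "vo2_second30", "vco2_first30", "vco2_second30",
  "m_wkg"
)

#' Read and write trial tables
#'
#' Trials are exchanged as CSV with a one-line schema header
#' (`# ruckmet-trials-v1`). Readers reject unknown schema versions and
#' unknown columns rather than guessing; gas flows are mL·s⁻¹ STPD (use
#' [lmin_to_mls()] before writing if a source reports L·min⁻¹). Required
#' columns are `participant_id`, `load_fraction`, `speed_mps`; gas windows,
#' body mass, resting rate and a precomputed `m_wkg` are optional.
#'
#' When gas-window columns are present, QC columns are appended (rows are
#' flagged, never dropped, unless `apply_qc = TRUE`) and `m_wkg` is filled
#' from indirect calorimetry where missing. When only V̇O₂ windows are
#' present, supply `assume_rer` to reconstruct V̇CO₂ at an assumed RER, the
#' convention for historical sources that reported oxygen uptake only.
#'
#' @param path File path.
#' @param apply_qc Drop rows failing steady-state QC (default `FALSE`:
#'   flag only)?
#' @param assume_rer Assumed RER for the V̇O₂-only path (default `NULL`).
#' @return `read_trials()` returns a tibble (with `qc_passed`/`qc_reasons`
#'   columns when gas data are present); `write_trials()` returns `path`
#'   invisibly.
#' @export
read_trials <- function(path, apply_qc = FALSE, assume_rer = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  header <- readLines(path, n = 1)
  version <- sub("^#\\s*", "", header)
  if (!startsWith(header, "#") || version != TRIALS_SCHEMA_VERSION) {
    abort(paste0("unsupported trial schema header: '", header,
                 "' (expected '# ", TRIALS_SCHEMA_VERSION, "')"))
  }
  d <- readr::read_csv(path, skip = 1, show_col_types = FALSE,
                       progress = FALSE)
  unknown <- setdiff(names(d), trials_known_columns)
  if (length(unknown) > 0) {
    abort(paste0("unknown columns in ", path, ": ",
                 paste(unknown, collapse = ", ")))
  }
  need <- c("participant_id", "load_fraction", "speed_mps")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    abort(paste0("missing required columns in ", path, ": ",
                 paste(miss, collapse = ", ")))
  }
  gas_cols <- c("vo2_first30", "vo2_second30", "vco2_first30", "vco2_second30")
  has_gas <- all(gas_cols %in% names(d))
  vo2_only <- all(gas_cols[1:2] %in% names(d)) && !has_gas
  if (vo2_only && !is.null(assume_rer)) {
    d$vco2_first30 <- assume_rer * d$vo2_first30
    d$vco2_second30 <- assume_rer * d$vo2_second30
    has_gas <- TRUE
  }
  if (has_gas) {
    d <- qc_trials(d)
    if ("body_mass_kg" %in% names(d)) {
      m_gas <- metabolic_rate_from_gas(
        (d$vo2_first30 + d$vo2_second30) / 2,
        (d$vco2_first30 + d$vco2_second30) / 2,
        d$body_mass_kg, check_rer = FALSE
      )
      if (!"m_wkg" %in% names(d)) d$m_wkg <- NA_real_
      d$m_wkg <- dplyr::coalesce(d$m_wkg, m_gas)
    }
    if (apply_qc) d <- d[d$qc_passed, ]
  }
  d
}

#' @rdname read_trials
#' @param trials A trial tibble (e.g. `simulate_study(...)$trials`).
#' @export
write_trials <- function(trials, path) {
  unknown <- setdiff(names(trials), trials_known_columns)
  if (length(unknown) > 0) {
    abort(paste0("refusing to write non-schema columns: ",
                 paste(unknown, collapse = ", ")))
  }
  writeLines(paste0("# ", TRIALS_SCHEMA_VERSION), path)
  readr::write_csv(trials, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Write a fit result as JSON
#'
#' Serializes the fitted coefficients together with the run settings and a
#' convergence-trace summary.
#'
#' @param fit A `ruckmet_fit`.
#' @param path Output path.
#' @param init Optional starting coefficients to record.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, init = NULL) {
  out <- list(
    coefficients = fit$coefficients[c("name", "a", "b", "p", "d", "x", "y")],
    residual_sd = fit$residual_sd,
    participant_intercept_sd = fit$participant_intercept_sd,
    converged = fit$converged,
    n_obs = fit$n_obs,
    n_participants = fit$n_participants,
    objective = fit$objective,
    n_iterations = nrow(fit$trace),
    bounds = default_fit_bounds()
  )
  if (!is.null(init)) {
    out$init <- init[c("name", "a", "b", "p", "d", "x", "y")]
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
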