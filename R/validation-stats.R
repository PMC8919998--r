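#' Cluster-weighted bias of paired differences
#'
#' Estimates the grand-mean paired difference (predicted − measured) while
#' accounting for repeated measures within participants and unequal numbers
#' of observations per participant. A one-way random-intercept structure is
#' assumed; the two variance components are estimated by the closed-form
#' method-of-moments (ANOVA) estimator and the bias is the exact
#' generalized-least-squares combination of participant means with weights
#' \eqn{w_i = n_i / (n_i \tau^2 + \sigma^2)}. For balanced data this reduces
#' to the unweighted mean of participant means. `bias_sd` is the sample SD
#' of the pooled differences, matching the conventional "bias ± SD"
#' presentation; inference should use the clustered estimators.
#'
#' @param difference Paired differences (predicted − measured), W·kg⁻¹.
#' @param participant_id Cluster labels, one per difference.
#' @return A list with `bias`, `bias_sd`, `tau2` (between-participant
#'   variance), `sigma2` (within-participant variance), `n_pairs`,
#'   `n_participants`.
#' @export
#' @examples
#' clustered_bias(c(-1, -1, 0, 0, 1, 1), rep(c("a", "b", "c"), each = 2))
clustered_bias <- function(difference, participant_id) {
  if (length(difference) != length(participant_id)) {
    abort("difference and participant_id must have the same length")
  }
  if (any(!is.finite(difference))) abort("differences must be finite")
  id <- as.character(participant_id)
  if (any(!nzchar(id))) abort("participant_id labels must be non-empty")
  g <- length(unique(id))
  if (g < 2) {
    warn("single participant: falling back to the simple mean difference")
    return(list(bias = mean(difference), bias_sd = if (length(difference) > 1) sd(difference) else 0,
                tau2 = NA_real_, sigma2 = NA_real_,
                n_pairs = length(difference), n_participants = 1L))
  }
  comp <- moment_components(difference, id)
  w <- comp$n_i / (comp$n_i * comp$tau2 + comp$sigma2)
  bias <- if (all(is.finite(w)) && sum(w) > 0) {
    sum(w * comp$mean_i) / sum(w)
  } else {
    mean(comp$mean_i) # degenerate zero-variance data: all means identical
  }
  list(bias = bias, bias_sd = sd(difference),
       tau2 = comp$tau2, sigma2 = comp$sigma2,
       n_pairs = length(difference), n_participants = g)
}

# Method-of-moments (one-way ANOVA) variance components for unbalanced
# clustered data; tau2 truncated at zero.
moment_components <- function(y, id) {
  f <- factor(id)
  n_i <- as.vector(table(f))
  sum_i <- as.vector(rowsum(y, f))
  mean_i <- sum_i / n_i
  n <- length(y)
  g <- length(n_i)
  ssw <- sum((y - mean_i[as.integer(f)])^2)
  sigma2 <- if (n > g) ssw / (n - g) else 0
  grand <- mean(y)
  msb <- sum(n_i * (mean_i - grand)^2) / (g - 1)
  n_tilde <- (n - sum(n_i^2) / n) / (g - 1)
  tau2 <- max(0, (msb - sigma2) / n_tilde)
  list(n_i = n_i, mean_i = mean_i, sigma2 = sigma2, tau2 = tau2, levels = levels(f))
}

#' Cluster bootstrap percentile confidence interval
#'
#' Resamples participants (clusters) with replacement, recomputes a
#' statistic of the paired differences on each bootstrap sample, and returns
#' the percentile interval. Resampled copies of a participant are treated as
#' distinct clusters, the standard cluster bootstrap convention.
#'
#' @inheritParams clustered_bias
#' @param statistic A function `(difference, participant_id) -> numeric(1)`;
#'   defaults to the cluster-weighted bias of [clustered_bias()].
#' @param level Interval level (default 0.90, i.e. the 5th/95th percentiles).
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @return Named numeric vector `c(low, high)`.
#' @export
percentile_bootstrap_ci <- function(difference, participant_id,
                                    statistic = NULL, level = 0.90,
                                    n_boot = 10000, seed = 1L) {
  id <- as.character(participant_id)
  ids <- unique(id)
  g <- length(ids)
  if (g < 2) abort("cluster bootstrap requires at least 2 participants")
  if (is.null(statistic)) {
    statistic <- function(d, pid) clustered_bias(d, pid)$bias
  }
  idx_by_id <- split(seq_along(difference), id)
  stats <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample.int(g, g, replace = TRUE)
      idx <- idx_by_id[take]
      d <- difference[unlist(idx, use.names = FALSE)]
      pid <- rep(seq_len(g), lengths(idx))
      statistic(d, pid)
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  out <- unname(quantile(stats, c(alpha, 1 - alpha), names = FALSE))
  c(low = out[1], high = out[2])
}

#' Two one-sided tests (TOST) for equivalence of predictions and measurements
#'
#' Declares statistical equivalence when the mean paired difference is
#' demonstrably inside ±delta, where delta is `limit_fraction` times the
#' mean measured rate (default 10%). Inference is at the participant level:
#' differences are first averaged within participant, honouring the
#' clustering, and the two one-sided t-tests use participant count minus one
#' degrees of freedom. `tost_p` is the larger of the two one-sided p-values;
#' `passed` requires the 90% confidence interval of the mean participant
#' difference to lie strictly within (−delta, +delta) — the interval
#' criterion, which at level `1 − 2*alpha` coincides with both one-sided
#' tests rejecting at `alpha`.
#'
#' @param predicted,measured Paired rates, W·kg⁻¹.
#' @inheritParams clustered_bias
#' @param limit_fraction Equivalence limit as a fraction of the mean
#'   measured rate (default 0.10).
#' @param alpha One-sided test level (default 0.05; CI level is 1 − 2·alpha).
#' @return A list with `passed`, `p`, `equivalence_limit`, `mean_difference`,
#'   `ci` (the t-based interval on participant means), `df`.
#' @export
tost_equivalence <- function(predicted, measured, participant_id,
                             limit_fraction = 0.10, alpha = 0.05) {
  if (!(length(predicted) == length(measured) &&
        length(measured) == length(participant_id))) {
    abort("predicted, measured and participant_id must have equal lengths")
  }
  delta <- limit_fraction * mean(measured)
  if (delta <= 0) abort("equivalence limit must be positive: mean measured rate must be > 0")
  d <- predicted - measured
  d_i <- as.vector(tapply(d, as.character(participant_id), mean))
  n <- length(d_i)
  if (n < 2) abort("TOST requires at least 2 participants")
  m <- mean(d_i)
  s <- sd(d_i)
  df <- n - 1
  if (s == 0) {
    passed <- abs(m) < delta
    return(list(passed = passed, p = 0, equivalence_limit = delta,
                mean_difference = m, ci = c(low = m, high = m), df = df))
  }
  se <- s / sqrt(n)
  p_upper <- pt((m - delta) / se, df)               # H0: mean >= +delta
  p_lower <- pt((m + delta) / se, df, lower.tail = FALSE) # H0: mean <= -delta
  ci <- m + c(-1, 1) * qt(1 - alpha, df) * se
  list(passed = ci[1] > -delta && ci[2] < delta,
       p = max(p_upper, p_lower),
       equivalence_limit = delta,
       mean_difference = m,
       ci = c(low = ci[1], high = ci[2]),
       df = df)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement index combining precision (correlation) and accuracy
#' (location/scale shift):
#' \deqn{CCC = \frac{2\,\mathrm{cov}(p, m)}{\mathrm{var}(p) +
#'   \mathrm{var}(m) + (\bar p - \bar m)^2}}
#' computed with population (1/n) moments over pooled pairs, the standard
#' convention for Lin's coefficient. Set `participant_means = TRUE` to
#' compute it on within-participant means instead.
#'
#' @inheritParams tost_equivalence
#' @param participant_means Average pairs within participant first?
#' @return CCC in \[−1, 1\].
#' @export
#' @examples
#' concordance_correlation(c(1, 2, 3), c(1, 2, 4))
concordance_correlation <- function(predicted, measured,
                                    participant_id = NULL,
                                    participant_means = FALSE) {
  if (length(predicted) != length(measured)) {
    abort("predicted and measured must have equal lengths")
  }
  if (participant_means) {
    if (is.null(participant_id)) abort("participant_id required for participant_means")
    id <- as.character(participant_id)
    predicted <- as.vector(tapply(predicted, id, mean))
    measured <- as.vector(tapply(measured, id, mean))
  }
  n <- length(predicted)
  if (n < 2) abort("CCC requires at least 2 pairs")
  mp <- mean(predicted); mm <- mean(measured)
  vp <- mean((predicted - mp)^2)
  vm <- mean((measured - mm)^2)
  cpm <- mean((predicted - mp) * (measured - mm))
  denom <- vp + vm + (mp - mm)^2
  if (denom == 0) abort("CCC undefined: zero variance and equal means in both vectors")
  2 * cpm / denom
}

#' Median-absolute-deviation outlier screen
#'
#' Flags values whose distance from the median exceeds `cutoff` multiples of
#' the scaled MAD (scale constant 1.4826 for consistency with the normal
#' SD). Returns a logical mask; the data are never mutated. When the MAD is
#' zero but the values are not all identical, every value off the median is
#' flagged, with a warning.
#'
#' @param values Numeric vector (length >= 3).
#' @param cutoff Multiples of the scaled MAD (default 3.0; 2.5 is the
#'   common conservative alternative).
#' @return Logical mask, `TRUE` = flagged as outlier.
#' @export
#' @examples
#' mad_outlier_screen(c(1, 2, 3, 100))
mad_outlier_screen <- function(values, cutoff = 3.0) {
  if (length(values) < 3) abort("MAD screen requires at least 3 values")
  if (any(!is.finite(values))) abort("values must be finite")
  med <- median(values)
  scaled_mad <- stats::mad(values) # constant = 1.4826
  if (scaled_mad == 0) {
    off <- values != med
    if (any(off)) {
      warn("MAD is zero with non-identical values: flagging every value off the median")
    }
    return(off)
  }
  abs(values - med) / scaled_mad > cutoff
}

#' Validate predictions against measurements
#'
#' Data-frame-first entry point for the agreement/equivalence workflow:
#' computes the cluster-weighted bias, SD of paired differences, cluster
#' bootstrap percentile 90% CI of the bias, Lin's CCC, and the TOST
#' equivalence verdict with limits equal to `limit_fraction` of the mean
#' measured rate.
#'
#' @param data A data frame of paired predictions and measurements.
#' @param predicted,measured,participant_id Column names (tidy-eval) holding
#'   the predicted rate, measured rate, and participant label. Defaults
#'   match the trial schema (`.pred_m_wkg`, `m_wkg`, `participant_id`).
#' @param limit_fraction Equivalence limit fraction (default 0.10).
#' @param ci_level Bootstrap interval level (default 0.90).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap.
#' @return A `ruckmet_validation` object; see [tidy.ruckmet_validation()].
#' @export
#' @examples
#' df <- tibble::tibble(
#'   participant_id = rep(letters[1:5], each = 4),
#'   m_wkg = 6 + rnorm(20, sd = 0.5)
#' )
#' df$.pred_m_wkg <- df$m_wkg + rnorm(20, sd = 0.3)
#' validate_predictions(df, seed = 1)
validate_predictions <- function(data,
                                 predicted = ".pred_m_wkg",
                                 measured = "m_wkg",
                                 participant_id = "participant_id",
                                 limit_fraction = 0.10,
                                 ci_level = 0.90,
                                 n_boot = 2000,
                                 seed = 1L) {
  pred <- pull_column(data, {{ predicted }})
  meas <- pull_column(data, {{ measured }})
  id <- as.character(pull_column(data, {{ participant_id }}))
  keep <- is.finite(pred) & is.finite(meas)
  if (!all(keep)) abort("predicted and measured values must be finite")
  d <- pred - meas
  cb <- clustered_bias(d, id)
  # a single-participant set (leave-one-subject-out holdout) has no cluster
  # structure left: treat pairs as independent for resampling and TOST
  infer_id <- id
  if (length(unique(id)) < 2) {
    warn("single participant: bootstrap and TOST treat pairs as independent")
    infer_id <- as.character(seq_along(d))
  }
  ci <- percentile_bootstrap_ci(d, infer_id, level = ci_level,
                                n_boot = n_boot, seed = seed)
  tost <- tost_equivalence(pred, meas, infer_id,
                           limit_fraction = limit_fraction)
  structure(
    list(
      n_pairs = length(d),
      n_participants = length(unique(id)),
      bias = cb$bias,
      bias_sd = cb$bias_sd,
      ci90 = ci,
      ccc = concordance_correlation(pred, meas),
      equivalence_limit = tost$equivalence_limit,
      tost_passed = tost$passed,
      tost_p = tost$p,
      limit_fraction = limit_fraction,
      ci_level = ci_level,
      n_boot = n_boot,
      seed = seed,
      pairs = tibble::tibble(participant_id = id, predicted = pred,
                             measured = meas, difference = d)
    ),
    class = "ruckmet_validation"
  )
}

pull_column <- function(data, col) {
  dplyr::pull(data, {{ col }})
}

#' @export
print.ruckmet_validation <- function(x, ...) {
  cat("<ruckmet_validation> ", x$n_pairs, " pairs, ",
      x$n_participants, " participants\n", sep = "")
  cat(format_validation(x), "\n")
  invisible(x)
}

#' Paper-style one-line validation summary
#'
#' @param report A `ruckmet_validation` object.
#' @return A character scalar like
#'   `"bias, -0.01 ± 0.62 W/kg; 90% CI, -0.15 to 0.11 W/kg; CCC, 0.965; equivalent (P = 0.001)"`.
#' @export
format_validation <- function(report) {
  sprintf("bias, %.2f ± %.2f W/kg; %d%% CI, %.2f to %.2f W/kg; CCC, %.3f; %s (P = %.3g)",
          report$bias, report$bias_sd, round(report$ci_level * 100),
          report$ci90[["low"]], report$ci90[["high"]], report$ccc,
          if (report$tost_passed) "equivalent" else "not equivalent",
          report$tost_p)
}

#' @describeIn validate_predictions Tidy the report into a one-row tibble.
#' @param x A `ruckmet_validation` object.
#' @param ... Unused.
#' @export
tidy.ruckmet_validation <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    n_participants = x$n_participants,
    bias = x$bias,
    bias_sd = x$bias_sd,
    ci90_low = x$ci90[["low"]],
    ci90_high = x$ci90[["high"]],
    ccc = x$ccc,
    equivalence_limit = x$equivalence_limit,
    tost_passed = x$tost_passed,
    tost_p = x$tost_p
  )
}

#' @describeIn validate_predictions Alias for `tidy()` (the report is a
#'   one-row summary).
#' @export
glance.ruckmet_validation <- function(x, ...) tidy(x, ...)

#' Write a validation report as JSON
#'
#' @param report A `ruckmet_validation` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(report, path) {
  out <- as.list(tidy(report))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
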