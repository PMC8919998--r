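#' Fit the backpacking model to trial data
#'
#' Estimates the six model coefficients from steady-state trials with an
#' additive participant random intercept:
#' \deqn{M_{ij} = (\dot{M}_{Rest,i} + a + b S_{ij}^p + d S_{ij}^4)
#'   (1 + x L_{ij}^y) + u_i + \varepsilon_{ij}}
#' Estimation profiles the intercepts out of a penalized least-squares
#' problem: for a given variance ratio \eqn{\lambda = \sigma^2/\tau^2} the
#' optimal intercepts given the fixed coefficients are the shrunken
#' participant means \eqn{u_i = n_i \bar r_i / (n_i + \lambda)}, so the
#' coefficients are found by bounded Levenberg–Marquardt on the stacked
#' residual vector \eqn{(r_{ij} - u_i,\ \sqrt{\lambda}\, u_i)}. An outer
#' loop re-estimates the two variance components from the residuals with
#' the closed-form method-of-moments (ANOVA) estimator and repeats the
#' solve until the components stabilise; a final solve at the frozen
#' penalty ratio supplies a monotone non-increasing objective trace. For a
#' balanced intercept-only structure this targets the same estimand as a
#' REML nonlinear mixed-effects fit.
#'
#' Trials are sorted internally by participant, speed and load, so the
#' result is invariant to input row order.
#'
#' @param trials A data frame with columns `participant_id`, `speed_mps`,
#'   `load_fraction`, `m_rest_wkg`, `m_wkg`. At least 2 participants, 2
#'   distinct loads and 3 distinct speeds are required for identifiability.
#' @param init A [backpack_coefficients()] set of starting values (default:
#'   the published set).
#' @param max_iter Cap on outer variance-update iterations (default 30).
#' @param tol Relative stability tolerance for the variance components
#'   across outer iterations (default 1e-8); the inner least-squares solves
#'   run to machine-level tolerances.
#' @param bounds Named list with elements `lower` and `upper`, each a named
#'   vector over `a`, `b`, `p`, `d`, `x`, `y`. Defaults keep the search in
#'   the physically interpretable region: `p` in \[0.1, 1\], `y` in
#'   \[0.5, 3\], `b`, `d`, `x` >= 0, `a` free.
#' @return An object of class `ruckmet_fit` with elements `coefficients`
#'   (a `ruckmet_coefficients`), `residual_sd`, `participant_intercept_sd`,
#'   `converged`, `n_obs`, `n_participants`, `objective` (final penalized
#'   sum of squares), `trace` (tibble of objectives: outer iterations, then
#'   the final frozen solve), `random_intercepts`, and `data` (the sorted
#'   trials with a `.fitted` column).
#' @seealso [tidy.ruckmet_fit()], [glance.ruckmet_fit()],
#'   [predict.ruckmet_fit()], [cross_validate()]
#' @export
#' @examples
#' study <- simulate_study(n = 8, n_females = 1, seed = 3,
#'                         noise = noise_model(residual_sd = 0, participant_intercept_sd = 0))
#' fit <- fit_backpacking_model(study$trials)
#' tidy(fit)
fit_backpacking_model <- function(trials,
                                  init = lcda_backpacking_coefficients(),
                                  max_iter = 30,
                                  tol = 1e-8,
                                  bounds = default_fit_bounds()) {
  need <- c("participant_id", "speed_mps", "load_fraction", "m_rest_wkg", "m_wkg")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    abort(paste0("missing required columns: ", paste(miss, collapse = ", ")))
  }
  d <- tibble::as_tibble(trials)
  d <- dplyr::arrange(d, .data$participant_id, .data$speed_mps, .data$load_fraction)
  id <- factor(as.character(d$participant_id))
  g <- nlevels(id)
  if (g < 2) abort("at least 2 participants are required")
  if (length(unique(d$load_fraction)) < 2) {
    abort("non-identifiable design: at least 2 distinct load fractions are required")
  }
  if (length(unique(d$speed_mps)) < 3) {
    abort("non-identifiable design: at least 3 distinct speeds are required")
  }
  if (nrow(d) < 6) abort("need at least as many observations as free parameters (6)")

  fit_data <- data.frame(
    y_obs = d$m_wkg, S = d$speed_mps, L = d$load_fraction, m_rest = d$m_rest_wkg
  )
  idx <- as.integer(id)
  n_i <- as.vector(table(id))
  theta <- coef_vector(init)
  lower <- bounds$lower[names(theta)]
  upper <- bounds$upper[names(theta)]

  shrunken_intercepts <- function(resid, lambda) {
    r_bar <- as.vector(rowsum(resid, id)) / n_i
    if (is.finite(lambda)) n_i * r_bar / (n_i + lambda) else rep(0, g)
  }
  # stacked penalized residuals with the intercepts profiled out
  profiled_residuals <- function(par, lambda) {
    par <- setNames(par, names(theta))
    r <- fit_data$y_obs - model_surface(par, fit_data)
    u <- shrunken_intercepts(r, lambda)
    res <- r - u[idx]
    if (is.finite(lambda) && lambda > 0) c(res, sqrt(lambda) * u) else res
  }
  solve_given_lambda <- function(start, lambda) {
    minpack.lm::nls.lm(
      par = start, fn = profiled_residuals, lambda = lambda,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-13,
                                           ptol = 1e-13)
    )
  }

  # initial variance components from the starting coefficients
  comp <- moment_components(fit_data$y_obs - model_surface(theta, fit_data), id)
  tau2 <- comp$tau2; sigma2 <- comp$sigma2
  lambda <- if (tau2 > 0) sigma2 / tau2 else Inf
  trace <- list()
  stable <- FALSE
  nls_ok <- TRUE
  for (iter in seq_len(max_iter)) {
    lm_fit <- tryCatch(solve_given_lambda(theta, lambda), error = function(e) e)
    if (inherits(lm_fit, "error")) { nls_ok <- FALSE; break }
    theta <- setNames(unlist(lm_fit$par), names(theta))
    resid <- fit_data$y_obs - model_surface(theta, fit_data)
    comp <- moment_components(resid, id)
    rel_change <- max(abs(comp$tau2 - tau2), abs(comp$sigma2 - sigma2)) /
      max(comp$tau2 + comp$sigma2, 1e-12)
    tau2 <- comp$tau2; sigma2 <- comp$sigma2
    lambda <- if (tau2 > 0) sigma2 / tau2 else Inf
    trace[[iter]] <- tibble::tibble(
      iteration = iter, objective = lm_fit$deviance, variance_update = TRUE
    )
    if (rel_change < tol) { stable <- TRUE; break }
  }

  # final solve at the frozen penalty ratio; its Levenberg–Marquardt
  # iterations accept only objective decreases, giving the monotone trace
  final_conv <- FALSE
  if (nls_ok) {
    lm_final <- tryCatch(solve_given_lambda(theta, lambda), error = function(e) e)
    if (inherits(lm_final, "error")) {
      nls_ok <- FALSE
    } else {
      theta <- setNames(unlist(lm_final$par), names(theta))
      final_conv <- lm_final$info %in% 1:4
      n_prev <- length(trace)
      trace[[n_prev + 1]] <- tibble::tibble(
        iteration = n_prev + seq_along(lm_final$rsstrace),
        objective = lm_final$rsstrace,
        variance_update = FALSE
      )
    }
  }
  if (!nls_ok) {
    warn("nonlinear least-squares stage failed; result flagged as non-converged")
  }

  resid <- fit_data$y_obs - model_surface(theta, fit_data)
  u <- shrunken_intercepts(resid, lambda)
  objective <- sum((resid - u[idx])^2) +
    (if (is.finite(lambda)) lambda * sum(u^2) else 0)
  fitted_vals <- model_surface(theta, fit_data) + u[idx]
  structure(
    list(
      coefficients = backpack_coefficients(
        a = theta[["a"]], b = theta[["b"]], p = theta[["p"]], d = theta[["d"]],
        x = theta[["x"]], y = theta[["y"]],
        name = "fitted", provenance = "fit_backpacking_model"
      ),
      residual_sd = sqrt(sigma2),
      participant_intercept_sd = sqrt(tau2),
      converged = nls_ok && stable && final_conv,
      n_obs = nrow(d),
      n_participants = g,
      objective = objective,
      trace = dplyr::bind_rows(trace),
      random_intercepts = tibble::tibble(participant_id = levels(id), u = u),
      data = dplyr::mutate(d, .fitted = fitted_vals)
    ),
    class = "ruckmet_fit"
  )
}

model_surface <- function(par, fit_data) {
  (fit_data$m_rest + par[["a"]] + par[["b"]] * fit_data$S^par[["p"]] +
     par[["d"]] * fit_data$S^4) *
    (1 + par[["x"]] * fit_data$L^par[["y"]])
}

#' @rdname fit_backpacking_model
#' @export
default_fit_bounds <- function() {
  list(
    lower = c(a = -Inf, b = 0, p = 0.1, d = 0, x = 0, y = 0.5),
    upper = c(a = Inf, b = Inf, p = 1.0, d = Inf, x = Inf, y = 3.0)
  )
}

#' @export
print.ruckmet_fit <- function(x, ...) {
  cat("<ruckmet_fit> ", x$n_obs, " trials, ", x$n_participants,
      " participants, ", if (x$converged) "converged" else "NOT converged",
      "\n", sep = "")
  print(x$coefficients)
  cat(sprintf("  residual SD %.3f, participant intercept SD %.3f (W/kg)\n",
              x$residual_sd, x$participant_intercept_sd))
  invisible(x)
}

#' Tidy and summarise fitted backpacking models
#'
#' `tidy()` returns the six coefficient estimates; `glance()` returns a
#' one-row model summary.
#'
#' @param x A `ruckmet_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ruckmet_fit <- function(x, ...) tidy(x$coefficients)

#' @rdname tidy.ruckmet_fit
#' @export
glance.ruckmet_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_participants = x$n_participants,
    residual_sd = x$residual_sd,
    participant_intercept_sd = x$participant_intercept_sd,
    objective = x$objective,
    n_iterations = nrow(x$trace),
    converged = x$converged
  )
}

#' Predict from a fitted backpacking model
#'
#' Population-level predictions (random intercepts set to zero) for new
#' trial conditions, as used when scoring holdout participants.
#'
#' @param object A `ruckmet_fit`.
#' @param newdata A data frame with `speed_mps`, `load_fraction`,
#'   `m_rest_wkg` (and optionally `grade_decimal`, `terrain_coefficient`).
#' @param ... Unused.
#' @return Numeric vector of predicted rates, W·kg⁻¹.
#' @export
predict.ruckmet_fit <- function(object, newdata, ...) {
  lf <- if ("load_fraction" %in% names(newdata)) newdata$load_fraction else 0
  gr <- if ("grade_decimal" %in% names(newdata)) newdata$grade_decimal else 0
  eta <- if ("terrain_coefficient" %in% names(newdata)) newdata$terrain_coefficient else 1
  predict_metabolic_rate(
    m_rest = newdata$m_rest_wkg, speed = newdata$speed_mps,
    load_fraction = lf, grade = gr, terrain = eta,
    coefficients = object$coefficients
  )
}

#' Stratified participant-level k-fold assignment
#'
#' Partitions participants into `k` folds for grouped cross-validation.
#' Females are dealt round-robin first (one per fold when counts allow),
#' then males continue the round-robin deal; within each sex the order is a
#' seeded uniform shuffle, so the assignment is deterministic given the
#' seed. With 30 participants (3 female) and `k = 3`, every fold receives
#' exactly 1 female and 9 males.
#'
#' @param participants A data frame with columns `participant_id` and
#'   (optionally) `sex` (`"female"`/`"male"`; absent means unstratified).
#' @param k Number of folds (default 3).
#' @param seed Integer seed.
#' @return A tibble with columns `participant_id`, `sex`, `fold`.
#' @export
kfold_split <- function(participants, k = 3, seed = 1L) {
  if (!"participant_id" %in% names(participants)) {
    abort("participants must contain a participant_id column")
  }
  p <- tibble::as_tibble(participants)
  if (!"sex" %in% names(p)) p$sex <- "male"
  p <- dplyr::distinct(p, .data$participant_id, .data$sex)
  n <- nrow(p)
  if (k < 2) abort("k must be at least 2")
  if (k > n) abort("k cannot exceed the number of participants")
  withr::with_seed(seed, {
    females <- sample(p$participant_id[p$sex == "female"])
    males <- sample(p$participant_id[p$sex != "female"])
  })
  dealt <- c(females, males)
  fold <- ((seq_along(dealt) - 1L) %% k) + 1L
  out <- tibble::tibble(participant_id = dealt, fold = fold)
  dplyr::arrange(dplyr::left_join(out, p, by = "participant_id"),
                 .data$fold, .data$participant_id)[, c("participant_id", "sex", "fold")]
}

#' Grouped k-fold cross-validation of the backpacking model
#'
#' Splits participants into `k` sex-stratified folds, fits the model to
#' `k − 1` folds, predicts the holdout participants at the population level,
#' and scores each fold (and the pooled holdout predictions) with
#' [validate_predictions()]. A participant's trials are never scored by a
#' model whose training set contained that participant; this subject-level
#' separation is asserted internally.
#'
#' @param trials Trial table as in [fit_backpacking_model()], plus a `sex`
#'   column if sex-stratified folds are wanted.
#' @param k Number of folds (default 3).
#' @param seed Seed controlling the fold assignment and bootstrap.
#' @param init Starting coefficients for each fold's fit.
#' @param limit_fraction TOST equivalence limit fraction (default 0.10).
#' @param n_boot Bootstrap replicates per report (default 2000).
#' @return An object of class `ruckmet_cv`: list with `assignment`,
#'   `fold_reports` (list of `ruckmet_validation`), `pooled` (a
#'   `ruckmet_validation`), and `fits`.
#' @export
cross_validate <- function(trials, k = 3, seed = 1L,
                           init = lcda_backpacking_coefficients(),
                           limit_fraction = 0.10, n_boot = 2000) {
  d <- tibble::as_tibble(trials)
  cols <- intersect(c("participant_id", "sex"), names(d))
  assignment <- kfold_split(dplyr::distinct(d[, cols, drop = FALSE]),
                            k = k, seed = seed)
  d <- dplyr::left_join(d, assignment[, c("participant_id", "fold")],
                        by = "participant_id")
  fold_reports <- vector("list", k)
  fits <- vector("list", k)
  holdout <- vector("list", k)
  for (f in seq_len(k)) {
    train <- d[d$fold != f, ]
    test <- d[d$fold == f, ]
    overlap <- intersect(unique(train$participant_id), unique(test$participant_id))
    stopifnot("subject-level separation violated" = length(overlap) == 0)
    fit <- tryCatch(
      fit_backpacking_model(train, init = init),
      error = function(e) {
        abort(sprintf("fold %d training failed: %s", f, conditionMessage(e)))
      }
    )
    test$.pred_m_wkg <- predict(fit, test)
    fold_reports[[f]] <- validate_predictions(
      test, limit_fraction = limit_fraction, n_boot = n_boot,
      seed = seed + f
    )
    fits[[f]] <- fit
    holdout[[f]] <- test
  }
  pooled <- validate_predictions(
    dplyr::bind_rows(holdout), limit_fraction = limit_fraction,
    n_boot = n_boot, seed = seed
  )
  structure(
    list(assignment = assignment, fold_reports = fold_reports,
         pooled = pooled, fits = fits, k = k, seed = seed),
    class = "ruckmet_cv"
  )
}

#' @export
print.ruckmet_cv <- function(x, ...) {
  cat("<ruckmet_cv> ", x$k, "-fold grouped cross-validation\n", sep = "")
  print(tidy(x))
  cat("pooled: ", format_validation(x$pooled), "\n")
  invisible(x)
}

#' Tidy cross-validation results
#'
#' One row per fold plus a `"pooled"` row, each carrying the validation
#' metrics of [tidy.ruckmet_validation()].
#'
#' @param x A `ruckmet_cv` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ruckmet_cv <- function(x, ...) {
  per_fold <- purrr::map(x$fold_reports, tidy)
  dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(fold = as.character(seq_len(x$k))),
                     dplyr::bind_rows(per_fold)),
    dplyr::bind_cols(tibble::tibble(fold = "pooled"), tidy(x$pooled))
  )
}

#' @rdname tidy.ruckmet_cv
#' @export
glance.ruckmet_cv <- function(x, ...) tidy(x$pooled)
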