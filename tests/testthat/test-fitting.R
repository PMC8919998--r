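test_that("noise-free data return the generating coefficients to 1e-6", {
  study <- simulate_study(n = 8, n_females = 1, seed = 31,
                          noise = noise_model(0, 0))
  fit <- fit_backpacking_model(study$trials, init = perturbed_init(77))
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_equal(est, published_values, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lt(fit$residual_sd, 1e-6)
})

test_that("the fit is invariant to trial row order", {
  study <- simulate_study(n = 6, n_females = 1, seed = 13)
  f1 <- fit_backpacking_model(study$trials)
  withr::with_seed(1, shuffled <- study$trials[sample(nrow(study$trials)), ])
  f2 <- fit_backpacking_model(shuffled)
  expect_identical(tidy(f1)$estimate, tidy(f2)$estimate)
  expect_identical(f1$objective, f2$objective)
})

test_that("a common participant-level offset is absorbed by the intercepts", {
  study <- simulate_study(n = 8, n_females = 1, seed = 5,
                          noise = noise_model(residual_sd = 0,
                                              participant_intercept_sd = 0.35))
  shifted <- dplyr::mutate(study$trials, m_wkg = m_wkg + 0.5)
  fit <- fit_backpacking_model(shifted)
  fit0 <- fit_backpacking_model(study$trials)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  # with zero residual noise the intercepts absorb u_i + 0.5 entirely and
  # the fixed coefficients still match the generating values
  expect_equal(est, published_values, tolerance = 1e-5)
  expect_equal(fit$random_intercepts$u - fit0$random_intercepts$u,
               rep(0.5, 8), tolerance = 1e-3)
})

test_that("non-identifiable designs are rejected explicitly", {
  study <- simulate_study(n = 4, n_females = 0, seed = 2)
  one_load <- dplyr::filter(study$trials, load_fraction == 0.44)
  expect_error(fit_backpacking_model(one_load), "2 distinct load")
  two_speeds <- dplyr::filter(study$trials, speed_mps %in% c(0, 0.89))
  expect_error(fit_backpacking_model(two_speeds), "3 distinct speeds")
  one_person <- dplyr::filter(study$trials, participant_id == "P01")
  expect_error(fit_backpacking_model(one_person), "2 participants")
})

test_that("the penalized objective never increases once the penalty is frozen", {
  study <- simulate_study(n = 10, n_females = 1, seed = 8)
  fit <- fit_backpacking_model(study$trials)
  frozen <- fit$trace[!fit$trace$variance_update, ]
  expect_gt(nrow(frozen), 1)
  expect_true(all(diff(frozen$objective) <= 1e-8 * frozen$objective[-nrow(frozen)]))
})

test_that("estimate dispersion shrinks when residual noise is halved", {
  fit_sds <- function(noise, seeds) {
    est <- sapply(seeds, function(s) {
      study <- simulate_study(n = 12, n_females = 1, seed = s, noise = noise,
                              emit_gas = FALSE)
      tidy(fit_backpacking_model(study$trials))$estimate
    })
    apply(est, 1, sd)
  }
  seeds <- 301:310
  disp_full <- fit_sds(noise_model(0.45, 0.35), seeds)
  disp_half <- fit_sds(noise_model(0.225, 0.35), seeds)
  expect_lt(sum(disp_half), sum(disp_full))
})

test_that("k-fold split stratifies sex and is deterministic", {
  participants <- generate_participants(n = 30, n_females = 3, seed = 1)
  split <- kfold_split(participants, k = 3, seed = 7)
  counts <- dplyr::count(split, fold, sex) |>
    tidyr::pivot_wider(names_from = sex, values_from = n)
  expect_equal(counts$female, c(1, 1, 1))
  expect_equal(counts$male, c(9, 9, 9))
  expect_setequal(split$participant_id, participants$participant_id)
  expect_identical(split, kfold_split(participants, k = 3, seed = 7))
  expect_false(identical(split$fold[order(split$participant_id)],
                         kfold_split(participants, k = 3, seed = 8)$fold[
                           order(kfold_split(participants, k = 3, seed = 8)$participant_id)]))
})

test_that("k-fold split balances small and edge-case cohorts", {
  p5 <- tibble::tibble(participant_id = paste0("q", 1:5))
  s5 <- kfold_split(p5, k = 2, seed = 3)
  expect_setequal(as.vector(table(s5$fold)), c(3, 2))
  expect_error(kfold_split(p5, k = 6, seed = 1), "cannot exceed")
  expect_error(kfold_split(p5, k = 1, seed = 1), "at least 2")
  # round-robin female rule generalizes when female count != k
  p6 <- tibble::tibble(participant_id = paste0("r", 1:8),
                       sex = rep(c("female", "male"), each = 4))
  s6 <- kfold_split(p6, k = 3, seed = 2)
  fem <- table(s6$fold[s6$sex == "female"])
  expect_lte(max(fem) - min(fem), 1)
})

test_that("grouped cross-validation keeps subjects separated and scores folds", {
  study <- simulate_study(n = 9, n_females = 0, seed = 44,
                          noise = noise_model(0, 0))
  cv <- cross_validate(study$trials, k = 3, seed = 2, n_boot = 200)
  # perfect model: every fold has zero bias and CCC 1
  for (r in cv$fold_reports) {
    expect_equal(r$bias, 0, tolerance = 1e-8)
    expect_equal(r$ccc, 1, tolerance = 1e-8)
    expect_true(r$tost_passed)
  }
  expect_equal(cv$pooled$n_pairs, nrow(study$trials))
  # each participant is scored exactly once, by a fold not trained on them
  scored <- unlist(lapply(cv$fold_reports, function(r) unique(r$pairs$participant_id)))
  expect_setequal(scored, unique(study$trials$participant_id))
  expect_equal(length(scored), 9)
  td <- tidy(cv)
  expect_equal(td$fold, c("1", "2", "3", "pooled"))
})

test_that("leave-one-subject-out degenerates correctly", {
  study <- simulate_study(n = 5, n_females = 0, seed = 19,
                          noise = noise_model(0, 0))
  # single-participant holdouts warn that pairs are treated as independent
  cv <- suppressWarnings(cross_validate(study$trials, k = 5, seed = 1,
                                        n_boot = 100))
  expect_equal(length(cv$fold_reports), 5)
  expect_true(all(vapply(cv$fold_reports,
                         function(r) r$n_participants == 1, logical(1))))
})

test_that("fit accessors expose a broom-style surface", {
  study <- simulate_study(n = 6, n_females = 1, seed = 3)
  fit <- fit_backpacking_model(study$trials)
  expect_named(tidy(fit), c("term", "estimate"))
  g <- glance(fit)
  expect_equal(g$n_obs, nrow(study$trials))
  expect_equal(g$n_participants, 6)
  preds <- predict(fit, study$trials)
  expect_equal(length(preds), nrow(study$trials))
  expect_true(all(preds > 0))
})
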