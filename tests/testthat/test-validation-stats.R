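test_that("clustered bias handles degenerate and balanced cases exactly", {
  id <- rep(c("a", "b", "c"), each = 4)
  z <- clustered_bias(rep(0, 12), id)
  expect_identical(z$bias, 0)
  expect_identical(z$bias_sd, 0)
  # balanced data with participant means (-1, 0, +1): bias is their mean, 0
  d <- c(rep(-1, 4), rep(0, 4), rep(1, 4))
  expect_equal(clustered_bias(d, id)$bias, 0)
  expect_warning(clustered_bias(c(1, 2, 3), rep("only", 3)), "single participant")
})

test_that("clustered bias equals the exact matrix GLS solution on a toy set", {
  toy <- toy_pairs()
  y <- toy$difference
  f <- factor(toy$participant_id)
  n_i <- as.vector(table(f))
  # independent method-of-moments components, written out in full
  means <- tapply(y, f, mean)
  ssw <- sum((y - means[f])^2)
  sigma2 <- ssw / (length(y) - nlevels(f))
  msb <- sum(n_i * (means - mean(y))^2) / (nlevels(f) - 1)
  n_tilde <- (length(y) - sum(n_i^2) / length(y)) / (nlevels(f) - 1)
  tau2 <- max(0, (msb - sigma2) / n_tilde)
  # exact GLS on the full covariance matrix V = tau2*ZZ' + sigma2*I
  Z <- model.matrix(~ f - 1)
  V <- tau2 * Z %*% t(Z) + sigma2 * diag(length(y))
  one <- rep(1, length(y))
  gls <- as.numeric(solve(t(one) %*% solve(V) %*% one) %*%
                      (t(one) %*% solve(V) %*% y))
  got <- clustered_bias(y, toy$participant_id)
  expect_equal(got$bias, gls, tolerance = 1e-12)
  expect_equal(got$bias_sd, sd(y))
  # the heavily sampled outlying participant is down-weighted toward the
  # average of participant means
  expect_lt(abs(got$bias - mean(means)), abs(mean(y) - mean(means)))
})

test_that("cluster bootstrap percentile interval is deterministic and degenerate-safe", {
  id <- rep(letters[1:5], each = 3)
  d <- rep(0.4, 15)
  ci <- percentile_bootstrap_ci(d, id, n_boot = 200, seed = 11)
  expect_equal(unname(ci), c(0.4, 0.4)) # constant data: zero-width interval
  withr::with_seed(123, x <- rnorm(15, 0, 0.5))
  ci1 <- percentile_bootstrap_ci(x, id, n_boot = 300, seed = 42)
  ci2 <- percentile_bootstrap_ci(x, id, n_boot = 300, seed = 42)
  ci3 <- percentile_bootstrap_ci(x, id, n_boot = 300, seed = 43)
  expect_identical(ci1, ci2)
  expect_false(identical(ci1, ci3))
  expect_lt(ci1[["low"]], ci1[["high"]])
  expect_error(percentile_bootstrap_ci(1:3, rep("a", 3), n_boot = 10),
               "at least 2")
})

test_that("TOST passes zero bias, fails the boundary, and is monotone in the limit", {
  id <- rep(letters[1:6], each = 3)
  meas <- rep(6.12, 18)
  # identical predictions: equivalent within delta = 0.612
  t0 <- tost_equivalence(meas, meas, id)
  expect_true(t0$passed)
  expect_equal(t0$equivalence_limit, 0.612)
  expect_equal(t0$p, 0)
  # participant mean differences exactly at +delta: boundary is not inside
  t1 <- tost_equivalence(meas + 0.612, meas, id)
  expect_false(t1$passed)
  # monotonicity: passing at a fraction implies passing at any larger one
  withr::with_seed(5, pred <- meas + rnorm(18, 0.1, 0.4))
  fr <- c(0.05, 0.10, 0.20, 0.40)
  passes <- vapply(fr, function(f) {
    tost_equivalence(pred, meas, id, limit_fraction = f)$passed
  }, logical(1))
  expect_true(all(diff(as.integer(passes)) >= 0))
  expect_error(tost_equivalence(1, 1, "a"), "at least 2")
})

test_that("concordance correlation matches its closed form", {
  expect_equal(concordance_correlation(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(concordance_correlation(c(1, 2, 3), c(1, 2, 4)), 6 / 7)
  expect_equal(concordance_correlation(c(-1, 0, 1), c(1, 0, -1)), -1.0)
  expect_error(concordance_correlation(c(1, 1), c(1, 1)), "zero variance")
})

test_that("CCC never exceeds the Pearson correlation in magnitude", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      x <- rnorm(30)
      y <- 0.8 * x + rnorm(30, sd = 0.5) + runif(1, -1, 1)
    })
    expect_lte(abs(concordance_correlation(x, y)), abs(cor(x, y)) + 1e-12)
  }
})

test_that("MAD screen flags gross outliers and never mutates clean data", {
  mask <- mad_outlier_screen(c(1, 2, 3, 100))
  expect_identical(mask, c(FALSE, FALSE, FALSE, TRUE))
  expect_false(any(mad_outlier_screen(rep(5, 6))))
  expect_false(any(mad_outlier_screen(c(4.9, 5.0, 5.1, 5.05))))
  # tighter cutoff flags more, never fewer
  v <- c(rnorm(20), 6)
  expect_true(all(mad_outlier_screen(v, cutoff = 3.0) <=
                    mad_outlier_screen(v, cutoff = 2.5)))
  expect_warning(mad_outlier_screen(c(1, 1, 1, 1, 9)), "MAD is zero")
})

test_that("validate_predictions assembles a coherent report", {
  withr::with_seed(21, {
    d <- tibble::tibble(
      participant_id = rep(sprintf("P%02d", 1:10), each = 6),
      m_wkg = runif(60, 3, 9)
    )
    d$.pred_m_wkg <- d$m_wkg + rnorm(10)[rep(1:10, each = 6)] * 0.2 +
      rnorm(60, 0, 0.3)
  })
  rep1 <- validate_predictions(d, n_boot = 500, seed = 2)
  expect_s3_class(rep1, "ruckmet_validation")
  expect_equal(rep1$n_pairs, 60)
  expect_equal(rep1$n_participants, 10)
  # percentile interval brackets the bias (high-probability property,
  # asserted with a small tolerance)
  expect_lte(rep1$ci90[["low"]], rep1$bias + 0.05)
  expect_gte(rep1$ci90[["high"]], rep1$bias - 0.05)
  expect_equal(rep1$equivalence_limit, 0.10 * mean(d$m_wkg))
  td <- tidy(rep1)
  expect_equal(nrow(td), 1)
  expect_named(td, c("n_pairs", "n_participants", "bias", "bias_sd",
                     "ci90_low", "ci90_high", "ccc", "equivalence_limit",
                     "tost_passed", "tost_p"))
  expect_identical(glance(rep1), td)
  expect_match(format_validation(rep1), "bias, .* W/kg; 90% CI")
})
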