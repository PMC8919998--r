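test_that("Cunningham resting rate matches its closed form and scaling", {
  # (500 + 22*60) kcal/day -> W -> per kg of a 77 kg person
  expect_equal(resting_metabolic_rate(60, 77),
               (500 + 22 * 60) * 4184 / 86400 / 77)
  expect_equal(resting_metabolic_rate(60, 77), 1.145, tolerance = 1e-3)
  # lean mass equal to body mass collapses to the closed form
  m <- c(55, 70, 90)
  expect_equal(resting_metabolic_rate(m, m), (500 + 22 * m) * 4184 / 86400 / m)
  # inverse proportionality in body mass at fixed lean mass
  expect_equal(resting_metabolic_rate(50, 100),
               resting_metabolic_rate(50, 50) / 2)
  expect_error(resting_metabolic_rate(-1, 70), "positive")
  expect_error(resting_metabolic_rate(80, 70), "exceed")
})

test_that("level-walking terms evaluate the three speed components", {
  expect_identical(level_walking_terms(0), 0.19)
  expect_equal(level_walking_terms(1), 0.19 + 1.78 + 0.27)
  expect_equal(level_walking_terms(1.34),
               0.19 + 1.78 * 1.34^0.58 + 0.27 * 1.34^4)
  expect_error(level_walking_terms(-0.1), "non-negative")
  expect_warning(level_walking_terms(2.5), "walk-run")
})

test_that("load multiplier is exactly 1 unloaded and follows the power law", {
  expect_identical(load_multiplier(0), 1)
  expect_equal(load_multiplier(1), 2.96)
  expect_equal(load_multiplier(0.66), 1 + 1.96 * 0.66^1.36)
  expect_error(load_multiplier(-0.1), "non-negative")
  expect_warning(load_multiplier(1.2), "outside the fitted domain")
})

test_that("grade cost vanishes on the level and when standing, exactly", {
  expect_identical(grade_cost(c(0.45, 1.34, 1.97), 0), c(0, 0, 0))
  expect_identical(grade_cost(0, c(-0.2, 0.1, 0.3)), c(0, 0, 0))
})

test_that("grade cost matches the damped uphill/downhill form", {
  expect_equal(grade_cost(1.34, 0.10),
               34 * 1.34 * 0.10 * (1 - 1.05^(1 - 1.1^(100 * 0.10 + 32))))
  expect_equal(grade_cost(1.34, 0.10), 4.2254, tolerance = 1e-4)
  # moderate downhill saves energy: sign follows the grade
  expect_lt(grade_cost(1.34, -0.10), 0)
  expect_gt(grade_cost(1.34, 0.05), 0)
  expect_warning(grade_cost(1.0, 0.45), "validity window")
})

test_that("full prediction reduces to the level-walking model bit-identically", {
  m_rest <- resting_metabolic_rate(60, 77)
  speeds <- seq(0, 1.97, by = 0.07)
  expect_identical(
    predict_metabolic_rate(m_rest, speeds, load_fraction = 0),
    (m_rest + level_walking_terms(speeds)) * 1
  )
  # and the worked loaded example: product of the two components
  expect_equal(predict_metabolic_rate(1.145, 1.34, 0.66),
               (1.145 + 0.19 + 1.78 * 1.34^0.58 + 0.27 * 1.34^4) *
                 (1 + 1.96 * 0.66^1.36))
  expect_equal(predict_metabolic_rate(1.145, 1.34, 0.66), 9.12,
               tolerance = 1e-3)
  # loaded standing cost
  expect_equal(predict_metabolic_rate(1.145, 0, 0.44),
               (1.145 + 0.19) * (1 + 1.96 * 0.44^1.36))
})

test_that("net-of-resting variant multiplies only the exercise component", {
  m_rest <- 1.2
  expect_equal(
    predict_metabolic_rate(m_rest, 1.34, 0.44, net_of_resting = TRUE),
    m_rest + level_walking_terms(1.34) * load_multiplier(0.44)
  )
})

test_that("predictions are strictly increasing in speed, load and terrain", {
  m_rest <- 1.1
  for (seed in 1:5) {
    withr::with_seed(seed, {
      s <- sort(runif(40, 0, 2.0))
      l <- sort(runif(40, 0, 1.0))
      eta <- sort(runif(40, 0.8, 2.2))
    })
    expect_true(all(diff(predict_metabolic_rate(m_rest, s, 0.3)) > 0))
    expect_true(all(diff(predict_metabolic_rate(m_rest, 1.3, l)) > 0))
    expect_true(all(diff(predict_metabolic_rate(m_rest, 1.3, 0.3,
                                                terrain = eta)) > 0))
  }
})

test_that("the model is mass-specific: body size enters only through resting rate", {
  # doubling body and lean mass changes the prediction only via m_rest
  r1 <- predict_metabolic_rate(resting_metabolic_rate(60, 77), 1.34, 0.44)
  r2 <- predict_metabolic_rate(resting_metabolic_rate(120, 154), 1.34, 0.44)
  expect_equal(r2 - r1,
               (resting_metabolic_rate(120, 154) - resting_metabolic_rate(60, 77)) *
                 load_multiplier(0.44))
})

test_that("package evaluation agrees with an independent oracle on a random grid", {
  withr::with_seed(99, {
    S <- runif(1000, 0, 1.97)
    L <- runif(1000, 0, 1)
    m_rest <- runif(1000, 0.9, 1.4)
  })
  expect_equal(predict_metabolic_rate(m_rest, S, L),
               oracle_level_model(m_rest, S, L), tolerance = 1e-12)
})

test_that("coefficient sets validate, round-trip through JSON, and tidy", {
  cs <- lcda_backpacking_coefficients()
  expect_equal(unlist(cs[c("a", "b", "p", "d", "x", "y")]), published_values)
  td <- tidy(cs)
  expect_equal(td$estimate, unname(published_values))
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficients(cs, path)
  back <- read_coefficients(path)
  expect_equal(back[c("a", "b", "p", "d", "x", "y", "name")],
               cs[c("a", "b", "p", "d", "x", "y", "name")])
  expect_error(backpack_coefficients(0.2, 1.8, 1.4, 0.3, 2, 1.4), "p")
  expect_error(backpack_coefficients(0.2, -1, 0.6, 0.3, 2, 1.4), "non-negative")
})

test_that("terrain table is well formed and treadmill is neutral", {
  tc <- terrain_coefficients()
  expect_true(all(tc$eta >= 1))
  expect_equal(tc$eta[tc$surface == "treadmill"], 1.0)
})

test_that("data-frame predictions match the vectorized core", {
  d <- tibble::tibble(m_rest_wkg = 1.1, speed_mps = c(0, 0.89, 1.34),
                      load_fraction = c(0, 0.22, 0.66))
  out <- add_metabolic_predictions(d)
  expect_s3_class(out, "tbl_df")
  expect_equal(out$.pred_m_wkg,
               predict_metabolic_rate(1.1, d$speed_mps, d$load_fraction))
  expect_error(add_metabolic_predictions(d[, "speed_mps"]), "missing required")
})
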