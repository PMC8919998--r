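# ruckmet

Predicting the metabolic cost of heavy backpack load carriage.

Foot marches with modern military rucksacks impose loads up to two-thirds of
body mass, and classic energy-cost equations systematically underestimate
what that costs. `ruckmet` implements the LCDA backpacking equation — a
mass-specific model of steady-state metabolic rate during standing and
walking with backpack loads — together with everything needed to measure,
fit, and validate it: indirect calorimetry with steady-state quality
control, nonlinear mixed fitting with participant random intercepts,
grouped k-fold cross-validation, equivalence (TOST) and agreement (Lin's
CCC) statistics with cluster bootstrap confidence intervals, the Pandolf
and minimum-mechanics comparator models, and a synthetic study generator
so the whole stack is testable without any measured data. It is written
for exercise physiologists, mission planners, and strength-and-conditioning
researchers working with load-carriage energetics.

## The model

$$\dot{M}\,[\mathrm{W\,kg^{-1}}] =
 \left(\dot{M}_{Rest} + a + \eta\,(b S^{p} + d S^{4}) + \dot{M}_{Grade}\right)
 \left(1 + x L_{Bp}^{\,y}\right)$$

* $S$ — walking speed (m·s⁻¹); $L_{Bp}$ — backpack mass / body mass;
  $G$ — decimal grade (rise/run) entering through $\dot{M}_{Grade}$;
  $\eta$ — terrain coefficient (1.0 for treadmill/pavement).
* $\dot{M}_{Rest}$ — resting metabolic rate from lean body mass
  (Cunningham equation), W·kg⁻¹.
* Published coefficients (`lcda_backpacking_coefficients()`):
  $a = 0.19$, $b = 1.78$, $p = 0.58$, $d = 0.27$, $x = 1.96$, $y = 1.36$.
* All rates are W per kg of **body** mass; the carried load is excluded
  from the denominator.

The multiplicative load factor $1 + x L^{y}$ with $y > 1$ is what makes
heavy loads disproportionately costly — the structural feature that linear
total-mass models miss.

## Worked example

Predict the cost of a 77 kg soldier (60 kg lean mass) under several
conditions:

```r
library(ruckmet)

m_rest <- resting_metabolic_rate(lean_mass = 60, body_mass = 77)
#> 1.145  (W/kg)

tibble::tibble(
  m_rest_wkg    = m_rest,
  speed_mps     = c(0, 0.89, 1.34, 1.34),
  load_fraction = c(0.44, 0, 0.44, 0.66)
) |>
  add_metabolic_predictions()
#> # A tibble: 4 × 4
#>   m_rest_wkg speed_mps load_fraction .pred_m_wkg
#> 1       1.14      0             0.44        2.19
#> 2       1.14      0.89          0           3.17
#> 3       1.14      1.34          0.44        7.08
#> 4       1.14      1.34          0.66        9.12
```

Standing with a 44% pack costs 2.19 W/kg (the load multiplies even resting
metabolism); walking at 1.34 m·s⁻¹ rises from 7.08 W/kg with a 44% pack to
9.12 W/kg at 66% — heavier packs cost disproportionately more.

Simulate a full synthetic study (30 participants, 600 trials), refit the
model, and cross-validate it by participant:

```r
study <- simulate_study(seed = 1)
fit <- fit_backpacking_model(study$trials)
tidy(fit)
#>   term  estimate
#> 1 a        0.163
#> 2 b        1.74
#> 3 p        0.636
#> 4 d        0.261
#> 5 x        1.98
#> 6 y        1.32

cv <- cross_validate(study$trials, k = 3, seed = 1, n_boot = 1000)
format_validation(cv$pooled)
#> "bias, -0.05 ± 0.61 W/kg; 90% CI, -0.17 to 0.06 W/kg; CCC, 0.973;
#>  equivalent (P = 3.19e-07)"
```

One noisy study recovers the generating coefficients to within a few
percent; pooled holdout predictions are statistically equivalent to the
simulated measurements within ±10% of the mean measured rate, with a
concordance correlation of 0.97. `autoplot()` methods exist for fits,
validation reports, and cross-validation objects; `plot_cost_curves()`
draws the model surface.

A thin command-line front end ships at `inst/cli/ruckmet`
(`ruckmet simulate|predict|fit|crossval|validate`), writing JSON run
records with seeds and configuration hashes alongside every output.

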