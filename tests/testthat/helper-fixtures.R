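# Shared fixtures: the published coefficient values (frozen independently of
# the constructor), an init perturbed +/-50% for recovery tests, and a small
# paired-difference toy set.

published_values <- c(a = 0.19, b = 1.78, p = 0.58, d = 0.27, x = 1.96, y = 1.36)

perturbed_init <- function(seed) {
  withr::with_seed(seed, {
    v <- published_values * runif(6, 0.5, 1.5)
    backpack_coefficients(
      a = v[["a"]], b = v[["b"]], p = min(v[["p"]], 1), d = v[["d"]],
      x = v[["x"]], y = min(max(v[["y"]], 0.5), 3)
    )
  })
}

# Independent evaluation of the level-walking equation with published
# coefficients, written out in full rather than composed from package parts.
oracle_level_model <- function(m_rest, S, L) {
  (m_rest + 0.19 + 1.78 * S^0.58 + 0.27 * S^4) * (1 + 1.96 * L^1.36)
}

# Paired toy set with three participants and unequal sampling.
toy_pairs <- function() {
  tibble::tibble(
    participant_id = c("a", "a", "a", "a", "a", "a", "b", "b", "c", "c"),
    difference = c(2.0, 2.2, 1.8, 2.1, 1.9, 2.0, 0.1, -0.1, -0.3, -0.1)
  )
}
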