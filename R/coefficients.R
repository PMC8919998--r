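#' Backpacking-model coefficient sets
#'
#' The load-carriage walking model has six free parameters: a constant walking
#' term `a` (W·kg⁻¹), a fractional-power speed term `b·S^p` with coefficient
#' `b` (W·kg⁻¹) and exponent `p` (dimensionless, in (0, 1]), a quartic speed
#' term `d·S⁴` (W·kg⁻¹), and a multiplicative load factor `1 + x·L^y` applied
#' to the whole bracket, where `L` is backpack mass divided by body mass.
#'
#' Some presentations write the speed exponent as a reciprocal, `S^(1/c)`.
#' A single exponent `p = 1/c` is stored here; `c` is reported only for
#' display (see [print.ruckmet_coefficients()]), which avoids carrying a
#' redundant reciprocal parameter through fitting.
#'
#' @param a Constant walking term, W·kg⁻¹. May be any real number.
#' @param b Fractional-speed coefficient, W·kg⁻¹. Must be non-negative.
#' @param p Speed exponent, dimensionless, in (0, 1].
#' @param d Quartic speed coefficient, W·kg⁻¹. Must be non-negative.
#' @param x Load-multiplier scale, dimensionless. Must be non-negative.
#' @param y Load exponent, dimensionless. Must be positive.
#' @param name Short identifier for the set.
#' @param provenance Free-text origin note carried through serialization.
#'
#' @return An object of class `ruckmet_coefficients`: a named list with
#'   elements `a`, `b`, `p`, `d`, `x`, `y`, `name`, `provenance`.
#' @seealso [lcda_backpacking_coefficients()] for the published set,
#'   [read_coefficients()]/[write_coefficients()] for JSON serialization.
#' @export
#' @examples
#' backpack_coefficients(0.2, 1.8, 0.6, 0.25, 2.0, 1.4, name = "demo")
backpack_coefficients <- function(a, b, p, d, x, y,
                                  name = "custom", provenance = NULL) {
  vals <- c(a = a, b = b, p = p, d = d, x = x, y = y)
  if (!all(is.finite(vals))) {
    abort("all six coefficients must be finite numbers")
  }
  if (p <= 0 || p > 1) {
    abort("speed exponent `p` must lie in (0, 1]")
  }
  if (b < 0 || d < 0 || x < 0) {
    abort("`b`, `d` and `x` must be non-negative")
  }
  if (y <= 0) {
    abort("load exponent `y` must be positive")
  }
  structure(
    list(a = a, b = b, p = p, d = d, x = x, y = y,
         name = name, provenance = provenance),
    class = "ruckmet_coefficients"
  )
}

#' Published LCDA backpacking coefficients
#'
#' The coefficient set of the LCDA backpacking equation as published for
#' standing and level walking with backpack loads up to 66% body mass at
#' speeds up to 1.97 m·s⁻¹:
#' \deqn{\dot{M} = (\dot{M}_{Rest} + 0.19 + 1.78\,S^{0.58} + 0.27\,S^4)
#'   (1 + 1.96\,L_{Bp}^{1.36})}
#'
#' @return A `ruckmet_coefficients` object named `"lcda_backpacking_2022"`.
#' @export
#' @examples
#' lcda_backpacking_coefficients()
lcda_backpacking_coefficients <- function() {
  backpack_coefficients(
    a = 0.19, b = 1.78, p = 0.58, d = 0.27, x = 1.96, y = 1.36,
    name = "lcda_backpacking_2022",
    provenance = "published LCDA backpacking equation coefficient set"
  )
}

#' @export
print.ruckmet_coefficients <- function(x, ...) {
  cat("<ruckmet_coefficients> ", x$name, "\n", sep = "")
  cat(sprintf("  M = (M_rest + %.4g + %.4g*S^%.4g + %.4g*S^4) * (1 + %.4g*L^%.4g)\n",
              x$a, x$b, x$p, x$d, x$x, x$y))
  cat(sprintf("  speed exponent p = %.4g (reciprocal form c = 1/p = %.4g)\n",
              x$p, 1 / x$p))
  if (!is.null(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @describeIn backpack_coefficients Tidy a coefficient set into a
#'   two-column tibble of terms and values.
#' @param x A `ruckmet_coefficients` object.
#' @param ... Unused.
#' @export
tidy.ruckmet_coefficients <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "p", "d", "x", "y"),
    estimate = unlist(x[c("a", "b", "p", "d", "x", "y")], use.names = FALSE)
  )
}

coef_vector <- function(coefficients) {
  unlist(coefficients[c("a", "b", "p", "d", "x", "y")], use.names = TRUE)
}

#' Read and write coefficient sets as JSON
#'
#' Coefficient sets are serialized as a flat JSON object with fields
#' `name`, `a`, `b`, `p`, `d`, `x`, `y`, `provenance`.
#'
#' @param path File path.
#' @return `read_coefficients()` returns a `ruckmet_coefficients` object;
#'   `write_coefficients()` returns `path` invisibly.
#' @export
read_coefficients <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("a", "b", "p", "d", "x", "y")
  if (!all(need %in% names(obj))) {
    abort(paste0("coefficient JSON must contain fields: ",
                 paste(need, collapse = ", ")))
  }
  backpack_coefficients(
    a = obj$a, b = obj$b, p = obj$p, d = obj$d, x = obj$x, y = obj$y,
    name = obj$name %||% "unnamed",
    provenance = obj$provenance
  )
}

#' @rdname read_coefficients
#' @param coefficients A `ruckmet_coefficients` object.
#' @export
write_coefficients <- function(coefficients, path) {
  stopifnot(inherits(coefficients, "ruckmet_coefficients"))
  out <- coefficients[c("name", "a", "b", "p", "d", "x", "y", "provenance")]
  if (is.null(out$provenance)) out$provenance <- NA
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Terrain coefficients for common surfaces
#'
#' A small table of multiplicative terrain coefficients (eta) that scale the
#' speed-dependent walking cost for surfaces other than a treadmill or paved
#' road. Values are transcriptions of the classic published terrain factors
#' for foot-march energy-cost models; treadmill walking uses 1.0.
#'
#' @return A tibble with columns `surface` and `eta`.
#' @export
#' @examples
#' terrain_coefficients()
terrain_coefficients <- function() {
  tibble::tibble(
    surface = c("treadmill", "paved_road", "dirt_road", "light_brush",
                "heavy_brush", "swampy_bog", "loose_sand"),
    eta = c(1.0, 1.0, 1.1, 1.2, 1.5, 1.8, 2.1)
  )
}
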