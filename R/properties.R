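#' Temperature-dependent thermophysical property set
#'
#' Bundles polynomial correlations (in kelvin) for density, dynamic viscosity
#' and thermal conductivity together with a constant specific heat, a validity
#' range, and a policy for temperatures outside that range.
#'
#' Coefficients are stored in ascending order (constant term first). The
#' default puree correlations were fitted over a 30-95 degC measurement window
#' and are extrapolated above it; the shipped validity range is therefore
#' [303.15, 400.15] K with `extrapolation_policy = "extrapolate"`.
#'
#' @param density_coeffs numeric, ascending polynomial coefficients, kg/m^3
#'   as a function of T in K.
#' @param viscosity_coeffs numeric, ascending coefficients, Pa s over T in K.
#' @param conductivity_coeffs numeric, ascending coefficients, W/(m K) over T in K.
#' @param specific_heat constant specific heat, J/(kg K).
#' @param valid_range length-2 numeric, validity interval in K.
#' @param extrapolation_policy one of `"extrapolate"` (evaluate anyway, warn),
#'   `"clamp"` (evaluate at the nearest range endpoint) or `"error"`.
#' @param name label used in messages and reports.
#' @return An object of class `thermo_properties`.
#' @seealso [chestnut_puree()], [eval_properties()]
#' @export
thermo_properties <- function(density_coeffs, viscosity_coeffs, conductivity_coeffs,
                              specific_heat,
                              valid_range = c(303.15, 400.15),
                              extrapolation_policy = c("extrapolate", "clamp", "error"),
                              name = "custom") {
  extrapolation_policy <- match.arg(extrapolation_policy)
  stopifnot(is.numeric(density_coeffs), length(density_coeffs) >= 1,
            is.numeric(viscosity_coeffs), length(viscosity_coeffs) >= 1,
            is.numeric(conductivity_coeffs), length(conductivity_coeffs) >= 1,
            is.numeric(specific_heat), length(specific_heat) == 1L, specific_heat > 0,
            length(valid_range) == 2L, valid_range[1] < valid_range[2])
  structure(list(density_coeffs = as.numeric(density_coeffs),
                 viscosity_coeffs = as.numeric(viscosity_coeffs),
                 conductivity_coeffs = as.numeric(conductivity_coeffs),
                 specific_heat = as.numeric(specific_heat),
                 valid_range = as.numeric(valid_range),
                 extrapolation_policy = extrapolation_policy,
                 name = name),
            class = "thermo_properties")
}

#' Built-in chestnut puree property set
#'
#' Default correlations for sweetened chestnut puree (T in kelvin):
#' a quadratic for density, a quintic for apparent viscosity, a quadratic
#' for thermal conductivity, and a constant specific heat of 3860 J/(kg K).
#' The puree is treated as a temperature-dependent Newtonian fluid.
#'
#' @return A `thermo_properties` object named `"chestnut_puree"`.
#' @examples
#' eval_properties(chestnut_puree(), 341.15)
#' @export
chestnut_puree <- function() {
  thermo_properties(
    density_coeffs = c(1225.5567102981, -0.4472664761, -3.5e-9),
    viscosity_coeffs = c(101200.919774749, -1351.86899336611, 7.23213374403098,
                         -0.019355480214816, 2.59069861904587e-5,
                         -1.387024283936e-8),
    conductivity_coeffs = c(0.982, -0.00272, 4.531e-6),
    specific_heat = 3860,
    valid_range = c(303.15, 400.15),
    extrapolation_policy = "extrapolate",
    name = "chestnut_puree")
}

#' Stagnant vapor headspace property set
#'
#' Constant properties used for the water-vapor headspace, which is modelled
#' as a stagnant conductive layer (no flow, no condensation).
#'
#' @param conductivity W/(m K). @param density kg/m^3. @param specific_heat J/(kg K).
#' @return A `thermo_properties` object with degree-0 polynomials.
#' @export
headspace_vapor <- function(conductivity = 0.03, density = 0.8, specific_heat = 2000) {
  thermo_properties(density_coeffs = density,
                    viscosity_coeffs = 1e-5,
                    conductivity_coeffs = conductivity,
                    specific_heat = specific_heat,
                    valid_range = c(1, 1e4),
                    extrapolation_policy = "clamp",
                    name = "headspace_vapor")
}

# plain power-sum evaluation (ascending coefficients); the Horner form is kept
# as an independent oracle in the test suite
poly_eval <- function(coeffs, x) {
  out <- rep(coeffs[1], length(x))
  if (length(coeffs) > 1L) {
    xp <- x
    for (k in 2:length(coeffs)) {
      out <- out + coeffs[k] * xp
      if (k < length(coeffs)) xp <- xp * x
    }
  }
  out
}

police_temperature <- function(props, T) {
  lo <- props$valid_range[1]; hi <- props$valid_range[2]
  out <- which(T < lo | T > hi)
  if (length(out)) {
    switch(props$extrapolation_policy,
      error = stop(sprintf("temperature %.6g K outside valid range [%.6g, %.6g] K for '%s'",
                           T[out[1]], lo, hi, props$name), call. = FALSE),
      clamp = T <- pmin(pmax(T, lo), hi),
      extrapolate = warning(sprintf(
        "extrapolating '%s' properties outside [%.6g, %.6g] K (%d value(s))",
        props$name, lo, hi, length(out)), call. = FALSE))
  }
  T
}

#' Evaluate thermophysical properties at given temperatures
#'
#' Evaluates the property correlations at `T` (kelvin), applying the set's
#' extrapolation policy outside the validity range, and derives the thermal
#' diffusivity `k / (rho * Cp)`.
#'
#' @param props a [thermo_properties()] object.
#' @param T temperatures in K (vectorized).
#' @return A data.frame with columns `temperature`, `density`, `viscosity`,
#'   `conductivity`, `specific_heat`, `thermal_diffusivity`.
#' @examples
#' eval_properties(chestnut_puree(), c(341.15, 394.15))
#' @export
eval_properties <- function(props, T) {
  stopifnot(inherits(props, "thermo_properties"))
  if (!is.numeric(T) || any(!is.finite(T)) || any(T <= 0))
    stop("T must be finite and positive (kelvin)", call. = FALSE)
  T <- police_temperature(props, T)
  rho <- poly_eval(props$density_coeffs, T)
  mu <- poly_eval(props$viscosity_coeffs, T)
  k <- poly_eval(props$conductivity_coeffs, T)
  check_positive <- function(v, what) {
    bad <- which(v <= 0)
    if (length(bad))
      stop(sprintf("evaluated %s is non-positive (%.6g) at T = %.6g K", what,
                   v[bad[1]], T[bad[1]]), call. = FALSE)
  }
  check_positive(rho, "density"); check_positive(mu, "viscosity")
  check_positive(k, "conductivity")
  data.frame(temperature = T, density = rho, viscosity = mu, conductivity = k,
             specific_heat = props$specific_heat,
             thermal_diffusivity = k / (rho * props$specific_heat))
}

#' @export
print.thermo_properties <- function(x, ...) {
  cat(sprintf("<thermo_properties: %s>\n", x$name))
  cat(sprintf("  density poly degree %d, viscosity degree %d, conductivity degree %d\n",
              length(x$density_coeffs) - 1L, length(x$viscosity_coeffs) - 1L,
              length(x$conductivity_coeffs) - 1L))
  cat(sprintf("  specific heat %.0f J/(kg K); valid %.2f-%.2f K; policy %s\n",
              x$specific_heat, x$valid_range[1], x$valid_range[2],
              x$extrapolation_policy))
  invisible(x)
}

# TRUE when every correlation is a constant (degree-0) polynomial; such sets
# admit a time-invariant conduction matrix that the solver factors once
is_constant_props <- function(props) {
  length(props$density_coeffs) == 1L && length(props$viscosity_coeffs) == 1L &&
    length(props$conductivity_coeffs) == 1L
}
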