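#' Size-dependent optimum temperature
#'
#' \eqn{T_{opt}(w) = \gamma_{opt} w^{v_{opt}}}. With the negative exponents
#' of the shipped species, larger fish have colder optima — the mechanism
#' behind ontogenetic shifts in thermal habitat suitability.
#'
#' @param s A [thermal_scaling()].
#' @param w Total body mass (g), > 0. Vectorized.
#' @return Temperature in degC.
#' @export
#' @examples
#' cod <- load_species("cod")
#' thermal_optimum(cod$intake_thermal, 10) # ~14.0 degC
thermal_optimum <- function(s, w) {
  check_mass(w)
  s$gamma_opt * w^s$v_opt
}

#' Size-dependent lethal maximum temperature
#'
#' \eqn{T_{max}(w) = \gamma_{max} w^{v_{max}}}: the upper end of the
#' thermal tolerance window, beyond which the performance factor is zero.
#'
#' @inheritParams thermal_optimum
#' @return Temperature in degC.
#' @export
thermal_maximum <- function(s, w) {
  check_mass(w)
  s$gamma_max * w^s$v_max
}

#' Size-dependent steepness of the thermal performance curve
#'
#' \eqn{Q(w) = \vartheta w^{\theta}}, a Q10-like parameter; must exceed 1
#' for the curve to be well defined (its logarithm enters the exponent).
#'
#' @inheritParams thermal_optimum
#' @return Dimensionless, > 1.
#' @export
thermal_q <- function(s, w) {
  check_mass(w)
  q <- s$theta_coef * w^s$theta_exp
  if (any(q <= 1)) {
    abort("thermal_q: Q(w) <= 1; thermal performance curve is degenerate here",
          class = "thermofish_domain_error")
  }
  q
}

#' Thermal performance factor
#'
#' The dimensionless multiplier \eqn{r(w, T) \in [0, 1]} applied to intake
#' and maintenance rates. It equals 1 at the size-specific optimum
#' \eqn{T_{opt}(w)}, falls off smoothly towards colder temperatures, and
#' drops to 0 at the size-specific lethal maximum \eqn{T_{max}(w)}:
#' \deqn{r = V^X e^{X (1 - V)}, \quad V = \frac{T_{max} - T}{T_{max} - T_{opt}},}
#' \deqn{X = \frac{W^2 \left[1 + \sqrt{1 + 40/Y}\right]^2}{400}, \quad
#'  W = (T_{max} - T_{opt}) \ln Q, \quad Y = (T_{max} - T_{opt} + 2) \ln Q.}
#' For \eqn{T \ge T_{max}} the factor is defined as exactly 0 (the curve's
#' lethal-limit semantics; \eqn{V^X} is undefined there for fractional
#' \eqn{X}).
#'
#' @inheritParams thermal_optimum
#' @param temp Ambient temperature (degC). Vectorized with `w` under the
#'   usual recycling rules.
#' @return Values in `[0, 1]`.
#' @export
#' @examples
#' cod <- load_species("cod")
#' temperature_factor(cod$intake_thermal, 10, 10)  # ~0.85
#' temperature_factor(cod$intake_thermal, 10,
#'                    thermal_optimum(cod$intake_thermal, 10))  # 1
temperature_factor <- function(s, w, temp) {
  check_mass(w)
  t_opt <- s$gamma_opt * w^s$v_opt
  t_max <- s$gamma_max * w^s$v_max
  q <- s$theta_coef * w^s$theta_exp
  if (any(t_max <= t_opt) || any(q <= 1)) {
    abort("temperature_factor: requires T_max(w) > T_opt(w) and Q(w) > 1",
          class = "thermofish_domain_error")
  }
  span <- t_max - t_opt
  lnq <- log(q)
  ww <- span * lnq
  yy <- (span + 2) * lnq
  xx <- ww^2 * (1 + sqrt(1 + 40 / yy))^2 / 400
  v <- (t_max - temp) / span
  r <- ifelse(temp >= t_max, 0, v^xx * exp(xx * (1 - v)))
  pmin(pmax(r, 0), 1)
}

check_mass <- function(w) {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w <= 0)) {
    abort("mass must be a positive finite number (g)",
          class = "thermofish_domain_error")
  }
  invisible(w)
}

#' Tabulate thermal performance curves
#'
#' Diagnostic helper: evaluates the intake and/or maintenance performance
#' curve of a species over a temperature grid at one or more body masses,
#' in long format ready for plotting or CSV export.
#'
#' @param species A `species_params` or shipped species name.
#' @param masses Total body masses (g).
#' @param temps Temperature grid (degC).
#' @param process `"intake"`, `"maintenance"` or both (default).
#' @return A tibble with columns `species`, `process`, `mass_g`,
#'   `temperature`, `factor`.
#' @export
thermal_curve <- function(species, masses = c(1, 10, 100),
                          temps = seq(0, 30, by = 0.25),
                          process = c("intake", "maintenance")) {
  p <- load_species(species)
  process <- match.arg(process, several.ok = TRUE)
  scal <- list(intake = p$intake_thermal, maintenance = p$maintenance_thermal)
  tidyr::expand_grid(process = process, mass_g = masses,
                     temperature = temps) |>
    dplyr::group_by(.data$process, .data$mass_g) |>
    dplyr::mutate(factor = temperature_factor(
      scal[[unique(.data$process)]], unique(.data$mass_g),
      .data$temperature)) |>
    dplyr::ungroup() |>
    dplyr::mutate(species = p$name, .before = 1)
}
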