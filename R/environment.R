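#' Seasonal temperature regime
#'
#' A temperature regime is the sinusoid
#' \deqn{T(t) = T_{mean} + a \sin\!\left(\frac{2\pi (t + \omega)}{GS}\right)}
#' over a growing season of `GS` days (model year). The shipped regimes
#' `"1980s"` (T_mean = 12.85, a = 5.3) and `"2010s"` (T_mean = 14.3,
#' a = 5.25), both with omega = 187 and GS = 250, describe the cooler and
#' warmer decades of western Wadden Sea surface temperature. With this
#' phase the season opens at the annual minimum, peaks mid-season (day
#' 125.5) and closes back at the minimum; the 115 winter days outside the
#' growing season are not part of the simulation clock.
#'
#' @param name Shipped regime name (`"1980s"`, `"2010s"`), a path to a
#'   regime YAML file, or `NULL` when the numeric fields are given.
#' @param T_mean Mean water temperature over the season (degC).
#' @param amplitude Seasonal amplitude `a` (degC), >= 0.
#' @param omega Phase shift (days).
#' @param GS Growing-season length (days), > 0.
#' @return An object of class `temperature_regime`.
#' @export
#' @examples
#' cool <- temperature_regime("1980s")
#' seasonal_temperature(cool, 125.5) # T_mean + a
temperature_regime <- function(name = NULL, T_mean = NULL, amplitude = NULL,
                               omega = 187, GS = 250) {
  if (!is.null(name) && is.null(T_mean)) {
    path <- name
    if (!file.exists(path)) {
      path <- system.file("extdata", "regimes", paste0(name, ".yaml"),
                          package = "thermofish")
      if (!nzchar(path)) {
        abort(paste0("unknown regime '", name, "': not a file and not one of {",
                     paste(regime_names(), collapse = ", "), "}"),
              class = "thermofish_schema_error")
      }
    }
    raw <- yaml::yaml.load_file(path)
    return(temperature_regime(NULL, raw$T_mean, raw$amplitude,
                              raw$omega, raw$GS) |>
             structure_name(raw$name))
  }
  reg <- list(name = if (is.null(name)) "custom" else name,
              T_mean = as.numeric(T_mean), amplitude = as.numeric(amplitude),
              omega = as.numeric(omega), GS = as.numeric(GS))
  if (!is.finite(reg$T_mean) || !is.finite(reg$amplitude) ||
      reg$amplitude < 0 || !is.finite(reg$GS) || reg$GS <= 0) {
    abort("temperature_regime: need finite T_mean, amplitude >= 0, GS > 0",
          class = "thermofish_validation_error")
  }
  structure(reg, class = "temperature_regime")
}

structure_name <- function(reg, nm) {
  if (!is.null(nm)) reg$name <- nm
  reg
}

#' Names of the shipped temperature regimes
#' @return Character vector accepted by [temperature_regime()].
#' @export
regime_names <- function() {
  sort(sub("\\.yaml$", "",
           dir(system.file("extdata", "regimes", package = "thermofish"),
               pattern = "\\.yaml$")))
}

as_regime <- function(x) {
  if (inherits(x, "temperature_regime")) x else temperature_regime(x)
}

#' Water temperature on a given day of the model year
#'
#' @param reg A [temperature_regime()] or shipped regime name.
#' @param t Day of the model year, real-valued in `[0, GS)`. Vectorized.
#'   Values outside the season are a domain error: the caller wraps years.
#' @return Temperature (degC).
#' @export
seasonal_temperature <- function(reg, t) {
  reg <- as_regime(reg)
  if (any(t < 0 | t >= reg$GS)) {
    abort(paste0("seasonal_temperature: t must lie in [0, ", reg$GS, ")"),
          class = "thermofish_domain_error")
  }
  reg$T_mean + reg$amplitude * sin(2 * pi * (t + reg$omega) / reg$GS)
}

#' Count days at or below a temperature threshold
#'
#' Diagnostic utility: number of integer days `t` in `0, ..., GS - 1` whose
#' temperature does not exceed `threshold`. Useful for quantifying the
#' duration of thermally favourable conditions under a regime (e.g. days at
#' or below 11 degC for juvenile cod). Note this summarizes the fitted
#' sinusoid, not the underlying monthly field data, so counts can differ
#' from values quoted directly from observations.
#'
#' @inheritParams seasonal_temperature
#' @param threshold Temperature threshold (degC).
#' @return Integer day count in `[0, GS]`.
#' @export
regime_summary <- function(reg, threshold) {
  reg <- as_regime(reg)
  days <- seq(0, reg$GS - 1)
  sum(seasonal_temperature(reg, days) <= threshold)
}

#' Define a simulation scenario
#'
#' A scenario bundles everything [run_individual()] needs: the species, the
#' temperature regime, the constant feeding level, the Euler step size and
#' the model options. The model is deterministic; `seed` is stored for
#' future stochastic extensions and does not affect results.
#'
#' @param species A `species_params` or shipped species name.
#' @param regime A `temperature_regime` or shipped regime name.
#' @param feeding_level Constant resource level in `[0, 1]`; 1 supports
#'   maximum growth, 0 is starvation. The study levels are 1.0, 0.7, 0.5.
#' @param dt Euler step (days), `0 < dt <= 1`; 1 (daily) is the reference.
#' @param max_years Simulated lifespan cap in model years; defaults to the
#'   species' `max_lifespan_years`.
#' @param thermal_mortality If `TRUE` (default) the individual dies when
#'   ambient temperature reaches the size-specific lethal maximum of the
#'   intake process, `T >= T_max_a(w)`; see the methods vignette for the
#'   rationale. With `FALSE` only starvation and lifespan kill.
#' @param prefeeding_mode Before age `A_f` the individual either does
#'   nothing (`"inert"`, default: egg plus yolk phase treated as
#'   energetically inactive at mass `w_b`) or pays maintenance only
#'   (`"maintenance_only"`).
#' @param thermal_mass_basis Mass at which thermal sizes (`T_opt`, `T_max`,
#'   `Q`) are evaluated: `"total"` (x + y, default) or `"standardized"`
#'   (m(x) = x (1 + q_j)).
#' @param seed Reserved; stored but unused.
#' @return An object of class `fish_scenario`.
#' @export
scenario <- function(species, regime, feeding_level, dt = 1,
                     max_years = NULL, thermal_mortality = TRUE,
                     prefeeding_mode = c("inert", "maintenance_only"),
                     thermal_mass_basis = c("total", "standardized"),
                     seed = 1L) {
  p <- load_species(species)
  reg <- as_regime(regime)
  if (!is.numeric(feeding_level) || length(feeding_level) != 1L ||
      feeding_level < 0 || feeding_level > 1) {
    abort("feeding_level must be a single value in [0, 1]",
          class = "thermofish_domain_error")
  }
  if (dt <= 0 || dt > 1) {
    abort("dt must satisfy 0 < dt <= 1 day",
          class = "thermofish_domain_error")
  }
  structure(list(
    species = p, regime = reg, feeding_level = feeding_level, dt = dt,
    max_years = if (is.null(max_years)) p$max_lifespan_years else max_years,
    thermal_mortality = isTRUE(thermal_mortality),
    prefeeding_mode = match.arg(prefeeding_mode),
    thermal_mass_basis = match.arg(thermal_mass_basis),
    seed = as.integer(seed)
  ), class = "fish_scenario")
}

#' @export
print.fish_scenario <- function(x, ...) {
  cat(sprintf("<fish_scenario> %s | %s regime | feeding level %.2f | dt = %g d\n",
              x$species$name, x$regime$name, x$feeding_level, x$dt))
  invisible(x)
}
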