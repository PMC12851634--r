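#' Plot a simulated life
#'
#' Length-at-age (default), body condition, or the net energy balance over
#' the life of one individual.
#'
#' @param object A `fish_run`.
#' @param what `"length"`, `"condition"` (Fulton's index) or
#'   `"net_energy"` (length-specific, g cm^-1 day^-1).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fish_run <- function(object,
                              what = c("length", "condition", "net_energy"),
                              ...) {
  what <- match.arg(what)
  df <- tidy(object)
  lab <- sprintf("%s | %s | feeding %.2f", df$species[1], df$regime[1],
                 df$feeding_level[1])
  switch(what,
    length = ggplot2::ggplot(df, ggplot2::aes(.data$age_years,
                                              .data$length_cm)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = object$scenario$species$L_m,
                          linetype = "dotted", colour = "grey40") +
      ggplot2::labs(x = "Age (model years)", y = "Length (cm)",
                    title = lab),
    condition = ggplot2::ggplot(df, ggplot2::aes(.data$age_years,
                                                 .data$fulton_k)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Age (model years)", y = "Fulton's condition index",
                    title = lab),
    net_energy = ggplot2::ggplot(df,
                                 ggplot2::aes(.data$age_years,
                                              .data$net_energy_per_length)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                          colour = "grey40") +
      ggplot2::labs(x = "Age (model years)",
                    y = expression(paste("Net energy (g ", cm^-1, " ",
                                         day^-1, ")")),
                    title = lab)
  )
}

#' Plot thermal performance curves
#'
#' Intake and maintenance performance factors against temperature at
#' several body masses, showing how the thermal window narrows and shifts
#' colder as fish grow.
#'
#' @inheritParams thermal_curve
#' @return A ggplot object.
#' @export
plot_thermal_response <- function(species, masses = c(1, 10, 100),
                                  temps = seq(0, 30, by = 0.25)) {
  df <- thermal_curve(species, masses, temps)
  ggplot2::ggplot(df, ggplot2::aes(.data$temperature, .data$factor,
                                   colour = factor(.data$mass_g))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~process) +
    ggplot2::labs(x = "Temperature (°C)", y = "Performance factor",
                  colour = "Mass (g)", title = df$species[1])
}

#' Plot the shipped seasonal temperature regimes
#'
#' @param regimes Regime names or `temperature_regime` objects.
#' @return A ggplot object.
#' @export
plot_regimes <- function(regimes = regime_names()) {
  df <- purrr::map_dfr(regimes, function(r) {
    reg <- as_regime(r)
    day <- seq(0, reg$GS - 1, by = 0.5)
    tibble::tibble(regime = reg$name, day = day,
                   temperature = seasonal_temperature(reg, day))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$temperature,
                                   colour = .data$regime)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Day of growing season", y = "Temperature (°C)",
                  colour = "Regime")
}
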