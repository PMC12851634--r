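#' Individual physiological state
#'
#' The state of one fish: structural mass `x` (g, never decreases),
#' reserve mass `y` (g, burned under energy deficits), age in days since
#' the start of the first growing season, and the maturity and alive
#' flags. The ratio `y / x` is the model's body condition.
#'
#' @param x Structural mass (g), > 0.
#' @param y Reserve mass (g), >= 0.
#' @param age_days Age in days (model clock; 250 days per year).
#' @param mature Has the individual passed the maturation length?
#' @param alive Is the individual alive?
#' @return An object of class `individual_state`.
#' @export
individual_state <- function(x, y, age_days = 0, mature = FALSE,
                             alive = TRUE) {
  if (!is.finite(x) || x <= 0) {
    abort("individual_state: structural mass x must be > 0",
          class = "thermofish_validation_error")
  }
  if (!is.finite(y) || y < 0) {
    abort("individual_state: reserve mass y must be >= 0",
          class = "thermofish_validation_error")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 age_days = as.numeric(age_days),
                 mature = isTRUE(mature), alive = isTRUE(alive)),
            class = "individual_state")
}

#' @export
print.individual_state <- function(x, ...) {
  cat(sprintf(
    "<individual_state> x = %.4g g, y = %.4g g (y/x = %.3f), age %.1f d, %s%s\n",
    x$x, x$y, x$y / x$x, x$age_days,
    if (x$mature) "adult" else "juvenile",
    if (x$alive) "" else ", dead"))
  invisible(x)
}

#' Standardized mass
#'
#' \eqn{m(x) = x (1 + q_j)}: structural mass plus reserves at the juvenile
#' maximum, excluding any gonadic build-up beyond `q_j x`. This is the size
#' measure driving the length and intake allometries, so a gravid adult is
#' no longer or hungrier than a spent one of equal structure.
#'
#' @param p A `species_params`.
#' @param st An `individual_state`.
#' @return Mass (g).
#' @export
standardized_mass <- function(p, st) {
  st$x * (1 + p$q_j)
}

#' Body length from the length-mass allometry
#'
#' \eqn{L(x) = \lambda_1 m(x)^{\lambda_2}} (cm). Depends on structural mass
#' only, so length never shrinks during starvation.
#'
#' @inheritParams standardized_mass
#' @return Length (cm).
#' @export
body_length <- function(p, st) {
  p$lambda1 * standardized_mass(p, st)^p$lambda2
}

#' Fulton's condition index
#'
#' \eqn{K = 100\, (x + y) / L^3} with mass in g and length in cm — the
#' standard field measure of plumpness, exposed for comparison with survey
#' data. The model's internal condition measure is [condition_ratio()].
#'
#' @inheritParams standardized_mass
#' @return Dimensionless index (typically 0.5-1.5 for round fish).
#' @export
fulton_condition <- function(p, st) {
  100 * (st$x + st$y) / body_length(p, st)^3
}

#' Reserve-to-structure condition ratio
#'
#' `y / x`, the model's body condition; bounded by `q_j` (juveniles) or
#' `q_a` (adults) under the allocation rule.
#'
#' @inheritParams standardized_mass
#' @return Dimensionless ratio >= 0.
#' @export
condition_ratio <- function(p, st) {
  st$y / st$x
}

# thermal sizes are evaluated at total mass x + y by default; the
# standardized-mass alternative follows the intake row's r_a(m(x), T)
# notation and is selectable per scenario.
thermal_basis_mass <- function(p, st, basis = "total") {
  if (identical(basis, "standardized")) standardized_mass(p, st)
  else st$x + st$y
}

#' Daily food intake
#'
#' \eqn{I = d_1 m(x)^{d_2}\, r_a(w, T)\, R_l} (g/day): the intake allometry
#' at standardized mass, cut by the thermal performance factor of the
#' acquisition process and by the feeding level.
#'
#' @inheritParams standardized_mass
#' @param temp Ambient temperature (degC).
#' @param feeding_level Resource level in `[0, 1]`.
#' @param thermal_mass_basis `"total"` or `"standardized"`; see
#'   [scenario()].
#' @return Intake (g/day).
#' @export
intake <- function(p, st, temp, feeding_level,
                   thermal_mass_basis = "total") {
  if (feeding_level < 0 || feeding_level > 1) {
    abort("feeding_level must lie in [0, 1]",
          class = "thermofish_domain_error")
  }
  r_a <- temperature_factor(p$intake_thermal,
                            thermal_basis_mass(p, st, thermal_mass_basis),
                            temp)
  p$d1 * standardized_mass(p, st)^p$d2 * r_a * feeding_level
}

#' Daily maintenance requirement
#'
#' \eqn{E_m = \rho_1 (x + y)^{\rho_2}\, r_m(w, T)} (g/day): maintenance is
#' paid on total mass — gonads included — and is modulated by the thermal
#' performance factor of the metabolic process.
#'
#' @inheritParams intake
#' @return Maintenance cost (g/day).
#' @export
maintenance <- function(p, st, temp, thermal_mass_basis = "total") {
  r_m <- temperature_factor(p$maintenance_thermal,
                            thermal_basis_mass(p, st, thermal_mass_basis),
                            temp)
  p$rho1 * (st$x + st$y)^p$rho2 * r_m
}

#' All per-day physiological rates as one record
#'
#' Computes intake, acquired (assimilated) energy \eqn{E_a = k_e I},
#' maintenance \eqn{E_m}, the net energy balance \eqn{E_g = E_a - E_m} and
#' the allocation fraction, in one consistent bundle.
#'
#' @inheritParams intake
#' @return A one-row tibble with columns `temperature`, `r_intake`,
#'   `r_maint`, `intake`, `acquired`, `maintenance`, `net_energy`,
#'   `alloc_fraction`.
#' @export
net_energy <- function(p, st, temp, feeding_level,
                       thermal_mass_basis = "total") {
  wt <- thermal_basis_mass(p, st, thermal_mass_basis)
  r_a <- temperature_factor(p$intake_thermal, wt, temp)
  r_m <- temperature_factor(p$maintenance_thermal, wt, temp)
  i <- p$d1 * standardized_mass(p, st)^p$d2 * r_a * feeding_level
  e_a <- p$k_e * i
  e_m <- p$rho1 * (st$x + st$y)^p$rho2 * r_m
  tibble::tibble(
    temperature = temp, r_intake = r_a, r_maint = r_m,
    intake = i, acquired = e_a, maintenance = e_m,
    net_energy = e_a - e_m,
    alloc_fraction = allocation_fraction(p, st)
  )
}

#' Fraction of surplus energy allocated to structure
#'
#' The condition-dependent allocation rule. With `q = q_j` (juveniles) or
#' `q_a` (adults):
#' \deqn{f(x, y) = \frac{1}{(1 + q) q^2} \left(\frac{y}{x}\right)^2
#'   \quad\text{if } y/x < q, \qquad f = \frac{1}{1 + q}
#'   \quad\text{otherwise.}}
#' Low condition sends almost all surplus to reserves (the quadratic
#' vanishes as y goes to 0: recovery of condition takes priority over
#' skeletal growth); at the ceiling `y/x = q` the split keeps condition
#' constant. Both branches agree at the switch point.
#'
#' @inheritParams standardized_mass
#' @return Fraction in `(0, 1/(1+q)]`.
#' @export
allocation_fraction <- function(p, st) {
  q <- if (st$mature) p$q_a else p$q_j
  cond <- st$y / st$x
  if (cond < q) cond^2 / ((1 + q) * q^2) else 1 / (1 + q)
}

#' State derivatives under the allocation rule
#'
#' When the energy balance is positive, the surplus is split between
#' structure (`f E_g`) and reserves (`(1 - f) E_g`); when negative, the
#' whole deficit is drawn from reserves and structure is untouched:
#' \deqn{dx/dt = f E_g \;[E_g > 0], \qquad
#'       dy/dt = (1 - f) E_g \;[E_g > 0] \;\text{ or }\; E_g \;[E_g \le 0].}
#'
#' @inheritParams intake
#' @return Named numeric vector `c(dx, dy)` (g/day).
#' @export
state_derivatives <- function(p, st, temp, feeding_level,
                              thermal_mass_basis = "total") {
  e_g <- net_energy(p, st, temp, feeding_level,
                    thermal_mass_basis)$net_energy
  if (e_g > 0) {
    f <- allocation_fraction(p, st)
    c(dx = f * e_g, dy = (1 - f) * e_g)
  } else {
    c(dx = 0, dy = e_g)
  }
}

#' Potential fecundity of the current state
#'
#' \deqn{F(x, y) = \frac{k_r (y - q_j x)}{w_b} \quad\text{if } L > L_m
#'   \text{ and } y > q_j x; \qquad 0 \text{ otherwise.}}
#' Reserves above the juvenile ceiling `q_j x` are gonads; they convert to
#' eggs of mass `w_b` with efficiency `k_r`. Returned as a real number;
#' spawning events floor it to whole eggs.
#'
#' @inheritParams standardized_mass
#' @return Egg count (non-negative real).
#' @export
fecundity <- function(p, st) {
  if (body_length(p, st) > p$L_m && st$y > p$q_j * st$x) {
    p$k_r * (st$y - p$q_j * st$x) / p$w_b
  } else {
    0
  }
}
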