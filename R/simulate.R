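#' Newborn state for a species
#'
#' A newborn carries the species' egg mass `w_b`, split so that its
#' condition sits exactly at the juvenile ceiling: `x = w_b / (1 + q_j)`,
#' `y = q_j w_b / (1 + q_j)` — the standard newborn convention in
#' physiologically structured consumer-resource models.
#'
#' @param p A `species_params` (or shipped species name).
#' @return An [individual_state()] at age 0, immature, alive.
#' @export
#' @examples
#' initial_state(load_species("cod"))
initial_state <- function(p) {
  p <- load_species(p)
  x <- p$w_b / (1 + p$q_j)
  individual_state(x = x, y = p$q_j * x)
}

# one Euler step evaluated at day-start temperature; returns the updated
# state plus the rates that produced it.  status: 0 alive, 1 starved,
# 2 thermal death.  Shared by step_day() and run_individual().
.step_core <- function(p, x, y, mature, temp, feeding_level, dt,
                       thermal_mortality, basis_standardized) {
  m <- x * (1 + p$q_j)
  w <- x + y
  wt <- if (basis_standardized) m else w
  it <- p$intake_thermal
  mt <- p$maintenance_thermal
  t_max_a <- it$gamma_max * wt^it$v_max
  if (thermal_mortality && temp >= t_max_a) {
    return(c(x = x, y = y, status = 2, r_a = 0, r_m = 0, i = 0,
             e_a = 0, e_m = 0, e_g = 0))
  }
  r_a <- .tfac(it, wt, temp)
  r_m <- .tfac(mt, wt, temp)
  i <- p$d1 * m^p$d2 * r_a * feeding_level
  e_a <- p$k_e * i
  e_m <- p$rho1 * w^p$rho2 * r_m
  e_g <- e_a - e_m
  status <- 0
  if (e_g > 0) {
    q <- if (mature) p$q_a else p$q_j
    cond <- y / x
    f <- if (cond < q) cond^2 / ((1 + q) * q^2) else 1 / (1 + q)
    x <- x + f * e_g * dt
    y <- y + (1 - f) * e_g * dt
  } else if (e_g < 0) {
    y <- y + e_g * dt
    if (y <= 0) {
      y <- 0
      status <- 1
    }
  }
  c(x = x, y = y, status = status, r_a = r_a, r_m = r_m, i = i,
    e_a = e_a, e_m = e_m, e_g = e_g)
}

# scalar thermal performance factor without argument checking (hot loop)
.tfac <- function(s, w, temp) {
  t_max <- s$gamma_max * w^s$v_max
  if (temp >= t_max) return(0)
  t_opt <- s$gamma_opt * w^s$v_opt
  span <- t_max - t_opt
  lnq <- log(s$theta_coef * w^s$theta_exp)
  ww <- span * lnq
  yy <- (span + 2) * lnq
  xx <- ww^2 * (1 + sqrt(1 + 40 / yy))^2 / 400
  v <- (t_max - temp) / span
  min(v^xx * exp(xx * (1 - v)), 1)
}

#' Advance an individual by one (partial) day
#'
#' Explicit Euler update of the state at the day-start temperature of the
#' regime, including the pre-feeding phase (no physiology before age
#' `A_f`), the negative-reserve guard (the step truncates at `y = 0` and
#' the individual dies of starvation) and, when enabled, thermal mortality
#' at the size-specific lethal maximum. Maturity is re-evaluated after the
#' update. Used by [run_individual()]; exposed for stepwise inspection.
#'
#' @param p A `species_params`.
#' @param st An `individual_state`; must be alive.
#' @param reg A [temperature_regime()] (or shipped name).
#' @param feeding_level Resource level in `[0, 1]`.
#' @param dt Step size (days), `0 < dt <= 1`.
#' @param thermal_mortality,prefeeding_mode,thermal_mass_basis See
#'   [scenario()].
#' @return The updated `individual_state`.
#' @export
step_day <- function(p, st, reg, feeding_level, dt = 1,
                     thermal_mortality = TRUE,
                     prefeeding_mode = "inert",
                     thermal_mass_basis = "total") {
  if (!st$alive) {
    abort("step_day: individual is dead", class = "thermofish_state_error")
  }
  if (dt <= 0 || dt > 1) {
    abort("step_day: dt must satisfy 0 < dt <= 1",
          class = "thermofish_domain_error")
  }
  p <- load_species(p)
  reg <- as_regime(reg)
  t_day <- st$age_days %% reg$GS
  temp <- seasonal_temperature(reg, t_day)
  x <- st$x; y <- st$y; status <- 0
  if (st$age_days >= p$A_f) {
    out <- .step_core(p, x, y, st$mature, temp, feeding_level, dt,
                      thermal_mortality,
                      identical(thermal_mass_basis, "standardized"))
    x <- out[["x"]]; y <- out[["y"]]; status <- out[["status"]]
  } else if (identical(prefeeding_mode, "maintenance_only")) {
    r_m <- .tfac(p$maintenance_thermal, x + y, temp)
    y <- y - p$rho1 * (x + y)^p$rho2 * r_m * dt
    if (y <= 0) {
      y <- 0
      status <- 1
    }
  }
  st2 <- individual_state(x, y, st$age_days + dt,
                          mature = st$mature, alive = status == 0)
  if (!st2$mature && body_length(p, st2) >= p$L_m) st2$mature <- TRUE
  st2
}

#' Annual spawning event
#'
#' On the first day of each model year after the first, a mature
#' individual converts all gonadic reserves — everything above the
#' juvenile condition ceiling `q_j x` — into eggs:
#' `eggs = floor(k_r (y - q_j x) / w_b)`, after which `y = q_j x`.
#' Immature individuals, and adults at or below the threshold condition,
#' are unchanged and no record is emitted.
#'
#' @param p A `species_params`.
#' @param st An `individual_state`.
#' @return A list with the updated `state` and `record` (a one-row tibble
#'   of the spawning event, or `NULL` when nothing was spawned).
#' @export
spawn_event <- function(p, st) {
  p <- load_species(p)
  if (!st$mature || st$y <= p$q_j * st$x) {
    return(list(state = st, record = NULL))
  }
  gonads <- st$y - p$q_j * st$x
  eggs <- floor(p$k_r * gonads / p$w_b)
  pre <- st
  st$y <- p$q_j * st$x
  record <- if (eggs >= 1) {
    tibble::tibble(
      event_year_label = floor(pre$age_days / 250),
      eggs = eggs,
      gonad_mass_removed = gonads,
      pre_x = pre$x, pre_y = pre$y, post_x = st$x, post_y = st$y,
      age_years = pre$age_days / 250
    )
  } else {
    NULL
  }
  list(state = st, record = record)
}

#' Simulate one individual's whole life
#'
#' Integrates the individual from egg mass to death or the species'
#' maximum lifespan with explicit Euler steps (daily by default), over
#' consecutive growing seasons of `GS` days. Reproduction happens on the
#' first day of each model year from the second year on, before that day's
#' feeding. Death occurs by starvation (reserves exhausted), by crossing
#' the size-specific lethal temperature (if `thermal_mortality`), or at
#' the lifespan cap. The model is fully deterministic: identical scenarios
#' give bit-identical output.
#'
#' @param scn A [scenario()].
#' @return An object of class `fish_run`: a list with
#'   \describe{
#'     \item{trajectory}{tibble of per-step records (year, day, state,
#'       rates, length, condition, net energy per length).}
#'     \item{spawning}{tibble of spawning events (possibly 0 rows). The
#'       `event_year_label` of an event at the start of model year `n + 1`
#'       is `n` — the age in completed years.}
#'     \item{death}{list with `cause` (`"starvation"`, `"thermal"`,
#'       `"lifespan"`) and `age_years`.}
#'     \item{scenario}{the input scenario.}
#'   }
#' @export
#' @examples
#' run <- run_individual(scenario("sprat", "1980s", 1.0))
#' glance(run)
run_individual <- function(scn) {
  stopifnot(inherits(scn, "fish_scenario"))
  p <- scn$species
  reg <- scn$regime
  dt <- scn$dt
  gs <- reg$GS
  rl <- scn$feeding_level
  basis_std <- identical(scn$thermal_mass_basis, "standardized")
  maint_only <- identical(scn$prefeeding_mode, "maintenance_only")
  nsteps <- round(gs / dt)
  tgrid <- (seq_len(nsteps) - 1) * dt
  temps <- reg$T_mean + reg$amplitude * sin(2 * pi * (tgrid + reg$omega) / gs)

  n_max <- scn$max_years * nsteps
  rec <- matrix(NA_real_, nrow = n_max, ncol = 18)
  colnames(rec) <- c("model_year", "day_in_year", "age_years", "temperature",
                     "x", "y", "total_mass", "length_cm", "condition_yx",
                     "fulton_k", "r_intake", "r_maint", "intake", "acquired",
                     "maintenance", "net_energy", "net_energy_per_length",
                     "mature")
  spawns <- list()

  x <- p$w_b / (1 + p$q_j)
  y <- p$q_j * x
  mature <- FALSE
  age <- 0
  cause <- "lifespan"
  k <- 0L

  for (yr in seq_len(scn$max_years)) {
    if (yr >= 2 && mature && y > p$q_j * x) {
      gonads <- y - p$q_j * x
      eggs <- floor(p$k_r * gonads / p$w_b)
      if (eggs >= 1) {
        spawns[[length(spawns) + 1L]] <- c(
          event_year_label = yr - 1, eggs = eggs,
          gonad_mass_removed = gonads, pre_x = x, pre_y = y,
          post_x = x, post_y = p$q_j * x, age_years = age / 250)
      }
      y <- p$q_j * x
    }
    for (i in seq_len(nsteps)) {
      temp <- temps[i]
      r_a <- NA_real_; r_m <- NA_real_
      iv <- 0; e_a <- 0; e_m <- 0; e_g <- 0
      if (age >= p$A_f) {
        out <- .step_core(p, x, y, mature, temp, rl, dt,
                          scn$thermal_mortality, basis_std)
        x <- out[["x"]]; y <- out[["y"]]
        r_a <- out[["r_a"]]; r_m <- out[["r_m"]]; iv <- out[["i"]]
        e_a <- out[["e_a"]]; e_m <- out[["e_m"]]; e_g <- out[["e_g"]]
        if (out[["status"]] == 1) cause <- "starvation"
        if (out[["status"]] == 2) cause <- "thermal"
      } else if (maint_only) {
        r_m <- .tfac(p$maintenance_thermal, x + y, temp)
        e_m <- p$rho1 * (x + y)^p$rho2 * r_m
        e_g <- -e_m
        y <- y - e_m * dt
        if (y <= 0) {
          y <- 0
          cause <- "starvation"
        }
      }
      age <- age + dt
      len <- p$lambda1 * (x * (1 + p$q_j))^p$lambda2
      if (!mature && len >= p$L_m) mature <- TRUE
      k <- k + 1L
      rec[k, ] <- c(yr, tgrid[i], age / 250, temp, x, y, x + y, len,
                    y / x, 100 * (x + y) / len^3, r_a, r_m, iv, e_a, e_m,
                    e_g, e_g / len, as.numeric(mature))
      if (cause != "lifespan") break
    }
    if (cause != "lifespan") break
  }

  traj <- tibble::as_tibble(rec[seq_len(k), , drop = FALSE])
  traj$model_year <- as.integer(traj$model_year)
  traj$mature <- traj$mature > 0
  spawning <- if (length(spawns)) {
    tibble::as_tibble(do.call(rbind, spawns))
  } else {
    tibble::tibble(event_year_label = numeric(), eggs = numeric(),
                   gonad_mass_removed = numeric(), pre_x = numeric(),
                   pre_y = numeric(), post_x = numeric(),
                   post_y = numeric(), age_years = numeric())
  }
  structure(list(trajectory = traj, spawning = spawning,
                 death = list(cause = cause, age_years = age / 250),
                 scenario = scn),
            class = "fish_run")
}

#' @export
print.fish_run <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<fish_run> %s | %s | feeding %.2f\n  died of %s at %.2f model years; max length %.1f cm; %d spawning event(s), %s eggs\n",
    x$scenario$species$name, x$scenario$regime$name,
    x$scenario$feeding_level, g$death_cause, g$death_age_years,
    g$max_length_cm, g$n_spawning_events,
    format(g$lifetime_eggs, big.mark = " ")))
  invisible(x)
}

#' Cumulative egg production over a life
#'
#' @param records The `spawning` tibble of a [run_individual()] result (or
#'   a `fish_run` itself).
#' @return A tibble with one row per spawning event: `event_year_label`,
#'   `eggs`, `cumulative_eggs`. The grand total is the last cumulative
#'   value (0 events give 0 rows).
#' @export
lifetime_fecundity <- function(records) {
  if (inherits(records, "fish_run")) records <- records$spawning
  records |>
    dplyr::arrange(.data$event_year_label) |>
    dplyr::transmute(event_year_label = .data$event_year_label,
                     eggs = .data$eggs,
                     cumulative_eggs = cumsum(.data$eggs))
}

#' Run the full scenario grid
#'
#' Simulates every combination of the requested species, regimes and
#' feeding levels (by default the full 5 x 2 x 3 study design) and returns
#' one summary row per run, with the `fish_run` objects in a list-column.
#'
#' @param species Character vector of species names (or list of
#'   `species_params`).
#' @param regimes Character vector of regime names (or list of regimes).
#' @param feeding_levels Numeric vector of feeding levels.
#' @param ... Passed on to [scenario()] (e.g. `dt`, `thermal_mortality`).
#' @return A tibble with columns `species`, `regime`, `feeding_level`,
#'   `max_length_cm`, `death_age_years`, `death_cause`,
#'   `n_spawning_events`, `lifetime_eggs`, `run`.
#' @export
run_grid <- function(species = species_names(), regimes = regime_names(),
                     feeding_levels = c(0.5, 0.7, 1.0), ...) {
  grid <- tidyr::expand_grid(species = species, regime = regimes,
                             feeding_level = feeding_levels)
  runs <- purrr::pmap(grid, function(species, regime, feeding_level) {
    run_individual(scenario(species, regime, feeding_level, ...))
  })
  dplyr::bind_cols(
    purrr::map_dfr(runs, glance),
    tibble::tibble(run = runs)
  )
}
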