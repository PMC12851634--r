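test_that("newborns start at egg mass with condition at the juvenile ceiling", {
  cod <- load_species("cod")
  st <- initial_state(cod)
  expect_equal(st$x, 0.00039 / 1.7, tolerance = 1e-12)
  expect_equal(st$y, 0.7 * 0.00039 / 1.7, tolerance = 1e-12)
  expect_equal(st$x + st$y, cod$w_b, tolerance = 1e-15)
  expect_false(st$mature)
  expect_true(st$alive)

  for (p in shipped_species()) {
    st <- initial_state(p)
    expect_equal(condition_ratio(p, st), p$q_j, tolerance = 1e-12)
    expect_equal(body_length(p, st), p$lambda1 * p$w_b^p$lambda2,
                 tolerance = 1e-12)
  }
})

test_that("daily steps starve reserves, conserve energy and refuse dead fish", {
  herring <- load_species("herring")
  reg <- temperature_regime("1980s")

  # starvation: y decreases, x untouched (past the pre-feeding phase)
  st <- individual_state(5, 3, age_days = 100)
  st2 <- step_day(herring, st, reg, 0)
  expect_identical(st2$x, st$x)
  expect_lt(st2$y, st$y)

  # growth: mass gain equals the energy balance times dt
  st <- individual_state(5, 3, age_days = 60)
  nb <- net_energy(herring, st, seasonal_temperature(reg, 60), 1)
  st2 <- step_day(herring, st, reg, 1)
  expect_gt(nb$net_energy, 0)
  expect_equal((st2$x + st2$y) - (st$x + st$y), nb$net_energy,
               tolerance = 1e-12)
  expect_gt(st2$x, st$x)

  # a step that would push y below zero truncates at 0 and kills
  st <- individual_state(5, 1e-6, age_days = 100)
  st2 <- step_day(herring, st, reg, 0)
  expect_identical(st2$y, 0)
  expect_false(st2$alive)
  expect_error(step_day(herring, st2, reg, 0),
               class = "thermofish_state_error")
})

test_that("spawning converts the gonad surplus to eggs and resets condition", {
  sprat <- load_species("sprat")
  st <- individual_state(10, 10, age_days = 500, mature = TRUE)
  out <- spawn_event(sprat, st)
  expect_equal(out$record$eggs, 1000)
  expect_equal(out$state$y, sprat$q_j * 10)
  expect_identical(out$state$x, st$x)
  expect_equal(out$record$gonad_mass_removed, 1)
  expect_equal(out$record$event_year_label, 2)

  # immature: unchanged, no record
  juv <- individual_state(10, 10, mature = FALSE)
  out <- spawn_event(sprat, juv)
  expect_null(out$record)
  expect_identical(out$state$y, juv$y)

  # boundary: exactly at threshold condition, nothing happens
  at <- individual_state(10, 9, mature = TRUE)
  out <- spawn_event(sprat, at)
  expect_null(out$record)
  expect_identical(out$state$y, 9)
})

test_that("whole-life runs are deterministic", {
  a <- run_individual(scenario("rockling", "2010s", 0.7))
  b <- run_individual(scenario("rockling", "2010s", 0.7))
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$spawning, b$spawning)
  expect_identical(a$death, b$death)
})

test_that("trajectories respect structural invariants", {
  for (sc in list(scenario("sprat", "1980s", 1.0),
                  scenario("herring", "2010s", 0.7),
                  scenario("mullet", "2010s", 0.5))) {
    run <- run_individual(sc)
    traj <- run$trajectory
    expect_true(all(diff(traj$length_cm) > -1e-12))   # length never shrinks
    expect_true(all(diff(traj$x) > -1e-12))           # structure never shrinks
    expect_true(all(traj$y >= 0))
    expect_equal(traj$net_energy_per_length,
                 traj$net_energy / traj$length_cm, tolerance = 1e-12)
    expect_equal(traj$total_mass, traj$x + traj$y, tolerance = 1e-12)
    # records stop at death or lifespan
    expect_lte(nrow(traj), sc$max_years * 250)
  }
})

test_that("cod never matures or spawns in any of the six study scenarios", {
  for (reg in c("1980s", "2010s")) {
    for (rl in c(0.5, 0.7, 1.0)) {
      run <- run_individual(scenario("cod", reg, rl))
      expect_identical(nrow(run$spawning), 0L)
      expect_false(any(run$trajectory$mature))
    }
  }
})

test_that("rockling hits a mid-season energy deficit and recovers in autumn", {
  # year 1, both regimes at the high feeding level; under the warm regime
  # the deficit window opens at every feeding level
  cases <- rbind(expand.grid(reg = c("1980s", "2010s"), rl = 1.0),
                 expand.grid(reg = "2010s", rl = c(0.5, 0.7)))
  for (i in seq_len(nrow(cases))) {
    run <- run_individual(scenario("rockling", as.character(cases$reg[i]),
                                   cases$rl[i]))
    y1 <- dplyr::filter(run$trajectory, model_year == 1)
    neg <- which(y1$net_energy < 0)
    expect_gt(length(neg), 0)
    expect_true(all(y1$day_in_year[neg] > 75 & y1$day_in_year[neg] < 175))
    after <- y1$net_energy[(max(neg) + 1):nrow(y1)]
    expect_true(any(after > 0))
  }
})

test_that("length-at-age increases with feeding level while runs are alive", {
  # the Fig 3-4 pattern: at any common age attained by all three feeding
  # levels, more food means longer fish
  for (sp in species_names()) {
    for (reg in regime_names()) {
      runs <- lapply(c(0.5, 0.7, 1.0), function(rl) {
        run_individual(scenario(sp, reg, rl))
      })
      n <- min(vapply(runs, function(r) nrow(r$trajectory), integer(1)))
      idx <- seq(25, n, by = 25)
      l5 <- runs[[1]]$trajectory$length_cm[idx]
      l7 <- runs[[2]]$trajectory$length_cm[idx]
      l10 <- runs[[3]]$trajectory$length_cm[idx]
      expect_true(all(l5 <= l7 + 1e-9), label = paste(sp, reg, "0.5 vs 0.7"))
      expect_true(all(l7 <= l10 + 1e-9), label = paste(sp, reg, "0.7 vs 1.0"))
    }
  }
})

test_that("daily Euler agrees with a 10x finer step within 1% on final length", {
  for (sp in species_names()) {
    for (reg in regime_names()) {
      for (rl in c(0.5, 1.0)) {
        coarse <- run_individual(scenario(sp, reg, rl, dt = 1))
        if (coarse$death$age_years < 1) next  # compare survivors of year 1
        fine <- run_individual(scenario(sp, reg, rl, dt = 0.1))
        lc <- max(coarse$trajectory$length_cm)
        lf <- max(fine$trajectory$length_cm)
        expect_lt(abs(lc - lf) / lc, 0.01, label = paste(sp, reg, rl))
      }
    }
  }
})

test_that("lifetime fecundity accumulates per event", {
  run <- run_individual(scenario("sprat", "1980s", 1.0))
  lf <- lifetime_fecundity(run)
  expect_identical(lf$cumulative_eggs, cumsum(lf$eggs))
  expect_identical(lf$cumulative_eggs[nrow(lf)], sum(run$spawning$eggs))
  expect_true(all(diff(lf$event_year_label) > 0))

  empty <- lifetime_fecundity(tibble::tibble(event_year_label = numeric(),
                                             eggs = numeric()))
  expect_identical(nrow(empty), 0L)
})

test_that("death causes and option switches behave as documented", {
  # warm high-food herring dies crossing its lethal limit in year 1
  warm <- run_individual(scenario("herring", "2010s", 1.0))
  expect_identical(warm$death$cause, "thermal")
  expect_lt(warm$death$age_years, 1)

  # without thermal mortality the same scenario survives the peak
  nolethal <- run_individual(scenario("herring", "2010s", 1.0,
                                      thermal_mortality = FALSE))
  expect_gt(nolethal$death$age_years, 1)

  # lifespan death when nothing else intervenes
  rock <- run_individual(scenario("rockling", "1980s", 0.7))
  expect_identical(rock$death$cause, "lifespan")
  expect_equal(rock$death$age_years, 4)

  # maintenance-only pre-feeding drains the yolk slightly; inert leaves it
  # untouched at the egg mass
  p <- load_species("mullet")
  inert <- run_individual(scenario("mullet", "1980s", 1.0))
  paying <- run_individual(scenario("mullet", "1980s", 1.0,
                                    prefeeding_mode = "maintenance_only"))
  last_prefeed <- p$A_f - 1
  expect_equal(inert$trajectory$total_mass[last_prefeed], p$w_b,
               tolerance = 1e-15)
  expect_lt(paying$trajectory$total_mass[last_prefeed], p$w_b)
})
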