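---
title: "The thermofish model: physiology, forcing and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The thermofish model: physiology, forcing and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofish)
```

## The individual and its energy budget

`thermofish` simulates one fish at a time, deterministically, on a daily
clock. The individual's state is two masses:

* **structural mass** `x` (g) — bones and vital organs, irreversible:
  it can never be catabolized, so body length never shrinks;
* **reserve mass** `y` (g) — fat, muscle and gonad tissue, reversible:
  it is built up in good times and burned when maintenance cannot be met.

Total mass is `w = x + y` and the **condition** is the ratio `y/x`.
*Standardized mass* `m(x) = x (1 + q_j)` is the size of a fish at the
juvenile condition ceiling with no gonadic surplus; it drives the length
allometry `L = lambda1 * m^lambda2` (cm) and the intake allometry, so a
gravid female is neither longer nor hungrier than a spent one of the same
structure. Fulton's condition index `100 w / L^3` is also exposed, because
that is what field surveys report.

Each day, at the day-start temperature `T`:

* intake `I = d1 * m^d2 * r_a(w, T) * R_l` (g/day), where `R_l` in [0, 1]
  is the constant feeding level (1 = enough food for maximum growth,
  0 = starvation);
* assimilation `E_a = k_e * I`;
* maintenance `E_m = rho1 * w^rho2 * r_m(w, T)`, paid on total mass,
  gonads included;
* net energy `E_g = E_a - E_m`.

A surplus (`E_g > 0`) is split by the condition-dependent allocation rule:
a fraction `f = (y/x)^2 / ((1+q) q^2)` goes to structure while condition
is below the ceiling `q` (`q_j` for juveniles, `q_a` for adults), and
`f = 1/(1+q)` at the ceiling, which holds condition exactly there. Both
branches agree at the switch point, and as `y -> 0` the quadratic sends
essentially everything to reserves: recovering condition takes priority
over skeletal growth. A deficit (`E_g < 0`) is drawn entirely from
reserves; structure is untouched.

Maturity flips permanently when `L >= L_m` (the equality is assigned to
the adult side; the rule is evaluated once per step, after the update).
On the first day of every model year from the second onward, a mature
fish with `y > q_j x` converts its whole gonadic surplus into eggs,
`floor(k_r (y - q_j x) / w_b)`, and drops back to condition `q_j`. The
conversion efficiency `k_r` discounts the egg count, not the mass
removed. An event at the start of model year `n + 1` is labelled year
`n` — the fish's age in completed years.

## Size-dependent thermal performance

Both intake and maintenance carry a thermal performance factor

$$ r(w, T) = V^X e^{X (1 - V)}, \qquad
   V = \frac{T_{max}(w) - T}{T_{max}(w) - T_{opt}(w)}, $$

with \(X\) assembled from \(W = (T_{max}-T_{opt})\ln Q\),
\(Y = (T_{max}-T_{opt}+2)\ln Q\) and
\(X = W^2\,[1 + \sqrt{1 + 40/Y}]^2/400\). The three thermal sizes are
power laws of body mass: `T_opt = gamma_opt * w^v_opt`,
`T_max = gamma_max * w^v_max`, `Q = theta_coef * w^theta_exp`. All
shipped exponents are negative, so the window both narrows and shifts
colder as the fish grows — a 1 g herring performs best near 17 °C, a
150 g herring near 14.5 °C with a lethal ceiling near 18 °C. `r` equals 1
at the optimum and 0 at `T_max`; below the optimum it decays smoothly
(no lower clamp — the formula is used as-is), and for `T >= T_max` it is
defined as exactly 0, since `V^X` is undefined there for fractional `X`
and `T_max` carries lethal-limit semantics. Registry loading rejects any
parameter set for which `T_max <= T_opt` or `Q <= 1` anywhere in the
operating mass range (egg mass to 10 kg).

Two readings are possible for the mass at which the thermal sizes are
evaluated: total mass `x + y`, or standardized mass `m(x)`. The package
evaluates them at **total mass** by default and exposes
`thermal_mass_basis = "standardized"` as a scenario switch. For a
juvenile at its condition ceiling the two coincide; for adults carrying
gonads they differ by at most the factor `(1 + q_a)/(1 + q_j)`, and the
shipped outcomes are nearly indistinguishable between the two readings.

## Mortality

Three causes of death are implemented:

1. **Starvation** — an integration step that would push `y` below zero is
   truncated at `y = 0` and the individual dies: reserves exhausted.
2. **Thermal mortality** — the individual dies when the ambient
   temperature reaches the size-specific lethal maximum of the
   acquisition process, `T >= T_max_a(w)`. This is the package's reading
   of `T_max` as a *tolerance* (lethal) limit rather than merely the zero
   of the performance curve. The distinction matters: without it, a fish
   pushed past `T_max` simply stops feeding *and* — because the
   maintenance curve collapses at nearly the same temperature — stops
   paying for itself, idling through the summer peak in suspended
   animation and surviving conditions that are, by the parameters' own
   meaning, lethal. With the rule enabled (the default), fast-growing
   boreal fish under the warm regime "grow to death": rapid early growth
   shrinks the thermal window until the summer peak crosses it. The
   switch `thermal_mortality = FALSE` restores the pure
   reserve-exhaustion model.
3. **Lifespan** — the run ends after the species' maximum lifespan
   (`max_lifespan_years` 250-day years).

## Seasonal environment

Temperature follows
`T(t) = T_mean + a * sin(2 * pi * (t + omega) / GS)` over a growing
season of `GS = 250` days; the remaining 115 winter days do not exist on
the model clock (no feeding, no maintenance, no aging beyond the year
count). With `omega = 187` the season opens at the annual minimum, peaks
at day 125.5 and closes at the minimum again. The shipped regimes are
`"1980s"` (mean 12.85 °C, amplitude 5.3) and `"2010s"` (14.3 °C, 5.25):
the warm curve dominates the cool one on every day of the season. Age is
`age_days / 250` exactly.

`regime_summary()` counts integer days at or below a threshold. At 11 °C
it gives 96 days (1980s) and 70 days (2010s) — a 26-day loss of cool
conditions. These counts are properties of the fitted sinusoids; summaries
of the underlying monthly field temperatures can differ by a few days, so
the function is a diagnostic, not a reproduction of any observational
figure.

## Simulation conventions

* **Integrator**: explicit Euler with `dt = 1` day is the reference;
  `dt` is configurable for convergence checks. Across all 30 shipped
  scenarios, daily stepping and `dt = 0.1` agree on maximum length to
  within 0.3%, so the daily reference is effectively converged. The whole
  5 species × 2 regimes × 3 feeding levels grid runs in a few seconds.
* **Start**: each life begins at the species' egg mass `w_b`, split so
  condition sits exactly at the juvenile ceiling
  (`x = w_b/(1+q_j)`, `y = q_j x`) — the standard newborn convention in
  physiologically structured consumer-resource models. Other splits are a
  config option away (construct the state by hand and use `step_day()`).
* **Pre-feeding phase**: the egg period `E_d` and age at first feeding
  `A_f` appear in no rate equation, so before age `A_f` days the
  individual is treated as energetically inert at mass `w_b` (default).
  The alternative `prefeeding_mode = "maintenance_only"` charges
  maintenance from day 0; for some parameterizations the yolk budget
  cannot cover it and the egg starves before first feeding, which is why
  inert is the default.
* **Ordering within a day**: spawning (year start only) happens before
  the feeding step; maturity is re-evaluated after the state update.
* **Lifespans** are not part of the physiological tables; the shipped
  values (cod 25, herring 12, rockling 4, sprat 6, mullet 25 model
  years) are documented approximations of reported longevities and are
  configurable per scenario (`max_years`).

## What the tests show — and what they do not

The unit and property suite checks the arithmetic of every rate against
independently coded brute-force oracles, the continuity and conservation
properties of the allocation rule, determinism, step-size robustness, and
the qualitative study patterns: cod never matures in any scenario;
rockling hits a mid-season energy deficit with autumn recovery; more food
never produces shorter fish at ages where runs are comparable; warm-regime
boreal fish die young.

Because early mortality truncates lives, "maximum length over the whole
life" is *not* monotone in feeding level — a fully fed herring under the
warm regime dies in its first summer at ~19 cm while its half-fed
counterpart survives for years and eventually overtakes it. The
monotonicity property is therefore asserted on length-at-age at common
ages while all runs are alive, which is the pattern the growth curves
actually exhibit.

Several headline outcomes of the shipped parameterization are only
qualitatively, not numerically, aligned with the magnitudes one might
expect for these species. In particular, the late-life energy balance is
slightly more favourable than the growth histories of the real
populations suggest: reproductive windows extend roughly two year-classes
longer than reported longevity-fecundity patterns (e.g. sprat still spawns
in year 5 under the warm regime; rockling survives to its lifespan cap
under the warm regime rather than starving before age 3), and the
warm-versus-cool contrast in early mullet fecundity is muted because the
cool-regime mullet matures just before, rather than just after, a year
boundary. These gaps trace to the published parameter tables themselves —
no amount of integration accuracy changes them (daily vs 10× finer
stepping agree to <0.3%) — and are reported as-is by the acceptance
script rather than patched. The corresponding checks in the acceptance
test file are expected to stay red until the parameterization itself is
revised.

The synthetic observation generator (`make_fake_observations()`) draws
lengths around a simulated length-at-age curve with a fixed coefficient
of variation. It emulates the *shape* of survey length-at-age tables
(one row per fish, ages, lengths, period and source labels) — not their
sampling design, gear selectivity, measurement error structure or
cohort mixture. Passing overlay tests therefore demonstrates plumbing
correctness, not agreement with any real survey.

## A worked example

```{r example, eval = FALSE}
library(thermofish)

run <- run_individual(scenario("herring", "1980s", 1.0))
glance(run)
#   died of thermal at 1.48 model years; max length 27.2 cm,
#   1 spawning event, 19 652 eggs

run_grid(species = "rockling") |> dplyr::select(-run)
# six rockling scenarios: lifespan deaths at 4 years, max lengths
# 17.7-24.0 cm, a single spawning year

autoplot(run)                      # length-at-age
autoplot(run, "net_energy")        # seasonal energy balance
plot_thermal_response("herring")   # shrinking thermal windows
```
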