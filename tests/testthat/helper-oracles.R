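# Independent straight-line oracles. These deliberately share no code with
# the package: every sub-formula is written out step by step so the tests
# cross-check two separate derivations of the same arithmetic.

# Thermal performance factor, brute force
brute_force_thermal <- function(gamma_opt, v_opt, gamma_max, v_max,
                                theta_coef, theta_exp, w, temp) {
  t_opt <- gamma_opt * exp(v_opt * log(w))
  t_max <- gamma_max * exp(v_max * log(w))
  q <- theta_coef * exp(theta_exp * log(w))
  if (temp >= t_max) return(0)
  big_w <- (t_max - t_opt) * log(q)
  big_y <- (t_max - t_opt + 2) * log(q)
  big_x <- (big_w * big_w) * (1 + (1 + 40 / big_y)^0.5)^2 / 400
  v <- (t_max - temp) / (t_max - t_opt)
  r <- exp(big_x * log(v)) * exp(big_x * (1 - v))
  min(r, 1)
}

brute_force_thermal_scaling <- function(s, w, temp) {
  brute_force_thermal(s$gamma_opt, s$v_opt, s$gamma_max, s$v_max,
                      s$theta_coef, s$theta_exp, w, temp)
}

# Continuous arc length (in days) of one sinusoid period spent at or below
# a threshold, by dense numerical sampling (independent of the package's
# integer-day count).
arc_days_below <- function(T_mean, amplitude, omega, GS, threshold,
                           n = 2e6) {
  t <- seq(0, GS, length.out = n)
  temp <- T_mean + amplitude * sin(2 * pi * (t + omega) / GS)
  GS * mean(temp <= threshold)
}

shipped_species <- function() lapply(species_names(), load_species)
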