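#' Thermal scaling coefficients for one physiological process
#'
#' Bundles the six coefficients that make a thermal performance curve
#' size-dependent: the optimum temperature \eqn{T_{opt}(w) = \gamma_{opt}
#' w^{v_{opt}}}, the lethal maximum \eqn{T_{max}(w) = \gamma_{max}
#' w^{v_{max}}} and the steepness parameter \eqn{Q(w) = \vartheta w^\theta}
#' (a Q10-like quantity controlling how sharply performance rises with
#' temperature). One such record exists per process: food intake
#' (acquisition) and maintenance metabolism.
#'
#' @param gamma_opt Scalar of the optimum-temperature power law
#'   (degC g^-v_opt).
#' @param v_opt Dimensionless exponent of the optimum-temperature power law
#'   (negative for all shipped species: bigger fish prefer colder water).
#' @param gamma_max Scalar of the lethal-maximum power law (degC g^-v_max).
#' @param v_max Dimensionless exponent of the lethal-maximum power law.
#' @param theta_coef Scalar \eqn{\vartheta} of the steepness power law
#'   (dimensionless, > 0).
#' @param theta_exp Exponent \eqn{\theta} of the steepness power law.
#'
#' @return An object of class `thermal_scaling`.
#' @seealso [temperature_factor()], [species_params()]
#' @export
#' @examples
#' ts <- thermal_scaling(16.78, -0.078, 22, -0.0435, 2.2, 0.075)
#' thermal_optimum(ts, 10)
thermal_scaling <- function(gamma_opt, v_opt, gamma_max, v_max,
                            theta_coef, theta_exp) {
  s <- list(
    gamma_opt = as.numeric(gamma_opt), v_opt = as.numeric(v_opt),
    gamma_max = as.numeric(gamma_max), v_max = as.numeric(v_max),
    theta_coef = as.numeric(theta_coef), theta_exp = as.numeric(theta_exp)
  )
  class(s) <- "thermal_scaling"
  validate_thermal_scaling(s)
  s
}

validate_thermal_scaling <- function(s) {
  for (f in c("gamma_opt", "v_opt", "gamma_max", "v_max",
              "theta_coef", "theta_exp")) {
    v <- s[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(paste0("thermal_scaling field '", f,
                   "' must be a single finite number"),
            class = "thermofish_validation_error")
    }
  }
  if (s$gamma_opt <= 0) {
    abort("thermal_scaling invariant violated: gamma_opt > 0",
          class = "thermofish_validation_error")
  }
  if (s$gamma_max <= 0) {
    abort("thermal_scaling invariant violated: gamma_max > 0",
          class = "thermofish_validation_error")
  }
  if (s$theta_coef <= 0) {
    abort("thermal_scaling invariant violated: theta_coef > 0",
          class = "thermofish_validation_error")
  }
  invisible(s)
}

# fields of a species record, in canonical order
.species_scalar_fields <- c(
  "w_b", "q_j", "q_a", "q_r", "k_r", "E_d", "A_f", "L_m",
  "lambda1", "lambda2", "d1", "d2", "rho1", "rho2", "k_e",
  "max_lifespan_years"
)
.species_fields <- c("name", .species_scalar_fields,
                     "intake_thermal", "maintenance_thermal")

#' Construct a validated species parameter set
#'
#' A species record holds the full life-history and physiological
#' parameterization of one species: egg mass `w_b` (g), juvenile and adult
#' maximum condition ratios `q_j`, `q_a` (reserve:structure), spawning
#' threshold condition `q_r`, gonad-to-offspring conversion efficiency
#' `k_r`, egg period `E_d` and age at first feeding `A_f` (days),
#' maturation length `L_m` (cm), the length-mass allometry `L = lambda1 *
#' m^lambda2` (cm from g), the intake allometry scalar/exponent `d1`, `d2`,
#' the maintenance allometry `rho1`, `rho2`, the resource conversion
#' efficiency `k_e`, the maximum lifespan in 250-day model years, and one
#' [thermal_scaling()] per physiological process.
#'
#' @param name Species identifier.
#' @param ... Named scalar fields (see Details) plus `intake_thermal` and
#'   `maintenance_thermal`, each a [thermal_scaling()] or a named list of
#'   its six coefficients.
#'
#' @details Validation enforces `0 < q_j <= q_a`, positive masses, lengths
#' and allometric scalars, efficiencies in (0, 1], and — for each thermal
#' scaling — that the lethal maximum exceeds the optimum and the steepness
#' `Q` exceeds 1 over the species' whole operating mass range (egg mass up
#' to 10 kg). `q_r != q_j` is permitted but warned about, since the
#' fecundity rule uses `q_j` as the gonad baseline.
#'
#' @return An object of class `species_params`.
#' @seealso [load_species()], [save_species()], [species_names()]
#' @export
species_params <- function(name, ...) {
  fields <- list(...)
  for (th in c("intake_thermal", "maintenance_thermal")) {
    if (is.list(fields[[th]]) && !inherits(fields[[th]], "thermal_scaling")) {
      fields[[th]] <- do.call(thermal_scaling, fields[[th]])
    }
  }
  p <- c(list(name = as.character(name)), fields)
  missing <- setdiff(.species_fields, names(p))
  if (length(missing)) {
    abort(paste0("species_params is missing field(s): ",
                 paste(missing, collapse = ", ")),
          class = "thermofish_schema_error")
  }
  extra <- setdiff(names(p), .species_fields)
  if (length(extra)) {
    abort(paste0("species_params has unknown field(s): ",
                 paste(extra, collapse = ", ")),
          class = "thermofish_schema_error")
  }
  p <- p[.species_fields]
  p[.species_scalar_fields] <- lapply(p[.species_scalar_fields], as.numeric)
  class(p) <- "species_params"
  validate_species_params(p)
}

#' @rdname species_params
#' @param p A `species_params` object.
#' @export
validate_species_params <- function(p) {
  stopifnot(inherits(p, "species_params"))
  for (f in .species_scalar_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(paste0("species field '", f, "' must be a single finite number"),
            class = "thermofish_validation_error")
    }
  }
  rules <- list(
    "w_b > 0"          = p$w_b > 0,
    "0 < q_j <= q_a"   = p$q_j > 0 && p$q_j <= p$q_a,
    "0 < k_e <= 1"     = p$k_e > 0 && p$k_e <= 1,
    "0 < k_r <= 1"     = p$k_r > 0 && p$k_r <= 1,
    "L_m > 0"          = p$L_m > 0,
    "lambda1 > 0"      = p$lambda1 > 0,
    "lambda2 > 0"      = p$lambda2 > 0,
    "d1 > 0"           = p$d1 > 0,
    "rho1 > 0"         = p$rho1 > 0,
    "E_d >= 0"         = p$E_d >= 0,
    "A_f >= E_d"       = p$A_f >= p$E_d,
    "max_lifespan_years >= 1" = p$max_lifespan_years >= 1
  )
  bad <- names(rules)[!vapply(rules, isTRUE, logical(1))]
  if (length(bad)) {
    abort(paste0("species '", p$name, "' violates invariant(s): ",
                 paste(bad, collapse = "; ")),
          class = "thermofish_validation_error")
  }
  if (p$q_r != p$q_j) {
    warn(paste0("species '", p$name, "': q_r (", p$q_r,
                ") differs from q_j (", p$q_j,
                "); the fecundity rule uses q_j as the gonad baseline"))
  }
  for (th in c("intake_thermal", "maintenance_thermal")) {
    validate_thermal_scaling(p[[th]])
    check_thermal_range(p[[th]], p$w_b, process = th, species = p$name)
  }
  p
}

# T_max > T_opt and Q > 1 must hold over the whole operating mass range,
# otherwise the performance curve is degenerate (checked at registry load).
check_thermal_range <- function(s, w_b, w_cap = 1e4,
                                process = "thermal", species = "?") {
  grid <- unique(c(w_b, 1, 100, w_cap))
  t_opt <- s$gamma_opt * grid^s$v_opt
  t_max <- s$gamma_max * grid^s$v_max
  q <- s$theta_coef * grid^s$theta_exp
  if (any(t_max <= t_opt)) {
    abort(paste0("species '", species, "', ", process,
                 ": T_max(w) <= T_opt(w) within the operating mass range"),
          class = "thermofish_validation_error")
  }
  if (any(q <= 1)) {
    abort(paste0("species '", species, "', ", process,
                 ": Q(w) <= 1 within the operating mass range"),
          class = "thermofish_validation_error")
  }
  invisible(TRUE)
}

#' Names of the shipped species parameterizations
#'
#' @return Character vector of config names accepted by [load_species()].
#' @export
species_names <- function() {
  sort(sub("\\.yaml$", "",
           dir(system.file("extdata", "species", package = "thermofish"),
               pattern = "\\.yaml$")))
}

#' Load a species parameter set
#'
#' Reads a species config file (YAML) and returns a validated
#' [species_params()]. `path_or_name` may be one of the shipped names (see
#' [species_names()]) or a path to a user-written file with the same
#' schema. Unknown keys are rejected and every invariant is re-checked on
#' load, so a hand-edited file cannot silently produce a degenerate
#' parameterization.
#'
#' @param path_or_name Shipped species name (e.g. `"cod"`) or file path.
#' @return A `species_params` object.
#' @export
#' @examples
#' cod <- load_species("cod")
#' cod$w_b   # egg mass, g
load_species <- function(path_or_name) {
  if (inherits(path_or_name, "species_params")) {
    return(validate_species_params(path_or_name))
  }
  path <- path_or_name
  if (!file.exists(path)) {
    shipped <- system.file("extdata", "species",
                           paste0(path_or_name, ".yaml"),
                           package = "thermofish")
    if (!nzchar(shipped)) {
      abort(paste0("unknown species '", path_or_name,
                   "': not a file and not one of {",
                   paste(species_names(), collapse = ", "), "}"),
            class = "thermofish_schema_error")
    }
    path <- shipped
  }
  raw <- yaml::yaml.load_file(path)
  if (!is.list(raw) || is.null(raw$name)) {
    abort(paste0("species config '", path, "' is missing field: name"),
          class = "thermofish_schema_error")
  }
  for (th in c("intake_thermal", "maintenance_thermal")) {
    if (!is.null(raw[[th]])) {
      extra <- setdiff(names(raw[[th]]),
                       c("gamma_opt", "v_opt", "gamma_max", "v_max",
                         "theta_coef", "theta_exp"))
      if (length(extra)) {
        abort(paste0("species config '", path, "', ", th,
                     ": unknown field(s): ", paste(extra, collapse = ", ")),
              class = "thermofish_schema_error")
      }
    }
  }
  do.call(species_params, c(list(name = raw$name),
                            raw[setdiff(names(raw), "name")]))
}

#' Save a species parameter set to a config file
#'
#' Writes YAML with enough significant digits that
#' `load_species(save_species(p, f))` reproduces `p` exactly (bit-level
#' round trip of every numeric field).
#'
#' @param p A `species_params` object.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
save_species <- function(p, path) {
  p <- validate_species_params(p)
  out <- unclass(p)
  out$intake_thermal <- unclass(out$intake_thermal)
  out$maintenance_thermal <- unclass(out$maintenance_thermal)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' All shipped species as one tidy table
#'
#' @return A tibble with one row per shipped species and one column per
#'   scalar parameter; thermal coefficients are prefixed `a_` (intake) and
#'   `m_` (maintenance).
#' @export
species_table <- function() {
  purrr::map_dfr(species_names(), function(nm) {
    p <- load_species(nm)
    tibble::as_tibble(c(
      list(name = p$name),
      p[.species_scalar_fields],
      stats::setNames(unclass(p$intake_thermal),
                      paste0("a_", names(unclass(p$intake_thermal)))),
      stats::setNames(unclass(p$maintenance_thermal),
                      paste0("m_", names(unclass(p$maintenance_thermal))))
    ))
  })
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params> ", x$name, "\n", sep = "")
  cat(sprintf("  egg mass w_b = %g g, maturation length L_m = %g cm\n",
              x$w_b, x$L_m))
  cat(sprintf("  condition ceilings q_j = %g (juvenile), q_a = %g (adult)\n",
              x$q_j, x$q_a))
  cat(sprintf("  intake d1 = %g, d2 = %g; maintenance rho1 = %g, rho2 = %g\n",
              x$d1, x$d2, x$rho1, x$rho2))
  cat(sprintf("  max lifespan %d model years\n",
              as.integer(x$max_lifespan_years)))
  invisible(x)
}
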