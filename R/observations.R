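#' Generate a synthetic survey-style observation table
#'
#' Produces fake length-at-age observations shaped like survey or
#' monitoring data (one row per measured fish), for exercising readers and
#' overlay reports without any real data. Lengths are drawn around the
#' simulated length-at-age curve of the species (1980s regime, feeding
#' level 0.7) with a fixed coefficient of variation. Deterministic per
#' seed; the caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param species Shipped species name or `species_params`.
#' @param n_per_age Observations per age class.
#' @param cv Coefficient of variation of lengths around the curve.
#' @return A tibble with columns `species`, `age_years`, `length_cm`,
#'   `period`, `source` (all lengths > 0, ages within the lifespan).
#' @export
make_fake_observations <- function(seed, species, n_per_age = 25,
                                   cv = 0.08) {
  p <- load_species(species)
  run <- run_individual(scenario(p, "1980s", 0.7))
  laa <- length_at_age(run)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  laa |>
    dplyr::rowwise() |>
    dplyr::reframe(
      age_years = .data$age_years,
      length_cm = pmax(stats::rnorm(n_per_age, .data$length_cm,
                                    cv * .data$length_cm),
                       0.1 * .data$length_cm)
    ) |>
    dplyr::mutate(species = p$name, period = "synthetic",
                  source = "thermofish::make_fake_observations",
                  .before = 1)
}

#' Compare simulated length envelopes with observations
#'
#' For each age class, the feeding-level envelope is the interval between
#' the length at the lowest and highest feeding level; the report gives
#' the fraction of observations falling inside it. This mirrors the
#' qualitative model-versus-survey comparison logic (food availability in
#' the field is unknown, so the feeding-level band is the model's
#' prediction interval); no test statistic is attached.
#'
#' @param runs A list of `fish_run` objects for one species (typically at
#'   feeding levels 0.5 and 1.0 under one regime).
#' @param obs An observation tibble as from [make_fake_observations()] (or
#'   read from CSV with the same columns).
#' @return A tibble per age: `age_years`, `sim_min`, `sim_max`, `n_obs`,
#'   `frac_inside`. Zero-row `obs` gives a zero-row report.
#' @export
overlay_report <- function(runs, obs) {
  if (inherits(runs, "fish_run")) runs <- list(runs)
  sp <- unique(vapply(runs, function(r) r$scenario$species$name, ""))
  if (length(sp) != 1L || (nrow(obs) && !all(obs$species == sp))) {
    abort("overlay_report: observation species do not match the runs",
          class = "thermofish_validation_error")
  }
  env <- purrr::map_dfr(runs, length_at_age) |>
    dplyr::group_by(.data$age_years) |>
    dplyr::summarise(sim_min = min(.data$length_cm),
                     sim_max = max(.data$length_cm), .groups = "drop")
  if (!nrow(obs)) {
    return(tibble::tibble(age_years = numeric(), sim_min = numeric(),
                          sim_max = numeric(), n_obs = integer(),
                          frac_inside = numeric()))
  }
  obs |>
    dplyr::inner_join(env, by = "age_years") |>
    dplyr::group_by(.data$age_years, .data$sim_min, .data$sim_max) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      frac_inside = mean(.data$length_cm >= .data$sim_min &
                           .data$length_cm <= .data$sim_max),
      .groups = "drop")
}

#' Read / write observation tables as CSV
#'
#' Plain-CSV persistence for survey-style length-at-age tables with the
#' documented header (`species`, `age_years`, `length_cm`, `period`,
#' `source`). The reader validates the schema and the basic range
#' invariants (lengths positive, ages non-negative).
#'
#' @param path CSV file path.
#' @return `read_observations()` returns a tibble; `write_observations()`
#'   returns `path` invisibly.
#' @export
read_observations <- function(path) {
  obs <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  needed <- c("species", "age_years", "length_cm", "period", "source")
  missing <- setdiff(needed, names(obs))
  if (length(missing)) {
    abort(paste0("observation table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "thermofish_schema_error")
  }
  if (any(obs$length_cm <= 0) || any(obs$age_years < 0)) {
    abort("observation table violates invariants: lengths > 0, ages >= 0",
          class = "thermofish_validation_error")
  }
  obs[needed]
}

#' @rdname read_observations
#' @param obs An observation tibble (as from [make_fake_observations()]).
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}
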