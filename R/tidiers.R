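#' Tidy the trajectory of a simulated life
#'
#' Returns the per-step trajectory as a tibble, prefixed with the scenario
#' identifiers so outputs from several runs can be row-bound directly.
#'
#' @param x A `fish_run`.
#' @param ... Unused.
#' @return A tibble with scenario columns (`species`, `regime`,
#'   `feeding_level`) followed by the trajectory columns.
#' @exportS3Method generics::tidy
tidy.fish_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(species = x$scenario$species$name,
                   regime = x$scenario$regime$name,
                   feeding_level = x$scenario$feeding_level)[
                     rep(1, nrow(x$trajectory)), ],
    x$trajectory
  )
}

#' One-row summary of a simulated life
#'
#' @param x A `fish_run`.
#' @param ... Unused.
#' @return A one-row tibble: scenario identifiers, `max_length_cm`,
#'   `final_mass_g`, `death_cause`, `death_age_years`,
#'   `n_spawning_events`, `last_spawning_year`, `lifetime_eggs`.
#' @exportS3Method generics::glance
glance.fish_run <- function(x, ...) {
  traj <- x$trajectory
  sp <- x$spawning
  tibble::tibble(
    species = x$scenario$species$name,
    regime = x$scenario$regime$name,
    feeding_level = x$scenario$feeding_level,
    max_length_cm = max(traj$length_cm),
    final_mass_g = traj$total_mass[nrow(traj)],
    death_cause = x$death$cause,
    death_age_years = x$death$age_years,
    n_spawning_events = nrow(sp),
    last_spawning_year = if (nrow(sp)) max(sp$event_year_label) else NA_real_,
    lifetime_eggs = sum(sp$eggs)
  )
}

#' Annual length-at-age from a run
#'
#' Length at the end of each completed model year — the quantity usually
#' compared with survey length-at-age data.
#'
#' @param x A `fish_run`.
#' @return A tibble with `age_years` (integer ages) and `length_cm`.
#' @export
length_at_age <- function(x) {
  stopifnot(inherits(x, "fish_run"))
  x$trajectory |>
    dplyr::group_by(.data$model_year) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::transmute(age_years = .data$model_year,
                     length_cm = .data$length_cm)
}
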