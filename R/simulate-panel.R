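#' Simulate a unit table and annual loss panel
#'
#' Draws the synthetic study described by a [sim_scenario()]: a set of
#' treated areas assigned to titling cohorts plus a pool of candidate
#' (never-titled) control areas, and for each unit-year a deforested-hectare
#' draw from the Poisson log-link model with unit effects, year effects, a
#' standardized-precipitation covariate and the planted treatment effect.
#' All draws come from a single generator stream seeded by `scenario$seed`,
#' so the output is byte-identical across calls.
#'
#' @param scenario A [sim_scenario()].
#' @return A list with two tibbles:
#' \describe{
#'   \item{units}{one row per area: `area_id`, `title_type` (`"candidate"`
#'     for controls), `title_year` (`NA` for candidates), `total_area_ha`.}
#'   \item{panel}{one row per area-year: `area_id`, `year`, `forest_class`,
#'     `loss_ha`, `rate` (= `loss_ha / total_area_ha`, clipped at 1),
#'     `precip_std`, `total_area_ha`.}
#' }
#' @export
simulate_panel <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  withr::with_seed(scenario$seed, {
    units <- .draw_units(scenario)
    panel <- .draw_panel(scenario, units)
  })
  list(units = units$public, panel = panel)
}

# Unit table plus the latent unit effects (kept internal to the generator).
.draw_units <- function(scenario) {
  n_treat <- sum(scenario$n_treated_per_cohort)
  n <- n_treat + scenario$n_controls
  area_ha <- .draw_areas(scenario$area_ha_distribution, n)
  title_year <- c(rep(scenario$cohort_years, scenario$n_treated_per_cohort),
                  rep(NA_integer_, scenario$n_controls))
  unit_fe <- rnorm(n, 0, scenario$unit_fe_sd)
  public <- tibble(
    area_id = sprintf("A%04d", seq_len(n)),
    title_type = ifelse(is.na(title_year), "candidate", scenario$title_type),
    title_year = title_year,
    total_area_ha = area_ha
  )
  list(public = public, unit_fe = unit_fe)
}

.draw_areas <- function(dist, n) {
  switch(dist$dist,
    lognormal = rlnorm(n, meanlog = dist$meanlog, sdlog = dist$sdlog),
    fixed = rep(dist$value, n),
    abort(paste0("Unknown area distribution '", dist$dist, "'."))
  )
}

.tau_for_cohort <- function(scenario, cohort) {
  if (length(scenario$tau) == 1L) return(unname(scenario$tau))
  unname(scenario$tau[as.character(cohort)])
}

# Expected log rate for every unit-year; shared by the panel and landscape
# generators so that both draw from the same conditional-mean surface.
.log_rate_grid <- function(scenario, units, unit_fe, precip) {
  n <- nrow(units)
  yrs <- scenario$panel_years
  grid <- tidyr::expand_grid(idx = seq_len(n), year = yrs)
  grid$area_id <- units$area_id[grid$idx]
  grid$title_year <- units$title_year[grid$idx]
  grid$total_area_ha <- units$total_area_ha[grid$idx]
  grid$unit_fe <- unit_fe[grid$idx]
  grid$year_fe <- unname(scenario$year_fe[as.character(grid$year)])
  grid$precip_std <- precip
  treated <- !is.na(grid$title_year) & grid$year >= grid$title_year
  tau_vec <- if (length(scenario$tau) == 1L) {
    rep(unname(scenario$tau), nrow(grid))
  } else {
    ifelse(is.na(grid$title_year), 0,
           unname(scenario$tau[as.character(grid$title_year)]))
  }
  grid$did <- as.integer(treated)
  grid$log_rate <- scenario$baseline_log_rate + grid$unit_fe + grid$year_fe +
    scenario$beta_precip * grid$precip_std + tau_vec * grid$did
  grid
}

.draw_panel <- function(scenario, units) {
  n <- nrow(units$public)
  n_yr <- length(scenario$panel_years)
  precip <- rnorm(n * n_yr)
  grid <- .log_rate_grid(scenario, units$public, units$unit_fe, precip)
  loss <- rpois(nrow(grid), grid$total_area_ha * exp(grid$log_rate))
  rate <- pmin(loss / grid$total_area_ha, 1)
  tibble(
    area_id = grid$area_id,
    year = grid$year,
    forest_class = scenario$forest_class,
    loss_ha = pmin(loss, grid$total_area_ha),
    rate = rate,
    precip_std = grid$precip_std,
    total_area_ha = grid$total_area_ha
  )
}
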