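#' Define a synthetic study scenario
#'
#' A scenario fully parameterizes a synthetic landscape of titled (treated)
#' and candidate (control) areas observed as an annual panel. Deforested
#' hectares in area `i` and year `t` are drawn as
#' `Poisson(area_i * exp(b0 + a_i + g_t + beta_precip * precip_it + tau_g * D_it))`
#' where `b0` is `baseline_log_rate`, `a_i ~ N(0, unit_fe_sd^2)` are unit
#' effects, `g_t` are fixed year effects, `precip_it` is standardized annual
#' precipitation, and `D_it` switches on from the titling (cohort) year of a
#' treated unit. The outcome rate is deforested hectares divided by area.
#'
#' @param n_treated_per_cohort Number of treated areas titled in each cohort
#'   year. A single count (recycled) or one count per cohort year.
#' @param n_controls Number of candidate (never-titled) control areas.
#' @param cohort_years Calendar years in which titles are granted; must lie
#'   within `panel_years`.
#' @param panel_years Inclusive span of observed years (default 2001-2019,
#'   the span of the annual loss record).
#' @param baseline_log_rate Log of the expected annual deforestation rate in
#'   a typical untreated unit-year (default `log(0.01)`, i.e. 1% per year).
#' @param unit_fe_sd Standard deviation of the unit effects on the log scale.
#' @param year_fe Per-year shifts of the log rate: a numeric vector of
#'   length `length(panel_years)` (default a mild oscillation), or a single
#'   number recycled.
#' @param beta_precip Effect of standardized precipitation on the log rate
#'   (negative in wet years forests burn and clear less).
#' @param tau Treatment effect on the log deforestation rate: a scalar for
#'   homogeneous effects or a vector named by cohort year for heterogeneous
#'   staggered effects.
#' @param area_ha_distribution Polygon-size law: a list with `dist` one of
#'   `"lognormal"` (`meanlog`, `sdlog`) or `"fixed"` (`value`).
#' @param title_type Label attached to treated units, one of `"HD"`,
#'   `"HKm"`, `"HTR"`.
#' @param forest_class Label attached to the panel records, one of
#'   `"all"`, `"degraded"`, `"primary"`.
#' @param seed Integer seed; all draws come from one seeded generator stream
#'   so outputs are byte-identical across runs.
#'
#' @return An object of class `sim_scenario`.
#' @seealso [preset_scenario()] for Table-1-style planted-truth presets,
#'   [simulate_panel()], [simulate_landscape()].
#' @export
#' @examples
#' sc <- sim_scenario(n_treated_per_cohort = 5, n_controls = 20,
#'                    cohort_years = c(2010, 2015), tau = 0.5, seed = 1)
#' sim <- simulate_panel(sc)
#' head(sim$panel)
sim_scenario <- function(n_treated_per_cohort = 8,
                         n_controls = 60,
                         cohort_years = 2009:2019,
                         panel_years = 2001:2019,
                         baseline_log_rate = log(0.01),
                         unit_fe_sd = 0.5,
                         year_fe = NULL,
                         beta_precip = -0.15,
                         tau = 0,
                         area_ha_distribution = list(dist = "lognormal",
                                                     meanlog = log(70),
                                                     sdlog = 1),
                         title_type = "HD",
                         forest_class = "all",
                         seed = 1L) {
  panel_years <- sort(as.integer(panel_years))
  cohort_years <- sort(as.integer(cohort_years))
  if (!all(cohort_years %in% panel_years)) {
    abort("All `cohort_years` must lie within `panel_years`.")
  }
  n_treated_per_cohort <- as.integer(n_treated_per_cohort)
  if (length(n_treated_per_cohort) == 1L) {
    n_treated_per_cohort <- rep(n_treated_per_cohort, length(cohort_years))
  }
  if (length(n_treated_per_cohort) != length(cohort_years)) {
    abort("`n_treated_per_cohort` must have length 1 or length(cohort_years).")
  }
  if (any(n_treated_per_cohort < 1L) || n_controls < 1L) {
    abort("Unit counts must be positive: need >= 1 treated per cohort and >= 1 control.")
  }
  if (is.null(year_fe)) {
    year_fe <- 0.1 * sin(seq_along(panel_years) / 2)
  }
  if (length(year_fe) == 1L) year_fe <- rep(year_fe, length(panel_years))
  if (length(year_fe) != length(panel_years)) {
    abort("`year_fe` must have length 1 or length(panel_years).")
  }
  year_fe <- setNames(as.numeric(year_fe), panel_years)
  if (length(tau) > 1L) {
    if (is.null(names(tau)) || !all(names(tau) %in% as.character(cohort_years))) {
      abort("A vector `tau` must be named by cohort year.")
    }
    tau <- tau[as.character(cohort_years)]
    tau[is.na(tau)] <- 0
    names(tau) <- cohort_years
  }
  title_type <- match.arg(title_type, c("HD", "HKm", "HTR"))
  forest_class <- match.arg(forest_class, c("all", "degraded", "primary"))
  stopifnot(is.list(area_ha_distribution), !is.null(area_ha_distribution$dist))

  structure(
    list(
      n_treated_per_cohort = n_treated_per_cohort,
      n_controls = as.integer(n_controls),
      cohort_years = cohort_years,
      panel_years = panel_years,
      baseline_log_rate = baseline_log_rate,
      unit_fe_sd = unit_fe_sd,
      year_fe = year_fe,
      beta_precip = beta_precip,
      tau = tau,
      area_ha_distribution = area_ha_distribution,
      title_type = title_type,
      forest_class = forest_class,
      seed = as.integer(seed)
    ),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario>\n")
  cat("  cohorts:", paste(x$cohort_years, collapse = ", "), "\n")
  cat("  treated/cohort:", paste(x$n_treated_per_cohort, collapse = ", "),
      " controls:", x$n_controls, "\n")
  cat("  panel:", min(x$panel_years), "-", max(x$panel_years), "\n")
  cat("  baseline rate:", signif(exp(x$baseline_log_rate), 3),
      " unit FE sd:", x$unit_fe_sd, "\n")
  cat("  tau:", paste(signif(x$tau, 3), collapse = ", "),
      " beta_precip:", x$beta_precip, "\n")
  cat("  title type:", x$title_type, " forest class:", x$forest_class,
      " seed:", x$seed, "\n")
  invisible(x)
}

# Planted-truth grid for the replication presets: effect of a title on the
# log deforestation rate, by title type and forest class, with class-specific
# precipitation effects and title-type baseline rates (HTR areas start from
# roughly double the forest-loss rate of HD/HKm areas).
.preset_grid <- function() {
  tibble::tribble(
    ~title_type, ~forest_class, ~tau, ~beta_precip, ~baseline_rate,
    "HD",  "all",      0.14, -0.15, 0.010,
    "HD",  "degraded", 0.27, -0.16, 0.012,
    "HD",  "primary",  0.35, -0.32, 0.004,
    "HKm", "all",      0.08, -0.15, 0.010,
    "HKm", "degraded", 0.00, -0.16, 0.012,
    "HKm", "primary",  0.75, -0.31, 0.004,
    "HTR", "all",     -0.10, -0.15, 0.020,
    "HTR", "degraded",-0.83, -0.16, 0.018
  )
}

#' Preset scenarios with planted treatment effects
#'
#' Returns a [sim_scenario()] whose true treatment effect, precipitation
#' effect and baseline rate are taken from a fixed grid of title-type by
#' forest-class cells (e.g. the HTR/degraded cell plants `tau = -0.83`).
#' Presets can be addressed either by `(title_type, forest_class)` or by a
#' single name such as `"htr_degraded"`.
#'
#' @param title_type `"HD"`, `"HKm"` or `"HTR"`, or a combined name like
#'   `"htr_degraded"`.
#' @param forest_class `"all"`, `"degraded"` or `"primary"` (ignored when a
#'   combined name is given).
#' @param ... Overrides passed on to [sim_scenario()] (e.g. `seed`,
#'   `n_controls`).
#' @return A `sim_scenario`.
#' @export
#' @examples
#' preset_scenario("htr_degraded", seed = 7)
preset_scenario <- function(title_type, forest_class = NULL, ...) {
  grid <- .preset_grid()
  if (is.null(forest_class) && grepl("_", title_type)) {
    parts <- strsplit(title_type, "_", fixed = TRUE)[[1]]
    title_type <- parts[1]
    forest_class <- parts[2]
  }
  tt <- grid$title_type[match(tolower(title_type), tolower(grid$title_type))]
  if (is.na(tt)) abort(paste0("Unknown title type '", title_type, "'."))
  row <- grid[tolower(grid$title_type) == tolower(title_type) &
                grid$forest_class == forest_class, ]
  if (nrow(row) != 1L) {
    abort(paste0("No preset cell for (", title_type, ", ", forest_class, ")."))
  }
  args <- list(
    tau = row$tau,
    beta_precip = row$beta_precip,
    baseline_log_rate = log(row$baseline_rate),
    title_type = row$title_type,
    forest_class = row$forest_class
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_scenario, args)
}

#' The standard Monte-Carlo laboratory scenario
#'
#' The fixed study conditions used by the package's validation experiments:
#' three titling cohorts (2010, 2013, 2016), 15 treated areas per cohort and
#' 105 candidate controls (150 areas in all), the full 2001-2019 panel, a 1%
#' baseline annual deforestation rate, moderate unit heterogeneity and the
#' default negative precipitation effect. Only the planted effect and the
#' seed vary between experiments.
#'
#' @param tau Planted treatment effect on the log rate.
#' @param ... Further overrides passed to [sim_scenario()].
#' @return A `sim_scenario`.
#' @export
lab_scenario <- function(tau = 0, ...) {
  args <- list(
    n_treated_per_cohort = 15,
    n_controls = 105,
    cohort_years = c(2010, 2013, 2016),
    tau = tau
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_scenario, args)
}
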