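#' Titling cohorts present in a unit table
#'
#' A cohort is the set of areas receiving their title in the same calendar
#' year; each cohort defines one sub-experiment of the stacked design.
#'
#' @param units Unit tibble with columns `area_id`, `title_type`,
#'   `title_year` (`NA` for candidates).
#' @param title_type_filter Optional title type (`"HD"`, `"HKm"`, `"HTR"`);
#'   when given, only units of that type define cohorts.
#' @return Sorted integer vector of distinct titling years with at least one
#'   treated unit.
#' @export
#' @examples
#' units <- tibble::tibble(area_id = c("a", "b", "c"),
#'                         title_type = c("HD", "HD", "HD"),
#'                         title_year = c(2016L, 2016L, 2018L))
#' build_cohorts(units) # 2016 2018
build_cohorts <- function(units, title_type_filter = NULL) {
  u <- units
  if (!is.null(title_type_filter)) {
    u <- dplyr::filter(u, .data$title_type == title_type_filter)
  }
  yrs <- sort(unique(u$title_year[!is.na(u$title_year)]))
  if (length(yrs) == 0) {
    abort("No titled units found; cannot build cohorts.")
  }
  as.integer(yrs)
}

#' Build the stacked difference-in-differences panel
#'
#' For each titling cohort `g`, forms one sub-experiment: units titled in
#' `g` (treated) plus control areas chosen by `control_rule`, each
#' contributing every panel year. Sub-experiments are concatenated with a
#' `cohort_id` label. Within each sub-experiment, `treat` marks treated
#' units, `post` marks years at or after the cohort year (a title can bind
#' within its calendar year), and `did = treat * post` is the
#' difference-in-differences interaction whose coefficient is the effect of
#' the title on the log deforestation rate.
#'
#' Candidate controls appear in every cohort's sub-experiment but count once
#' in `n_clusters`, since standard errors are clustered on `area_id` across
#' the whole stack.
#'
#' @param units Unit tibble (`area_id`, `title_type`, `title_year`,
#'   `total_area_ha`).
#' @param panel Annual loss records (`area_id`, `year`, `forest_class`,
#'   `loss_ha`, `rate`, `precip_std`, ...) as from [simulate_panel()] or
#'   [zonal_annual_loss()].
#' @param cohorts Cohort years (default [build_cohorts()] on `units`).
#' @param control_rule `"candidates"` (default): controls are areas never
#'   titled in the data — the designated-but-untitled candidate pool.
#'   `"not_yet_treated"`: additionally admits units titled after the last
#'   year under study.
#' @param years Panel years each selected unit contributes (default the
#'   years present in `panel`).
#' @return A list with `stack` (tibble of stacked observations, including
#'   the fixed-effect keys `cohort_area`, `cohort_year`, `cohort_post`,
#'   `cohort_treat`) and `summary` (a `stack_summary`: `n_cohorts`,
#'   `n_rows`, `n_clusters`, per-cohort unit counts).
#' @export
build_stack <- function(units, panel, cohorts = NULL,
                        control_rule = c("candidates", "not_yet_treated"),
                        years = NULL) {
  control_rule <- match.arg(control_rule)
  if (is.null(cohorts)) cohorts <- build_cohorts(units)
  if (is.null(years)) years <- sort(unique(panel$year))
  if (length(years) == 0) abort("`years` must be nonempty.")
  missing_units <- setdiff(unique(panel$area_id), units$area_id)
  if (length(missing_units) > 0) {
    abort(paste0("Panel references unknown unit(s): ",
                 paste(utils::head(missing_units, 5), collapse = ", "), "."))
  }
  last_year <- max(years)

  pieces <- purrr::map(cohorts, function(g) {
    treated_ids <- units$area_id[!is.na(units$title_year) &
                                   units$title_year == g]
    control_ids <- units$area_id[is.na(units$title_year)]
    if (control_rule == "not_yet_treated") {
      control_ids <- c(control_ids,
                       units$area_id[!is.na(units$title_year) &
                                       units$title_year > last_year])
    }
    if (length(control_ids) == 0) {
      abort(paste0("Empty control pool for cohort ", g, "."))
    }
    ids <- c(treated_ids, control_ids)
    sub <- panel[panel$area_id %in% ids & panel$year %in% years, ]
    sub$cohort_id <- as.integer(g)
    sub$treat <- as.integer(sub$area_id %in% treated_ids)
    sub$post <- as.integer(sub$year >= g)
    sub$did <- sub$treat * sub$post
    sub
  })
  stack <- dplyr::bind_rows(pieces)
  stack <- dplyr::rename(stack, outcome_rate = "rate")
  stack$cohort_area <- paste(stack$cohort_id, stack$area_id, sep = ":")
  stack$cohort_year <- paste(stack$cohort_id, stack$year, sep = ":")
  stack$cohort_post <- paste(stack$cohort_id, stack$post, sep = ":")
  stack$cohort_treat <- paste(stack$cohort_id, stack$treat, sep = ":")

  per_cohort <- dplyr::summarise(
    dplyr::group_by(stack, .data$cohort_id),
    n_units = dplyr::n_distinct(.data$area_id),
    n_treated = dplyr::n_distinct(.data$area_id[.data$treat == 1]),
    .groups = "drop"
  )
  summary <- structure(
    list(
      n_cohorts = length(cohorts),
      n_rows = nrow(stack),
      n_clusters = dplyr::n_distinct(stack$area_id),
      per_cohort = per_cohort
    ),
    class = "stack_summary"
  )
  list(stack = as_tibble(stack), summary = summary)
}

#' @export
print.stack_summary <- function(x, ...) {
  cat("<stack_summary> ", x$n_cohorts, " cohorts, ", x$n_rows, " rows, ",
      x$n_clusters, " clusters\n", sep = "")
  print(x$per_cohort)
  invisible(x)
}

#' Standardize a covariate over the estimation sample
#'
#' Replaces `column` by `(x - mean(x)) / sd_n(x)` where `sd_n` uses the
#' population denominator `n`, computed over the rows of the estimation
#' sample (i.e. after stacking, once per regression sample).
#'
#' @param stack A stacked panel tibble (or any data frame).
#' @param column Name of the column to standardize.
#' @return The input with `column` standardized.
#' @export
standardize_covariate <- function(stack, column = "precip_std") {
  if (!column %in% names(stack)) {
    abort(paste0("Column '", column, "' not found."))
  }
  x <- stack[[column]]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s == 0) {
    abort(paste0("Column '", column, "' is constant; cannot standardize."))
  }
  stack[[column]] <- (x - m) / s
  stack
}

#' Fixed-effect layout for the stacked regression
#'
#' `fe_mode = "shared"` (default) uses the four-layer layout of the target
#' design: shared study-area fixed effects, shared year fixed effects,
#' cohort-specific pre/post fixed effects and cohort-specific treated/control
#' group fixed effects. `fe_mode = "interacted"` interacts the area and year
#' effects with the cohort as well (fully cohort-specific sub-experiments).
#'
#' @param fe_mode `"shared"` or `"interacted"`.
#' @return Character vector of fixed-effect key columns present in
#'   [build_stack()]'s output.
#' @export
fe_columns <- function(fe_mode = c("shared", "interacted")) {
  fe_mode <- match.arg(fe_mode)
  if (fe_mode == "shared") {
    c("area_id", "year", "cohort_post", "cohort_treat")
  } else {
    c("cohort_area", "cohort_year", "cohort_post", "cohort_treat")
  }
}
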