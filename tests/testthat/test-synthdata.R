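test_that("scenario validation rejects invalid designs", {
  expect_error(sim_scenario(cohort_years = 1995, panel_years = 2001:2019),
               "within")
  expect_error(sim_scenario(n_controls = 0), "positive")
  expect_error(sim_scenario(n_treated_per_cohort = 0), "positive")
  expect_error(sim_scenario(cohort_years = c(2010, 2014),
                            tau = c(0.1, 0.2)), "named")
  expect_error(sim_scenario(year_fe = c(0, 1)), "length")
})

test_that("panel generator is deterministic and satisfies its invariants", {
  sc <- tiny_scenario(seed = 7)
  a <- simulate_panel(sc)
  b <- simulate_panel(sc)
  expect_identical(a, b)

  n_units <- sum(sc$n_treated_per_cohort) + sc$n_controls
  expect_equal(nrow(a$units), n_units)
  expect_equal(nrow(a$panel), n_units * length(sc$panel_years))
  expect_true(all(a$units$total_area_ha > 0))
  # title year present iff titled
  expect_true(all(is.na(a$units$title_year) ==
                    (a$units$title_type == "candidate")))
  # rate in [0,1], loss bounded by area
  expect_true(all(a$panel$rate >= 0 & a$panel$rate <= 1))
  expect_true(all(a$panel$loss_ha <= a$panel$total_area_ha))
  # a different seed changes the draws
  expect_false(identical(a$panel$loss_ha,
                         simulate_panel(tiny_scenario(seed = 8))$panel$loss_ha))
})

test_that("degenerate constant-rate scenario recovers the baseline rate", {
  sc <- sim_scenario(
    n_treated_per_cohort = 10, n_controls = 190, cohort_years = 2010,
    tau = 0, beta_precip = 0, unit_fe_sd = 0, year_fe = 0,
    baseline_log_rate = log(0.01),
    area_ha_distribution = list(dist = "fixed", value = 500), seed = 11
  )
  panel <- simulate_panel(sc)$panel
  expect_equal(nrow(panel), 200 * 19)
  mc_se <- sd(panel$rate) / sqrt(nrow(panel))
  expect_lt(abs(mean(panel$rate) - 0.01), 3 * mc_se)
})

test_that("homogeneous treatment effect scales treated-post rates by exp(tau)", {
  # Identical outcome law across units (no unit/year/precip effects), one
  # cohort: the treated-post vs control-post group-mean ratio is the oracle.
  sc <- sim_scenario(
    n_treated_per_cohort = 100, n_controls = 100, cohort_years = 2010,
    tau = 0.5, beta_precip = 0, unit_fe_sd = 0, year_fe = 0,
    baseline_log_rate = log(0.02),
    area_ha_distribution = list(dist = "fixed", value = 500), seed = 42
  )
  sim <- simulate_panel(sc)
  post <- dplyr::left_join(sim$panel, sim$units[, c("area_id", "title_type")],
                           by = "area_id") |>
    dplyr::filter(year >= 2010)
  g <- split(post$rate, post$title_type != "candidate")
  m0 <- mean(g[["FALSE"]]); m1 <- mean(g[["TRUE"]])
  se_log <- sqrt(sd(g[["FALSE"]])^2 / m0^2 / length(g[["FALSE"]]) +
                   sd(g[["TRUE"]])^2 / m1^2 / length(g[["TRUE"]]))
  expect_lt(abs(log(m1 / m0) - 0.5), 3 * se_log)
})

test_that("htr_degraded preset plants the -0.83 effect on treated-post rates", {
  sc <- preset_scenario("htr_degraded",
                        n_treated_per_cohort = 60, n_controls = 5,
                        cohort_years = 2008, unit_fe_sd = 0, year_fe = 0,
                        beta_precip = 0,
                        area_ha_distribution = list(dist = "fixed",
                                                    value = 1000))
  expect_equal(unname(sc$tau), -0.83)
  expect_equal(sc$title_type, "HTR")
  # Counterfactual: the same design with tau = 0.
  sc0 <- sc; sc0$tau <- 0
  ratio_logs <- vapply(1:8, function(s) {
    sc$seed <- s; sc0$seed <- s
    tp <- function(x) {
      sim <- simulate_panel(x)
      treated <- sim$units$area_id[sim$units$title_type != "candidate"]
      mean(sim$panel$rate[sim$panel$area_id %in% treated &
                            sim$panel$year >= 2008])
    }
    log(tp(sc) / tp(sc0))
  }, numeric(1))
  mc_se <- sd(ratio_logs) / sqrt(length(ratio_logs))
  expect_lt(abs(mean(ratio_logs) - (-0.83)), 3 * mc_se + 0.02)
})

test_that("with tau = 0 treated and control outcomes share one law", {
  # Two-sample test of treated-post vs control-post mean rates across seeds
  # rejects at about the nominal level.
  rejections <- vapply(1:30, function(s) {
    sc <- sim_scenario(
      n_treated_per_cohort = 30, n_controls = 30, cohort_years = 2010,
      tau = 0, beta_precip = 0, unit_fe_sd = 0, year_fe = 0,
      area_ha_distribution = list(dist = "fixed", value = 300), seed = s
    )
    sim <- simulate_panel(sc)
    treated <- sim$units$area_id[sim$units$title_type != "candidate"]
    post <- sim$panel[sim$panel$year >= 2010, ]
    tt <- stats::t.test(post$rate[post$area_id %in% treated],
                        post$rate[!post$area_id %in% treated])
    tt$p.value < 0.05
  }, logical(1))
  # binomial(30, 0.05): >= 7 rejections has probability < 1e-3
  expect_lte(sum(rejections), 6)
})

test_that("preset grid covers the estimation cells with planted values", {
  expect_equal(unname(preset_scenario("HD", "all")$tau), 0.14)
  expect_equal(preset_scenario("HD", "primary")$beta_precip, -0.32)
  expect_equal(preset_scenario("HTR", "all")$title_type, "HTR")
  expect_error(preset_scenario("HTR", "primary"), "No preset cell")
  expect_error(preset_scenario("XX", "all"), "Unknown title type")
})
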