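test_that("intercept-only fit recovers the closed-form Poisson mean", {
  d <- tibble::tibble(y = c(1, 2, 3), x = 0, id = c("a", "b", "c"))
  expect_message(
    fit <- fit_ppml(d, outcome = "y", covariates = "x", fe = character(0),
                    cluster = "id"),
    "collinear"
  )
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(2),
               tolerance = 1e-8)
  expect_equal(fit$dropped_collinear, "x")
})

test_that("absorbed-FE estimates equal the explicit-dummy GLM oracle", {
  # small stack (~475 rows), two absorbed dimensions
  sc <- sim_scenario(n_treated_per_cohort = 5, n_controls = 20,
                     cohort_years = 2010, tau = 0.3, seed = 7)
  stack <- make_stack(sc)
  fit <- fit_ppml(stack, fe = c("area_id", "year"))
  ref <- oracle_glm(stack, c("area_id", "year"))
  expect_equal(unname(fit$coefficients[c("did", "precip_std")]),
               unname(ref$coef), tolerance = 1e-6)
  expect_equal(unname(fit$se[c("did", "precip_std")]), unname(ref$se),
               tolerance = 1e-4)
  expect_equal(fit$n_obs, ref$n)
})

test_that("count-plus-offset mode is supported and consistent", {
  sc <- tiny_scenario(tau = 0.4, seed = 13)
  stack <- make_stack(sc)
  stack$log_area <- log(stack$total_area_ha)
  fit_count <- fit_ppml(stack, outcome = "loss_ha", offset = "log_area",
                        fe = fe_columns("shared"))
  # zero offset is a no-op
  stack$zero <- 0
  fit0 <- fit_ppml(stack, fe = fe_columns("shared"))
  fitz <- fit_ppml(stack, offset = "zero", fe = fe_columns("shared"))
  expect_equal(fit0$coefficients, fitz$coefficients, tolerance = 1e-9)
  # the count formulation recovers the planted effect within its own CI
  expect_lt(abs(fit_count$coefficients["did"] - 0.4),
            3 * fit_count$se["did"])
})

test_that("outcome scaling leaves the treatment coefficient unchanged", {
  stack <- make_stack(tiny_scenario(seed = 5))
  f1 <- fit_ppml(stack, fe = fe_columns("shared"))
  stack$outcome_rate <- stack$outcome_rate * 37.5
  f2 <- fit_ppml(stack, fe = fe_columns("shared"))
  expect_equal(f1$coefficients["did"], f2$coefficients["did"],
               tolerance = 1e-6)
  expect_equal(f1$se["did"], f2$se["did"], tolerance = 1e-6)
})

test_that("all-zero-outcome FE groups are dropped and reported", {
  sc <- sim_scenario(n_treated_per_cohort = 4, n_controls = 12,
                     cohort_years = 2010, tau = 0, seed = 2)
  stack <- make_stack(sc)
  # force one unit to all-zero outcomes
  victim <- stack$area_id[1]
  stack$outcome_rate[stack$area_id == victim] <- 0
  fit <- fit_ppml(stack, fe = c("area_id", "year"))
  expect_gte(fit$n_dropped_separated, 19)
  expect_equal(fit$n_obs + fit$n_dropped_separated, nrow(stack))
  # matching oracle on the same dropped sample
  ref <- oracle_glm(stack, c("area_id", "year"))
  expect_equal(unname(fit$coefficients[c("did", "precip_std")]),
               unname(ref$coef), tolerance = 1e-6)

  stack$outcome_rate <- 0
  expect_error(fit_ppml(stack, fe = c("area_id", "year")), "separated")
})

test_that("clustered sandwich matches a hand computation on 9 rows", {
  # 3 clusters x 3 rows, one covariate, no fixed effects
  d <- tibble::tibble(
    y = c(1, 2, 0, 4, 3, 5, 2, 2, 1),
    x = c(0.1, -0.2, 0.3, 1.1, 0.9, 1.4, -0.5, -0.1, 0.2),
    cl = rep(c("a", "b", "c"), each = 3)
  )
  fit <- fit_ppml(d, outcome = "y", covariates = "x", fe = character(0),
                  cluster = "cl")
  # hand-computed sandwich at the fitted coefficients
  X <- cbind(1, d$x)
  mu <- exp(X %*% fit$coefficients)
  A <- t(X) %*% (X * as.vector(mu))
  S <- X * as.vector(d$y - mu)
  Sc <- rowsum(S, d$cl)
  V <- solve(A) %*% ((3 / 2) * t(Sc) %*% Sc) %*% solve(A)
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-10)

  expect_error(cluster_vcov(fit, cluster = rep("one", 9)), "2 clusters")
})

test_that("degenerate one-row clusters reduce to the HC variance", {
  set.seed(1)
  d <- tibble::tibble(
    y = rpois(40, exp(0.5 + 0.3 * rep(c(0, 1), 20))),
    x = rep(c(0, 1), 20),
    id = sprintf("r%02d", 1:40)
  )
  fit <- fit_ppml(d, outcome = "y", covariates = "x", fe = character(0),
                  cluster = "id")
  g <- stats::glm(y ~ x, family = stats::poisson(), data = d)
  hc0 <- sandwich::vcovHC(g, type = "HC0")
  expect_equal(unname(fit$vcov), unname(hc0) * 40 / 39, tolerance = 1e-6)
})

test_that("duplicating rows within clusters leaves clustered SEs unchanged", {
  stack <- make_stack(tiny_scenario(seed = 9))
  f1 <- fit_ppml(stack, fe = fe_columns("shared"))
  f2 <- fit_ppml(dplyr::bind_rows(stack, stack), fe = fe_columns("shared"))
  expect_equal(f1$coefficients["did"], f2$coefficients["did"],
               tolerance = 1e-7)
  expect_equal(f1$se["did"], f2$se["did"], tolerance = 1e-6)
})

test_that("Wald intervals are symmetric and match printed-style values", {
  # width 0.24 around 0.14 reproduces [0.02, 0.26]
  ci <- ci_wald(0.14, 0.24 / (2 * qnorm(0.975)))
  expect_equal(round(ci[1, ], 2), c(low = 0.02, high = 0.26))
  # standard normal quantile
  ci2 <- ci_wald(0, 1)
  expect_equal(unname(ci2[1, ]), c(-1.959964, 1.959964), tolerance = 1e-6)
  # zero-SE limit collapses to the point estimate
  ci3 <- ci_wald(0.5, 0)
  expect_equal(unname(ci3[1, ]), c(0.5, 0.5))
  expect_error(ci_wald(0, 1, level = 1.2), "level")
  expect_error(ci_wald(0, -1), ">= 0")
})

test_that("tidy, glance and confint expose the estimate contract", {
  stack <- make_stack(tiny_scenario(seed = 3))
  fit <- fit_ppml(stack, fe = fe_columns("shared"))
  td <- tidy(fit)
  expect_setequal(td$term, c("did", "precip_std"))
  expect_equal(td$conf.high - td$estimate, td$estimate - td$conf.low,
               tolerance = 1e-10)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_lte(gl$n.clusters, gl$nobs)
  ci <- confint(fit, "did")
  expect_equal(unname(ci[1, 1]),
               unname(fit$coefficients["did"] - 1.959964 * fit$se["did"]),
               tolerance = 1e-5)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("input validation fails fast", {
  stack <- make_stack(tiny_scenario(seed = 4))
  expect_error(fit_ppml(stack, outcome = "nope"), "not found")
  expect_error(fit_ppml(stack, covariates = character(0)), "one covariate")
  neg <- stack; neg$outcome_rate[1] <- -1
  expect_error(fit_ppml(neg), "non-negative")
  nacl <- stack; nacl$area_id[1] <- NA
  expect_error(fit_ppml(nacl), "Cluster key")
})
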