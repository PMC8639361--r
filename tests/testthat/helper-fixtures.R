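# Shared fixtures: small deterministic scenarios and the explicit-dummy GLM
# oracle used to cross-check the absorbed-FE estimator.

tiny_scenario <- function(tau = 0.5, seed = 42, ...) {
  args <- list(
    n_treated_per_cohort = 10, n_controls = 40,
    cohort_years = c(2010, 2014), tau = tau, seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_scenario, args)
}

make_stack <- function(scenario) {
  sim <- simulate_panel(scenario)
  st <- build_stack(sim$units, sim$panel)
  standardize_covariate(st$stack, "precip_std")
}

# Explicit-dummy-variable Poisson GLM with cluster-robust SEs: the
# independent oracle for fit_ppml. Drops separated rows the same way the
# estimator defines them (FE groups with all-zero outcome) so both work on
# the same likelihood.
oracle_glm <- function(stack, fe_cols, covariates = c("did", "precip_std"),
                       outcome = "outcome_rate", cluster = "area_id") {
  df <- as.data.frame(stack)
  repeat {
    changed <- FALSE
    for (f in fe_cols) {
      g <- df[[f]]
      zero <- names(which(tapply(df[[outcome]], g, sum) == 0))
      if (length(zero) > 0) {
        df <- df[!(g %in% zero), , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (f in fe_cols) df[[f]] <- factor(df[[f]])
  fml <- stats::as.formula(paste(
    outcome, "~", paste(c(covariates, fe_cols), collapse = " + ")))
  g <- suppressWarnings(stats::glm(fml, family = stats::poisson(), data = df,
                                   control = list(epsilon = 1e-12,
                                                  maxit = 100)))
  V <- sandwich::vcovCL(g, cluster = df[[cluster]], cadjust = TRUE)
  list(
    coef = stats::coef(g)[covariates],
    se = sqrt(diag(V)[covariates]),
    n = nrow(df)
  )
}
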