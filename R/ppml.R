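#' Poisson pseudo-maximum-likelihood with absorbed fixed effects
#'
#' Fits the log-link conditional-mean model
#' `E[y | x] = exp(x'b + fe)` by iteratively reweighted least squares,
#' absorbing high-dimensional fixed effects through weighted alternating
#' demeaning of the working variables instead of explicit dummy columns.
#' PPML is consistent for any non-negative outcome with this conditional
#' mean — counts or rates alike — so the deforestation rate can be used
#' directly; an equivalent count formulation passes `loss_ha` as the outcome
#' with `offset = log(total_area_ha)`.
#'
#' Observations belonging to a fixed-effect group whose outcome is
#' identically zero are perfectly fit by a group effect of minus infinity
#' and carry no information about `b`; they are dropped before estimation
#' (iterating across dimensions until stable) and counted in
#' `n_dropped_separated`. Collinear covariates are detected by pivoted QR on
#' the demeaned design and dropped with a message.
#'
#' Standard errors are cluster-robust: the sandwich
#' `A^{-1} (sum_c s_c s_c') A^{-1}` on the absorbed design, where `A` is the
#' expected information for `b` after profiling out the fixed effects and
#' `s_c` sums the scores `(y_i - mu_i) x~_i` within cluster `c`, with a
#' `G/(G-1)` small-sample factor (switchable via [cluster_vcov()]).
#'
#' @param data Data frame of observations (typically the `stack` from
#'   [build_stack()]).
#' @param outcome Name of the non-negative outcome column (default
#'   `"outcome_rate"`).
#' @param covariates Character vector of covariate column names (default
#'   `c("did", "precip_std")`).
#' @param fe Character vector of fixed-effect key columns to absorb, e.g.
#'   [fe_columns()]; may be empty (`character(0)`) for no fixed effects, in
#'   which case an intercept is included.
#' @param cluster Name of the cluster key column (default `"area_id"`, the
#'   level at which treatment is assigned).
#' @param offset Optional name of a column added (on the log scale) to the
#'   linear predictor with coefficient one.
#' @param tol Relative deviance-change convergence tolerance.
#' @param coef_tol Maximum absolute coefficient-change tolerance.
#' @param demean_tol Inner alternating-projection tolerance.
#' @param max_iter Maximum IRLS iterations; non-convergence is an error
#'   carrying the deviance trace.
#' @return An object of class `ppml_fit` with elements `coefficients`,
#'   `se`, `ci` (95% Wald), `vcov`, `n_obs`, `n_clusters`,
#'   `n_dropped_separated`, `iterations`, `converged`, `deviance`,
#'   `dropped_collinear`, plus the internals needed by [cluster_vcov()].
#'   Methods: [tidy()], [glance()], `confint()`, `print()`, [autoplot()].
#' @export
#' @examples
#' sim <- simulate_panel(sim_scenario(n_treated_per_cohort = 5,
#'                                    n_controls = 20,
#'                                    cohort_years = c(2010, 2015),
#'                                    tau = 0.5, seed = 1))
#' st <- build_stack(sim$units, sim$panel)
#' fit <- fit_ppml(st$stack, fe = fe_columns("shared"))
#' tidy(fit)
fit_ppml <- function(data, outcome = "outcome_rate",
                     covariates = c("did", "precip_std"),
                     fe = fe_columns("shared"),
                     cluster = "area_id",
                     offset = NULL,
                     tol = 1e-8, coef_tol = 1e-7, demean_tol = 1e-8,
                     max_iter = 100L) {
  for (col in c(outcome, covariates, fe, cluster, offset)) {
    if (!col %in% names(data)) abort(paste0("Column '", col, "' not found."))
  }
  if (length(covariates) < 1) abort("Need at least one covariate.")
  y <- as.numeric(data[[outcome]])
  if (any(!is.finite(y)) || any(y < 0)) {
    abort("Outcome must be finite and non-negative.")
  }
  X <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  cl <- data[[cluster]]
  if (anyNA(cl)) abort("Cluster key must be defined for all rows.")
  off <- if (is.null(offset)) rep(0, length(y)) else as.numeric(data[[offset]])
  fe_raw <- lapply(fe, function(f) data[[f]])

  # Separation: drop rows in all-zero-outcome FE groups, iterating since a
  # drop in one dimension can empty groups of another.
  keep <- rep(TRUE, length(y))
  if (length(fe_raw) > 0) {
    repeat {
      changed <- FALSE
      for (f in fe_raw) {
        g <- factor(f[keep])
        zero_groups <- levels(g)[tapply(y[keep], g, sum) == 0]
        if (length(zero_groups) > 0) {
          drop_now <- keep & (as.character(f) %in% zero_groups)
          keep[drop_now] <- FALSE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  n_dropped <- sum(!keep)
  if (!any(keep)) abort("All observations separated (every FE group has all-zero outcome).")
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  cl <- cl[keep]; off <- off[keep]
  fe_idx <- lapply(fe_raw, function(f) .fe_codes(f[keep])$idx)
  n <- length(y)

  if (length(fe_idx) == 0) {
    # No absorbed dimensions: include an explicit intercept.
    X <- cbind(`(Intercept)` = 1, X)
  }

  # Initialize near the group means of the first FE dimension (global mean
  # when nothing is absorbed); all groups have positive means post-drop.
  ybar <- if (length(fe_idx) > 0) {
    gm <- rowsum(y, fe_idx[[1]]) / tabulate(fe_idx[[1]])
    gm[fe_idx[[1]]]
  } else rep(mean(y), n)
  mu <- pmax((y + ybar) / 2, 1e-12)
  eta <- log(mu)

  dev <- .poisson_deviance(y, mu)
  beta <- rep(0, ncol(X))
  dev_trace <- dev
  converged <- FALSE
  kept_cols <- seq_len(ncol(X))
  iter <- 0L

  coef_change <- Inf
  for (iter in seq_len(max_iter)) {
    w <- mu
    z <- (eta - off) + (y - mu) / mu
    # Loose inner tolerance while the outer iteration is far from its
    # optimum; full precision once coefficient movement is small.
    tol_inner <- if (coef_change > 1e-3) max(demean_tol, 1e-6) else demean_tol
    ZM <- .demean_fe(cbind(z, X), w, fe_idx, tol = tol_inner)
    zt <- ZM[, 1]
    Xt <- ZM[, -1, drop = FALSE]

    sw <- sqrt(w)
    qrX <- qr(Xt[, kept_cols, drop = FALSE] * sw)
    rank <- qrX$rank
    if (rank < length(kept_cols)) {
      dropped <- kept_cols[qrX$pivot[(rank + 1):length(kept_cols)]]
      inform(paste0("Dropping collinear covariate(s): ",
                    paste(colnames(X)[dropped], collapse = ", "), "."))
      kept_cols <- setdiff(kept_cols, dropped)
      qrX <- qr(Xt[, kept_cols, drop = FALSE] * sw)
    }
    beta_new <- beta
    beta_new[kept_cols] <- qr.coef(qrX, zt * sw)
    beta_new[setdiff(seq_along(beta), kept_cols)] <- NA_real_
    resid <- zt - Xt[, kept_cols, drop = FALSE] %*%
      beta_new[kept_cols]
    eta_new <- (z - resid) + off

    mu_new <- exp(eta_new)
    dev_new <- .poisson_deviance(y, mu_new)
    # Step-halve if the deviance worsens appreciably. The starting values
    # are quasi-saturated (deviance below the model minimum), so halving
    # only engages once the linear predictor lies in the model space.
    halvings <- 0L
    while (iter > 1L && is.finite(dev) &&
           (!is.finite(dev_new) || dev_new > dev * (1 + 1e-10)) &&
           halvings < 20L) {
      eta_new <- (eta_new + eta) / 2
      beta_new[kept_cols] <- (beta_new[kept_cols] + beta[kept_cols]) / 2
      mu_new <- exp(eta_new)
      dev_new <- .poisson_deviance(y, mu_new)
      halvings <- halvings + 1L
    }

    coef_change <- max(abs(beta_new[kept_cols] - beta[kept_cols]), 0)
    dev_change <- abs(dev_new - dev) / (0.1 + abs(dev_new))
    beta <- beta_new; eta <- as.vector(eta_new); mu <- as.vector(mu_new)
    dev <- dev_new
    dev_trace <- c(dev_trace, dev)
    if (dev_change < tol && coef_change < coef_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(paste0("PPML did not converge in ", max_iter,
                 " iterations. Deviance trace: ",
                 paste(signif(utils::tail(dev_trace, 8), 6), collapse = ", ")))
  }

  # Final absorbed design at the converged weights, for inference.
  w <- mu
  Xt <- .demean_fe(X, w, fe_idx, tol = demean_tol)
  Xk <- Xt[, kept_cols, drop = FALSE]
  A <- crossprod(Xk * sqrt(w))
  bread_inv <- solve(A)

  fit <- structure(
    list(
      coefficients = setNames(as.vector(beta), colnames(X)),
      kept = colnames(X)[kept_cols],
      dropped_collinear = colnames(X)[setdiff(seq_along(beta), kept_cols)],
      n_obs = n,
      n_clusters = dplyr::n_distinct(cl),
      n_dropped_separated = n_dropped,
      iterations = iter,
      converged = converged,
      deviance = dev,
      outcome = outcome,
      fe = fe,
      cluster_name = cluster,
      # internals for the sandwich
      X_demeaned = Xk,
      weights = w,
      score_resid = y - mu,
      cluster_values = cl,
      bread_inv = bread_inv,
      fitted = mu
    ),
    class = "ppml_fit"
  )
  V <- cluster_vcov(fit)
  se <- setNames(rep(NA_real_, length(beta)), colnames(X))
  se[fit$kept] <- sqrt(diag(V))
  fit$vcov <- V
  fit$se <- se
  fit$ci <- ci_wald(fit$coefficients, se)
  fit
}

.poisson_deviance <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

#' Cluster-robust sandwich variance for a PPML fit
#'
#' Computes `V = A^{-1} (sum_c s_c s_c') A^{-1}` on the absorbed design,
#' where `A = X~' W X~` is the expected information for the covariates after
#' profiling out the fixed effects and `s_c` is the within-cluster sum of
#' the scores `(y_i - mu_i) x~_i`. With `small_sample = TRUE` (default) the
#' meat is scaled by `G/(G-1)`, `G` the number of clusters.
#'
#' @param fit A `ppml_fit`.
#' @param cluster Optional replacement cluster assignment (vector of length
#'   `n_obs`); defaults to the clustering used at fit time.
#' @param small_sample Apply the `G/(G-1)` factor?
#' @return Variance matrix for the retained covariates.
#' @export
cluster_vcov <- function(fit, cluster = NULL, small_sample = TRUE) {
  stopifnot(inherits(fit, "ppml_fit"))
  cl <- cluster %||% fit$cluster_values
  if (length(cl) != fit$n_obs) {
    abort("`cluster` must assign a cluster to every estimation row.")
  }
  G <- dplyr::n_distinct(cl)
  if (G < 2) abort("Need at least 2 clusters.")
  S <- fit$X_demeaned * fit$score_resid
  Sc <- rowsum(S, as.integer(factor(cl)))
  meat <- crossprod(Sc)
  adj <- if (small_sample) G / (G - 1) else 1
  fit$bread_inv %*% (adj * meat) %*% fit$bread_inv
}

#' Symmetric Wald confidence interval
#'
#' `estimate +/- z * se` with `z` the standard-normal quantile for the
#' requested two-sided level.
#'
#' @param estimate,se Numeric vectors (recycled); `se` must be >= 0.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A two-column matrix `low`, `high`.
#' @export
#' @examples
#' ci_wald(0.14, 0.24 / (2 * qnorm(0.975))) # about [0.02, 0.26]
ci_wald <- function(estimate, se, level = 0.95) {
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  if (any(se < 0, na.rm = TRUE)) abort("`se` must be >= 0.")
  z <- qnorm(1 - (1 - level) / 2)
  cbind(low = estimate - z * se, high = estimate + z * se)
}

#' @export
confint.ppml_fit <- function(object, parm = NULL, level = 0.95, ...) {
  est <- object$coefficients
  se <- object$se
  if (!is.null(parm)) {
    est <- est[parm]; se <- se[parm]
  }
  ci <- ci_wald(est, se, level)
  rownames(ci) <- names(est)
  ci
}

#' @export
print.ppml_fit <- function(x, digits = 4, ...) {
  cat("PPML fit (absorbed FE:", if (length(x$fe)) paste(x$fe, collapse = " + ")
      else "none", ")\n")
  td <- tidy(x)
  print(as.data.frame(td), digits = digits, row.names = FALSE)
  cat(x$n_obs, "obs,", x$n_clusters, "clusters (", x$cluster_name, "),",
      x$n_dropped_separated, "separated rows dropped,",
      x$iterations, "IRLS iterations\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ppml_fit <- function(x, conf.int = TRUE, conf.level = 0.95, ...) {
  est <- x$coefficients[x$kept]
  se <- x$se[x$kept]
  stat <- est / se
  out <- tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pnorm(-abs(unname(stat)))
  )
  if (conf.int) {
    ci <- ci_wald(est, se, conf.level)
    out$conf.low <- unname(ci[, "low"])
    out$conf.high <- unname(ci[, "high"])
  }
  out
}

#' @exportS3Method generics::glance
glance.ppml_fit <- function(x, ...) {
  tibble(
    nobs = x$n_obs,
    n.clusters = x$n_clusters,
    n.separated = x$n_dropped_separated,
    deviance = x$deviance,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.ppml_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Coefficient (log deforestation rate)", y = NULL,
                  title = "PPML estimates with cluster-robust 95% CI") +
    ggplot2::theme_minimal()
}
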