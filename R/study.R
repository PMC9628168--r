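#' Frequentist metrics for replicated Bayesian estimates
#'
#' Given replicated point estimates (posterior means) of a parameter with a
#' known generating value: `relative_bias` is the mean of
#' \eqn{(\hat\theta - \theta)/\theta} (undefined, and an error, when the
#' truth is zero); `mse_est` is the mean of \eqn{(\hat\theta - \theta)^2};
#' `coverage` is the fraction of credible intervals containing the truth,
#' with a truth exactly on a bound counting as covered (closed intervals).
#'
#' @param estimates numeric vector of per-replicate estimates.
#' @param truth generating parameter value.
#' @param intervals two-column matrix (lower, upper) of per-replicate
#'   credible intervals.
#' @return a single number.
#' @name study_metrics
NULL

#' @rdname study_metrics
#' @export
relative_bias <- function(estimates, truth) {
  if (truth == 0) stop("relative bias is undefined for a zero truth", call. = FALSE)
  mean((estimates - truth) / truth)
}

#' @rdname study_metrics
#' @export
mse_est <- function(estimates, truth) {
  stopifnot(length(estimates) >= 1)
  mean((estimates - truth)^2)
}

#' @rdname study_metrics
#' @export
coverage <- function(intervals, truth) {
  intervals <- matrix(intervals, ncol = 2)
  if (any(intervals[, 1] > intervals[, 2]))
    stop("interval lower bounds exceed upper bounds", call. = FALSE)
  mean(intervals[, 1] <= truth & truth <= intervals[, 2])
}

#' Simulation study: replicated simulate-fit-score cycles
#'
#' For every combination of sample size `n` and fitted family, repeatedly
#' generates a dataset from `design` (with `n` substituted), fits the
#' zero-augmented two-part model of that family by MCMC, and accumulates
#' relative bias, MSE and 95% coverage per parameter plus the convergence
#' rate (fraction of fits with all split-chain R-hat below `rhat_threshold`)
#' and, optionally, the four model-comparison criteria per fit. Replicate
#' seeds are derived deterministically from `seed`, so a run is reproducible
#' end to end.
#'
#' @param design a [sim_design]; its `n` is overridden by `n_values`.
#' @param n_values integer vector of level-3 sample sizes.
#' @param fit_families character vector of families to fit (`"bp"`,
#'   `"gamma"`); the generating family is `design$family`.
#' @param n_reps replicates per cell (study default 100; reduce for
#'   desk-scale runs).
#' @param control a [zab_control]; its seed is overridden per replicate.
#' @param seed master seed.
#' @param criteria also compute DIC3/LPML/WAIC/LOO per fit?
#' @param exclude_nonconverged drop non-converged fits from the bias/MSE/CP
#'   averages? They always count in the convergence rate.
#' @param rhat_threshold R-hat convergence threshold.
#' @return object of class `zab_study`: list with `metrics` (data frame with
#'   columns `true_model`, `fitted_model`, `n`, `parameter`, `rel_bias`,
#'   `mse`, `cp`, `cr`) and `criteria` (data frame, or `NULL`).
#' @export
run_study <- function(design, n_values = design$n, fit_families = design$family,
                      n_reps = 100, control = zab_control(n_iter = 10000,
                        n_burnin = 5000, thin = 20),
                      seed = 1, criteria = FALSE,
                      exclude_nonconverged = FALSE, rhat_threshold = 1.1) {
  stopifnot(inherits(design, "zab_sim_design"))
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps * length(n_values))
  dim(rep_seeds) <- c(n_reps, length(n_values))

  truth_of <- function(d, fam) {
    # psi/sigma scales are family-specific; only comparable when the fitted
    # family matches the generating one
    c(beta0 = d$beta0, beta1 = d$beta1, tau = d$tau,
      sigma2_p = d$sigma2_p, sigma2_c = d$sigma2_c, psi = d$psi)
  }
  par_name <- c(beta0 = "beta_(Intercept)", beta1 = "beta_x", tau = "tau",
                sigma2_p = "sigma2_p", sigma2_c = "sigma2_c", psi = "psi")

  metrics <- list(); crit_rows <- list()
  for (ni in seq_along(n_values)) {
    n <- n_values[ni]
    d <- design; d$n <- as.integer(n)
    ests <- list(); los <- list(); his <- list(); conv <- list()
    for (fam in fit_families) {
      k <- length(par_name)
      ests[[fam]] <- matrix(NA_real_, n_reps, k, dimnames = list(NULL, names(par_name)))
      los[[fam]] <- ests[[fam]]; his[[fam]] <- ests[[fam]]
      conv[[fam]] <- logical(n_reps)
    }
    for (r in seq_len(n_reps)) {
      sim <- simulate_sim_design(d, seed = rep_seeds[r, ni])
      for (fam in fit_families) {
        ctl <- control
        ctl$seed <- as.integer((rep_seeds[r, ni] + match(fam, c("bp", "gamma"))) %%
                                 (.Machine$integer.max - 2L))
        fit <- zab_fit(sim$data,
                       zab_model(family = fam, constant_tau = TRUE),
                       priors = zab_priors_sim(), control = ctl)
        sm <- summary(fit)
        idx <- match(par_name, sm$parameter)
        ests[[fam]][r, ] <- sm$mean[idx]
        los[[fam]][r, ] <- sm$q2.5[idx]
        his[[fam]][r, ] <- sm$q97.5[idx]
        conv[[fam]][r] <- all(sm$rhat < rhat_threshold, na.rm = TRUE)
        if (criteria) {
          cr <- zab_criteria(fit)
          crit_rows[[length(crit_rows) + 1L]] <- cbind(
            data.frame(true_model = design$family, fitted_model = fam,
                       n = n, rep = r), cr)
        }
      }
    }
    for (fam in fit_families) {
      truth <- truth_of(d, fam)
      keep <- if (exclude_nonconverged) conv[[fam]] else rep(TRUE, n_reps)
      if (!any(keep)) keep <- rep(TRUE, n_reps)
      for (p in names(par_name)) {
        metrics[[length(metrics) + 1L]] <- data.frame(
          true_model = design$family, fitted_model = fam, n = n, parameter = p,
          rel_bias = relative_bias(ests[[fam]][keep, p], truth[[p]]),
          mse = mse_est(ests[[fam]][keep, p], truth[[p]]),
          cp = coverage(cbind(los[[fam]][keep, p], his[[fam]][keep, p]), truth[[p]]),
          cr = mean(conv[[fam]]),
          # dispersion parameters live on different scales across families
          comparable = fam == design$family || p != "psi")
      }
    }
  }
  structure(list(metrics = do.call(rbind, metrics),
                 criteria = if (length(crit_rows)) do.call(rbind, crit_rows) else NULL,
                 seed = as.integer(seed)),
            class = "zab_study")
}

#' @export
print.zab_study <- function(x, digits = 3, ...) {
  cat("Simulation study (seed", x$seed, ")\n")
  m <- x$metrics
  m[c("rel_bias", "mse", "cp", "cr")] <- lapply(m[c("rel_bias", "mse", "cp", "cr")],
                                                round, digits)
  print.data.frame(m, row.names = FALSE)
  invisible(x)
}

#' Effect transforms on the response scale
#'
#' Back-transforms coefficients of the fitted two-part model to directly
#' interpretable quantities: `zero_probability` is the probability of a zero
#' response at a covariate profile of the zero part,
#' \eqn{1 - \mathrm{logit}^{-1}(\alpha'x)}; `pct_odds_change` is the percent
#' change in the odds of a positive response per unit increase of a zero-part
#' covariate, \eqn{100(e^{\alpha_\gamma} - 1)}; `mean_ratio` is the
#' multiplicative change of the positive mean per unit increase of a
#' continuous-part covariate, \eqn{e^{\beta_\theta}}.
#'
#' @param alpha zero-part coefficient vector.
#' @param profile covariate profile (same length as `alpha`, including the
#'   leading 1 for the intercept).
#' @param coef a single coefficient.
#' @examples
#' zero_probability(c(1.645, -0.183), c(1, 1))  # ~0.19: male profile
#' pct_odds_change(0.117)                       # ~12.41%
#' mean_ratio(0.22)                             # ~1.25
#' @return a single number.
#' @name effects
NULL

#' @rdname effects
#' @export
zero_probability <- function(alpha, profile) {
  stopifnot(length(alpha) == length(profile))
  1 - zero_prob(sum(alpha * profile))
}

#' @rdname effects
#' @export
pct_odds_change <- function(coef) 100 * expm1(coef)

#' @rdname effects
#' @export
mean_ratio <- function(coef) exp(coef)

#' Effect report for a fitted model
#'
#' Tabulates [pct_odds_change] for every zero-part coefficient and
#' [mean_ratio] for every continuous-part coefficient at the posterior
#' means, plus the probability of a zero response at a reference profile
#' (all covariates 0, i.e. intercept only).
#'
#' @param summary a `zab_summary` (from [summary.zab_fit]) or a named
#'   coefficient vector with `alpha_*`/`beta_*` names.
#' @return list with `zero_prob_reference`, `odds` (named vector, percent),
#'   `mean_ratios` (named vector).
#' @export
zab_effects <- function(summary) {
  coefs <- if (is.data.frame(summary)) {
    stats::setNames(summary$mean, summary$parameter)
  } else summary
  a <- coefs[grep("^alpha_", names(coefs))]
  b <- coefs[grep("^beta_", names(coefs))]
  list(
    zero_prob_reference = if (length(a)) unname(1 - zero_prob(a[[1]])) else NA_real_,
    odds = if (length(a) > 1) stats::setNames(pct_odds_change(a[-1]),
                                              sub("^alpha_", "", names(a)[-1]))
           else numeric(0),
    mean_ratios = if (length(b) > 1) stats::setNames(mean_ratio(b[-1]),
                                                     sub("^beta_", "", names(b)[-1]))
                  else numeric(0))
}
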