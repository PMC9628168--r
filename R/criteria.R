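logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
logmeanexp <- function(x) logsumexp(x) - log(length(x))

#' Pointwise log-likelihood matrix
#'
#' Evaluates, for every retained posterior draw `m` (chains pooled) and every
#' subject `i`, the log of the hurdle mixture density of subject `i` at draw
#' `m`'s parameters. By default the density is evaluated conditionally on the
#' draw's sampled cluster random effects (the standard practice for
#' CPO/WAIC in hierarchical MCMC output); `marginal = TRUE` instead averages
#' the density over `n_marginal` fresh random-effect draws from their
#' distribution at each posterior draw, approximating the density with the
#' random effects integrated out.
#'
#' @param fit a `zab_fit` object.
#' @param marginal average over fresh random-effect draws?
#' @param n_marginal Monte-Carlo size of the marginalization (per draw).
#' @return a `K x N` matrix of log-densities (class `zab_pointwise`).
#' @export
pointwise_loglik <- function(fit, marginal = FALSE, n_marginal = 20L) {
  data <- fit$data; model <- fit$model
  pool <- pooled_draws(fit)
  K <- nrow(pool); N <- data$N
  re_pool <- list(
    p1 = do.call(rbind, lapply(fit$re, `[[`, "p1")),
    p2 = do.call(rbind, lapply(fit$re, `[[`, "p2")),
    c1 = do.call(rbind, lapply(fit$re, `[[`, "c1")),
    c2 = do.call(rbind, lapply(fit$re, `[[`, "c2")))
  a_cols <- grep("^alpha_", colnames(pool))
  b_cols <- grep("^beta_", colnames(pool))
  out <- matrix(NA_real_, K, N)
  for (m in seq_len(K)) {
    if (marginal) {
      acc <- matrix(NA_real_, n_marginal, N)
      for (r in seq_len(n_marginal)) {
        re <- draw_re_fresh(fit, pool[m, ])
        acc[r, ] <- row_loglik(fit, pool[m, ], re, a_cols, b_cols)
      }
      out[m, ] <- apply(acc, 2, logmeanexp)
    } else {
      re <- list(p1 = re_row(re_pool$p1, m), p2 = re_row(re_pool$p2, m),
                 c1 = re_row(re_pool$c1, m), c2 = re_row(re_pool$c2, m))
      out[m, ] <- row_loglik(fit, pool[m, ], re, a_cols, b_cols)
    }
  }
  structure(out, class = c("zab_pointwise", "matrix"))
}

re_row <- function(m, i) if (is.null(m) || length(m) == 0L || ncol(m) == 0L) NULL else m[i, ]

# fresh random effects from their level distribution at one posterior draw
draw_re_fresh <- function(fit, par) {
  model <- fit$model; data <- fit$data
  out <- list(p1 = NULL, p2 = NULL, c1 = NULL, c2 = NULL)
  rmvn0 <- function(n, S) {
    L <- chol(S)
    matrix(stats::rnorm(2 * n), n, 2) %*% L
  }
  if (fit$has_p) {
    if (model$correlated_re) {
      S <- matrix(c(par["Sigma1[1,1]"], par["Sigma1[1,2]"],
                    par["Sigma1[1,2]"], par["Sigma1[2,2]"]), 2, 2)
      u <- rmvn0(data$n_prov, S)
      out$p1 <- u[, 1]; out$p2 <- u[, 2]
    } else {
      out$p2 <- stats::rnorm(data$n_prov, 0, sqrt(par["sigma2_p"]))
    }
  }
  if (fit$has_c) {
    if (model$correlated_re) {
      S <- matrix(c(par["Sigma2[1,1]"], par["Sigma2[1,2]"],
                    par["Sigma2[1,2]"], par["Sigma2[2,2]"]), 2, 2)
      u <- rmvn0(data$n_city, S)
      out$c1 <- u[, 1]; out$c2 <- u[, 2]
    } else {
      out$c2 <- stats::rnorm(data$n_city, 0, sqrt(par["sigma2_c"]))
    }
  }
  out
}

# per-subject mixture log-density at one parameter draw + one RE state
row_loglik <- function(fit, par, re, a_cols, b_cols) {
  data <- fit$data; model <- fit$model
  eta <- linear_predictors(data,
    alpha = if (model$constant_tau) rep(0, ncol(data$X1)) else par[a_cols],
    beta = par[b_cols],
    p1 = re$p1, p2 = re$p2, c1 = re$c1, c2 = re$c2)
  tau <- if (model$constant_tau) rep(par[["tau"]], data$N) else zero_prob(eta$eta1)
  mu <- exp(pmin(pmax(eta$eta2, -ETA_CAP), ETA_CAP))
  mixture_logpdf(data$y, tau, mu, par[["psi"]], model$family)
}

#' Bayesian model-comparison criteria
#'
#' `dic3` is the modified deviance information criterion
#' \eqn{\mathrm{DIC}_3 = \bar D + p_D}, where \eqn{\bar D} is the posterior
#' mean deviance and \eqn{p_D = \bar D - D(\bar\theta)} with the plug-in
#' deviance evaluated at the posterior means of all quantities, random
#' effects included. `lpml` is the log pseudo marginal likelihood: the sum
#' of log conditional predictive ordinates, each CPO the harmonic mean of
#' the per-draw densities (computed in log space). `waic` uses the
#' variance-based penalty \eqn{p_{\mathrm{WAIC2}}} and satisfies
#' \eqn{\mathrm{WAIC} = 2 p_{\mathrm{WAIC2}} - 2\,\mathrm{LPPD}} exactly.
#' `loo_is` is importance-sampling leave-one-out cross-validation with
#' reciprocal-density weights, optionally truncated at
#' \eqn{\sqrt{K}\,\bar w} for stability; with truncation disabled it equals
#' `-2 * LPML` exactly.
#'
#' Smaller DIC3/WAIC/LOO and larger LPML indicate better fit.
#'
#' @param ll a `K x N` pointwise log-likelihood matrix from
#'   [pointwise_loglik].
#' @param fit the `zab_fit` the matrix came from (needed by `dic3` for the
#'   plug-in deviance).
#' @param truncate truncate the importance weights?
#' @return `dic3`: list `DIC3`, `pD`, `Dbar`; `lpml`: list `LPML`, `CPO`;
#'   `waic`: list `WAIC`, `pWAIC2`, `LPPD`; `loo_is`: list `LOO`,
#'   `LPPD_loo`, `flagged` (subjects whose largest normalized weight
#'   exceeds 0.5).
#' @name criteria
NULL

#' @rdname criteria
#' @export
dic3 <- function(ll, fit) {
  K <- nrow(ll)
  dev <- -2 * rowSums(ll)
  Dbar <- mean(dev)
  pool <- pooled_draws(fit)
  par_bar <- colMeans(pool)
  re_bar <- list(
    p1 = re_mean(fit, "p1"), p2 = re_mean(fit, "p2"),
    c1 = re_mean(fit, "c1"), c2 = re_mean(fit, "c2"))
  a_cols <- grep("^alpha_", colnames(pool))
  b_cols <- grep("^beta_", colnames(pool))
  Dhat <- -2 * sum(row_loglik(fit, par_bar, re_bar, a_cols, b_cols))
  pD <- Dbar - Dhat
  list(DIC3 = Dbar + pD, pD = pD, Dbar = Dbar)
}

re_mean <- function(fit, which) {
  m <- do.call(rbind, lapply(fit$re, `[[`, which))
  if (is.null(m) || length(m) == 0L || ncol(m) == 0L) NULL else colMeans(m)
}

#' @rdname criteria
#' @export
lpml <- function(ll) {
  # log CPO_i = -log mean exp(-ll_i)
  log_cpo <- apply(ll, 2, function(col) {
    if (all(!is.finite(col))) return(-Inf)
    -logmeanexp(-col)
  })
  if (any(!is.finite(log_cpo)))
    warning("some subjects have zero predictive density in every draw; LPML = -Inf")
  list(LPML = sum(log_cpo), CPO = exp(log_cpo))
}

#' @rdname criteria
#' @export
waic <- function(ll) {
  stopifnot(nrow(ll) >= 2)
  lppd_i <- apply(ll, 2, logmeanexp)
  p2_i <- apply(ll, 2, stats::var)
  LPPD <- sum(lppd_i)
  pWAIC2 <- sum(p2_i)
  list(WAIC = 2 * pWAIC2 - 2 * LPPD, pWAIC2 = pWAIC2, LPPD = LPPD)
}

#' @rdname criteria
#' @export
loo_is <- function(ll, truncate = TRUE) {
  stopifnot(nrow(ll) >= 2)
  K <- nrow(ll)
  res <- apply(ll, 2, function(col) {
    lw <- -col                     # reciprocal-density importance weights
    if (truncate) lw <- pmin(lw, logmeanexp(lw) + 0.5 * log(K))
    lw_norm <- lw - logsumexp(lw)
    c(est = logsumexp(col + lw) - logsumexp(lw), maxw = max(exp(lw_norm)))
  })
  flagged <- which(res["maxw", ] > 0.5)
  LPPD_loo <- sum(res["est", ])
  list(LOO = -2 * LPPD_loo, LPPD_loo = LPPD_loo, flagged = flagged)
}

#' All four criteria for one fit
#'
#' Convenience wrapper computing DIC3, LPML, WAIC and LOO-CV from a single
#' pointwise log-likelihood matrix.
#'
#' @param fit a `zab_fit` object.
#' @param ll optional precomputed [pointwise_loglik] matrix.
#' @param ... passed to [pointwise_loglik].
#' @return a one-row data frame of class `zab_criteria` with columns `DIC3`,
#'   `pD`, `LPML`, `WAIC`, `pWAIC2`, `LPPD`, `LOO`.
#' @export
zab_criteria <- function(fit, ll = NULL, ...) {
  if (is.null(ll)) ll <- pointwise_loglik(fit, ...)
  d <- dic3(ll, fit); l <- lpml(ll); w <- waic(ll); o <- loo_is(ll)
  out <- data.frame(DIC3 = d$DIC3, pD = d$pD, LPML = l$LPML,
                    WAIC = w$WAIC, pWAIC2 = w$pWAIC2, LPPD = w$LPPD,
                    LOO = o$LOO)
  class(out) <- c("zab_criteria", "data.frame")
  out
}
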