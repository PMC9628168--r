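#' Link functions of the two-part model
#'
#' Part I uses a logit link for the probability \eqn{\tau} that the response
#' is positive; Part II uses a log link for the conditional mean \eqn{\mu} of
#' the positive response.
#'
#' @param eta linear predictor value(s).
#' @return `zero_prob` the probability in (0,1); `positive_mean` the positive
#'   conditional mean.
#' @examples
#' zero_prob(0)           # 0.5
#' 1 - zero_prob(1.645)   # ~0.16: probability of a zero response
#' positive_mean(0.22)    # ~1.25-fold mean
#' @name links
NULL

# linear predictors are capped before exponentiation; exp(40) ~ 2e17 is far
# beyond any plausible conditional mean and keeps downstream lgamma finite
ETA_CAP <- 40

#' @rdname links
#' @export
zero_prob <- function(eta) {
  stats::plogis(eta)
}

#' @rdname links
#' @export
positive_mean <- function(eta) {
  if (any(abs(eta) > ETA_CAP, na.rm = TRUE)) {
    warning("linear predictor capped at +/-", ETA_CAP, " before exponentiation")
    eta <- pmin(pmax(eta, -ETA_CAP), ETA_CAP)
  }
  exp(eta)
}

#' Linear predictors of both model parts
#'
#' \eqn{\eta_1 = X_1\alpha + p_{1,i} + c_{1,ij}} and
#' \eqn{\eta_2 = X_2\beta + p_{2,i} + c_{2,ij}}, with the random-effect
#' contribution of any omitted level treated as zero.
#'
#' @param data a [zab_data] object.
#' @param alpha,beta fixed-effect coefficient vectors (lengths `ncol(X1)`,
#'   `ncol(X2)`).
#' @param p1,p2 level-3 random effects (length `n_prov`), or `NULL`.
#' @param c1,c2 level-2 random effects (length `n_city`), or `NULL`.
#' @return list with per-subject vectors `eta1`, `eta2`.
#' @export
linear_predictors <- function(data, alpha, beta, p1 = NULL, p2 = NULL,
                              c1 = NULL, c2 = NULL) {
  stopifnot(inherits(data, "zab_data"))
  if (length(alpha) != ncol(data$X1))
    stop("length(alpha) must equal ncol(X1)", call. = FALSE)
  if (length(beta) != ncol(data$X2))
    stop("length(beta) must equal ncol(X2)", call. = FALSE)
  re_at <- function(v, idx, n) {
    if (is.null(v)) return(0)
    if (length(v) != n) stop("random-effect vector of wrong length", call. = FALSE)
    v[idx]
  }
  eta1 <- drop(data$X1 %*% alpha) +
    re_at(p1, data$prov, data$n_prov) + re_at(c1, data$city, data$n_city)
  eta2 <- drop(data$X2 %*% beta) +
    re_at(p2, data$prov, data$n_prov) + re_at(c2, data$city, data$n_city)
  list(eta1 = eta1, eta2 = eta2)
}

# tau is bounded away from {0,1} so that log() never produces NaN from
# rounding; mismatched degenerate cases still return -Inf via log(TAU_EPS)
TAU_EPS <- 1e-12

#' Component log-likelihoods and the hurdle mixture density
#'
#' `binary_loglik` is the Bernoulli log-likelihood of the zero/positive
#' indicators; `continuous_loglik` is the positive-part log-likelihood, where
#' subjects with a zero response contribute nothing; `mixture_logpdf` is the
#' per-subject log of the hurdle density
#' \eqn{(1-\tau)^{1-\omega} [\tau f(y \mid \mu, \psi)]^{\omega}}.
#'
#' @param omega 0/1 indicators of a positive response.
#' @param tau per-subject probabilities of a positive response.
#' @param y non-negative responses.
#' @param mu per-subject positive-part means.
#' @param psi positive precision (beta-prime) or shape (gamma).
#' @param family `"bp"` or `"gamma"`.
#' @return `binary_loglik`, `continuous_loglik`: a single number (possibly
#'   `-Inf`); `mixture_logpdf`: a per-subject vector.
#' @name loglik
NULL

#' @rdname loglik
#' @export
binary_loglik <- function(omega, tau) {
  tau <- pmin(pmax(tau, TAU_EPS), 1 - TAU_EPS)
  sum(omega * log(tau) + (1 - omega) * log1p(-tau))
}

#' @rdname loglik
#' @export
continuous_loglik <- function(y, omega, mu, psi, family = "bp") {
  if (any((y > 0) != (omega == 1)))
    stop("omega inconsistent with I(y > 0)", call. = FALSE)
  pos <- omega == 1
  if (!any(pos)) return(0)
  mu_pos <- if (length(mu) == 1L) mu else mu[pos]
  sum(family_logpdf(y[pos], mu_pos, psi, family))
}

#' @rdname loglik
#' @export
mixture_logpdf <- function(y, tau, mu, psi, family = "bp") {
  if (any(y < 0)) stop("'y' must be non-negative", call. = FALSE)
  tau <- pmin(pmax(tau, TAU_EPS), 1 - TAU_EPS)
  n <- length(y)
  tau <- rep_len(tau, n); mu <- rep_len(mu, n)
  out <- log1p(-tau)
  pos <- y > 0
  if (any(pos))
    out[pos] <- log(tau[pos]) + family_logpdf(y[pos], mu[pos], psi, family)
  out
}

# log density of Inverse-Wishart(Omega, nu) at 2x2 PD matrix S
dinvwishart_log <- function(S, Omega, nu) {
  p <- 2
  detS <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  if (!is.finite(detS) || detS <= 0 || S[1, 1] <= 0) return(-Inf)
  detO <- Omega[1, 1] * Omega[2, 2] - Omega[1, 2] * Omega[2, 1]
  Sinv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2, 2) / detS
  lmvgamma <- lgamma(nu / 2) + lgamma((nu - 1) / 2) + 0.5 * log(pi)
  (nu / 2) * log(detO) - (nu * p / 2) * log(2) - lmvgamma -
    ((nu + p + 1) / 2) * log(detS) - 0.5 * sum(diag(Omega %*% Sinv))
}

dinvgamma_log <- function(x, a, b) {
  if (x <= 0) return(-Inf)
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

# log N(0, Sigma) density summed over rows of the n x 2 matrix U
dmvnorm0_log <- function(U, Sigma) {
  det <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2] * Sigma[2, 1]
  if (!is.finite(det) || det <= 0 || Sigma[1, 1] <= 0) return(-Inf)
  Sinv <- matrix(c(Sigma[2, 2], -Sigma[1, 2], -Sigma[2, 1], Sigma[1, 1]), 2, 2) / det
  q <- rowSums((U %*% Sinv) * U)
  sum(-log(2 * pi) - 0.5 * log(det) - 0.5 * q)
}

#' Log prior density
#'
#' Sum of the independent log prior densities of all sampled parameters under
#' a [zab_priors] specification: normal coefficients, gamma or inverse-gamma
#' `psi`, inverse-Wishart level covariances (correlated mode) or
#' inverse-gamma level variances plus a beta `tau` (reduced mode). Returns
#' `-Inf` for states outside the support (e.g. a non-positive-definite
#' covariance).
#'
#' @param alpha,beta coefficient vectors (`alpha` ignored when
#'   `model$constant_tau`).
#' @param psi positive dispersion parameter.
#' @param Sigma1,Sigma2 2x2 covariance matrices (correlated mode).
#' @param sigma2_p,sigma2_c level variances (independent mode).
#' @param tau constant probability of a positive response (reduced mode).
#' @param priors a [zab_priors] object.
#' @param model a [zab_model] object.
#' @return a single number, finite or `-Inf`.
#' @export
log_prior <- function(alpha = NULL, beta, psi, Sigma1 = NULL, Sigma2 = NULL,
                      sigma2_p = NULL, sigma2_c = NULL, tau = NULL,
                      priors, model) {
  lp <- 0
  if (!model$constant_tau && length(alpha))
    lp <- lp + sum(stats::dnorm(alpha, 0, sqrt(priors$alpha_var), log = TRUE))
  lp <- lp + sum(stats::dnorm(beta, 0, sqrt(priors$beta_var), log = TRUE))
  lp <- lp + if (priors$psi_prior == "gamma")
    stats::dgamma(psi, shape = priors$psi_a, rate = priors$psi_b, log = TRUE)
  else dinvgamma_log(psi, priors$psi_a, priors$psi_b)
  if (model$constant_tau) {
    if (is.null(tau) || tau <= 0 || tau >= 1) return(-Inf)
    lp <- lp + stats::dbeta(tau, priors$tau_a, priors$tau_b, log = TRUE)
  }
  if (model$correlated_re) {
    if (model$include_level3)
      lp <- lp + dinvwishart_log(Sigma1, priors$Omega1, priors$nu1)
    if (model$include_level2)
      lp <- lp + dinvwishart_log(Sigma2, priors$Omega2, priors$nu2)
  } else {
    if (model$include_level3)
      lp <- lp + dinvgamma_log(sigma2_p, priors$sigma2_a, priors$sigma2_b)
    if (model$include_level2)
      lp <- lp + dinvgamma_log(sigma2_c, priors$sigma2_a, priors$sigma2_b)
  }
  lp
}

#' Unnormalized joint log posterior (conditional on random effects)
#'
#' The MCMC target: data log-likelihood (binary + continuous part) plus the
#' normal log-density of the random effects given the level covariances plus
#' [log_prior]. Random effects are sampled rather than integrated out, so
#' this is the integrand of the marginal posterior.
#'
#' @param data a [zab_data] object.
#' @param state named list with elements `alpha`, `beta`, `psi`, and — as the
#'   model requires — `tau`, `p1`, `p2`, `c1`, `c2`, `Sigma1`, `Sigma2`,
#'   `sigma2_p`, `sigma2_c`.
#' @param priors a [zab_priors] object.
#' @param model a [zab_model] object.
#' @return a single number, finite or `-Inf`.
#' @export
log_posterior_conditional <- function(data, state, priors, model) {
  s <- state
  lp <- log_prior(alpha = s$alpha, beta = s$beta, psi = s$psi,
                  Sigma1 = s$Sigma1, Sigma2 = s$Sigma2,
                  sigma2_p = s$sigma2_p, sigma2_c = s$sigma2_c,
                  tau = s$tau, priors = priors, model = model)
  if (!is.finite(lp)) return(-Inf)
  # random-effect log-densities
  if (model$correlated_re) {
    if (model$include_level3)
      lp <- lp + dmvnorm0_log(cbind(s$p1, s$p2), s$Sigma1)
    if (model$include_level2)
      lp <- lp + dmvnorm0_log(cbind(s$c1, s$c2), s$Sigma2)
  } else {
    if (model$include_level3)
      lp <- lp + sum(stats::dnorm(s$p2, 0, sqrt(s$sigma2_p), log = TRUE))
    if (model$include_level2)
      lp <- lp + sum(stats::dnorm(s$c2, 0, sqrt(s$sigma2_c), log = TRUE))
  }
  if (!is.finite(lp)) return(-Inf)
  if (data$N == 0L) return(lp)
  eta <- linear_predictors(data,
    alpha = if (model$constant_tau) rep(0, ncol(data$X1)) else s$alpha,
    beta = s$beta,
    p1 = if (model$correlated_re && model$include_level3) s$p1 else NULL,
    p2 = if (model$include_level3) s$p2 else NULL,
    c1 = if (model$correlated_re && model$include_level2) s$c1 else NULL,
    c2 = if (model$include_level2) s$c2 else NULL)
  tau <- if (model$constant_tau) rep(s$tau, data$N) else zero_prob(eta$eta1)
  mu <- positive_mean(eta$eta2)
  lp + binary_loglik(data$omega, tau) +
    continuous_loglik(data$y, data$omega, mu, s$psi, model$family)
}
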