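#' Simulation-study design
#'
#' The reduced three-level design of the estimator-evaluation study: a
#' constant probability `tau` of a positive response, a single Bernoulli(0.8)
#' covariate, independent scalar random effects per level entering the
#' positive mean only, and a beta-prime or gamma positive part. Stated
#' defaults: `beta0 = 2`, `beta1 = 1.5`, `tau = 0.2`, `sigma2_p = 1.8`,
#' `sigma2_c = 2.3`, and `psi = 0.1` for the beta-prime family or `psi = 1`
#' for the gamma family. The design does not state the number of level-2
#' units per level-3 unit or subjects per level-2 unit; the package fixes
#' `n_i = 2` and `m_ij = 5` (so `n` level-3 units give `10 n` subjects),
#' both configurable.
#'
#' @param family `"bp"` or `"gamma"`.
#' @param n number of level-3 units ("sample size" of the study).
#' @param n_i level-2 units per level-3 unit.
#' @param m_ij subjects per level-2 unit.
#' @param beta0,beta1 intercept and slope of the positive-mean predictor.
#' @param tau constant probability of a positive response.
#' @param sigma2_p,sigma2_c level-3 and level-2 random-effect variances.
#' @param psi positive-part precision (beta-prime) or shape (gamma); default
#'   0.1 for `"bp"`, 1 for `"gamma"`.
#' @param x_prob success probability of the Bernoulli covariate.
#' @return object of class `zab_sim_design`.
#' @export
sim_design <- function(family = c("bp", "gamma"), n = 100, n_i = 2, m_ij = 5,
                       beta0 = 2, beta1 = 1.5, tau = 0.2,
                       sigma2_p = 1.8, sigma2_c = 2.3,
                       psi = NULL, x_prob = 0.8) {
  family <- match.arg(family)
  if (is.null(psi)) psi <- if (family == "bp") 0.1 else 1
  stopifnot(n >= 1, n_i >= 1, m_ij >= 1, tau > 0, tau < 1,
            sigma2_p > 0, sigma2_c > 0, psi > 0, x_prob > 0, x_prob < 1)
  structure(list(family = family, n = as.integer(n), n_i = as.integer(n_i),
                 m_ij = as.integer(m_ij), beta0 = beta0, beta1 = beta1,
                 tau = tau, sigma2_p = sigma2_p, sigma2_c = sigma2_c,
                 psi = psi, x_prob = x_prob),
            class = "zab_sim_design")
}

#' Generate a dataset from the simulation-study design
#'
#' Draws `p_i ~ N(0, sigma2_p)` per level-3 unit, `c_ij ~ N(0, sigma2_c)`
#' per level-2 unit, the covariate `x ~ Bernoulli(x_prob)` per subject,
#' occurrence `omega ~ Bernoulli(tau)`, and — for subjects with `omega = 1` —
#' a positive response from the design family with mean
#' `exp(beta0 + beta1 x + p_i + c_ij)` and dispersion `psi`; all other
#' responses are exactly 0.
#'
#' @param design a [sim_design] object.
#' @param seed integer seed; the same design and seed reproduce the dataset
#'   bitwise.
#' @return list with `data` (a [zab_data]) and `truth` (the generating
#'   parameter values and random-effect draws).
#' @export
simulate_sim_design <- function(design, seed) {
  stopifnot(inherits(design, "zab_sim_design"))
  set.seed(as.integer(seed))
  d <- design
  n_city <- d$n * d$n_i
  N <- n_city * d$m_ij
  prov_of_city <- rep(seq_len(d$n), each = d$n_i)
  city <- rep(seq_len(n_city), each = d$m_ij)
  prov <- prov_of_city[city]
  p <- stats::rnorm(d$n, 0, sqrt(d$sigma2_p))
  cc <- stats::rnorm(n_city, 0, sqrt(d$sigma2_c))
  x <- stats::rbinom(N, 1, d$x_prob)
  omega <- stats::rbinom(N, 1, d$tau)
  eta2 <- d$beta0 + d$beta1 * x + p[prov] + cc[city]
  y <- numeric(N)
  pos <- omega == 1
  if (any(pos))
    y[pos] <- family_sample(sum(pos), exp(pmin(eta2[pos], 40)), d$psi, d$family)
  df <- data.frame(province = prov, city = city, y = y, x = x)
  data <- zab_data(df, response = "y", level3 = "province", level2 = "city",
                   mean_covariates = "x")
  truth <- list(family = d$family, beta0 = d$beta0, beta1 = d$beta1,
                tau = d$tau, sigma2_p = d$sigma2_p, sigma2_c = d$sigma2_c,
                psi = d$psi, p = p, c = cc, seed = as.integer(seed))
  list(data = data, truth = truth)
}

#' Survey-like three-level design
#'
#' Emulates the structure of the withheld pharmaceutical-expenditure survey:
#' 31 level-3 units, 429 level-2 units, six covariates (four continuous, one
#' count-like, one binary) entering both model parts, correlated bivariate
#' random effects per level, a target fraction of exactly-zero responses
#' (default 16.1%) and a heavy right tail in the positive part. The
#' covariate laws are fixed, documented stand-ins (log-normal expenditure
#' totals and insurance coverage, shifted-Poisson counts, truncated-normal
#' age, Bernoulli sex); no attempt is made to match the survey's descriptive
#' moments beyond the zero fraction.
#'
#' @param n_prov number of level-3 units.
#' @param n_city number of level-2 units (spread as evenly as possible).
#' @param m subjects per level-2 unit.
#' @param family `"bp"` or `"gamma"`.
#' @param zero_fraction target expected proportion of zero responses.
#' @param alpha,beta covariate coefficients for Parts I and II (the Part I
#'   intercept is solved so the expected zero fraction hits the target; the
#'   supplied `alpha[1]` is ignored).
#' @param Sigma1,Sigma2 2x2 level covariances.
#' @param psi positive-part dispersion (small values give a heavy tail under
#'   the beta-prime family).
#' @return object of class `zab_pe_design`.
#' @export
pe_like_design <- function(n_prov = 31, n_city = 429, m = 10,
                           family = "bp", zero_fraction = 0.161,
                           alpha = c(0, 0.1, -0.01, -0.2),
                           beta = c(-1, 0.02, -0.01, -0.04, 0.2, 0.005, -0.1),
                           Sigma1 = matrix(c(0.15, -0.004, -0.004, 0.05), 2, 2),
                           Sigma2 = matrix(c(0.4, -0.05, -0.05, 0.6), 2, 2),
                           psi = 0.5) {
  stopifnot(n_city >= n_prov, zero_fraction > 0, zero_fraction < 1,
            length(alpha) == 4, length(beta) == 7, psi > 0)
  for (S in list(Sigma1, Sigma2))
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("level covariance must be positive definite", call. = FALSE)
  structure(list(n_prov = as.integer(n_prov), n_city = as.integer(n_city),
                 m = as.integer(m), family = family,
                 zero_fraction = zero_fraction, alpha = alpha, beta = beta,
                 Sigma1 = Sigma1, Sigma2 = Sigma2, psi = psi),
            class = "zab_pe_design")
}

#' Generate a survey-like dataset
#'
#' Full two-part generation under [pe_like_design]: covariate-dependent
#' occurrence and positive mean, correlated bivariate random effects per
#' level. The Part I intercept is solved numerically (given the realized
#' covariates and random effects) so the expected zero fraction equals the
#' target.
#'
#' @param design a [pe_like_design] object.
#' @param seed integer seed.
#' @return list with `data` (a [zab_data]) and `truth`.
#' @export
simulate_pe_like <- function(design, seed) {
  stopifnot(inherits(design, "zab_pe_design"))
  set.seed(as.integer(seed))
  d <- design
  # spread cities over provinces as evenly as possible
  prov_of_city <- sort(rep_len(seq_len(d$n_prov), d$n_city))
  N <- d$n_city * d$m
  city <- rep(seq_len(d$n_city), each = d$m)
  prov <- prov_of_city[city]
  rmvn0 <- function(n, S) matrix(stats::rnorm(2 * n), n, 2) %*% chol(S)
  P <- rmvn0(d$n_prov, d$Sigma1)
  C <- rmvn0(d$n_city, d$Sigma2)
  covs <- data.frame(
    total = round(stats::rlnorm(N, meanlog = 1.5, sdlog = 1.2), 2),
    icpd = round(stats::rlnorm(N, meanlog = 1.0, sdlog = 0.8), 2),
    ndpp = stats::rpois(N, 2) + 1L,
    nop = stats::rpois(N, 3) + 1L,
    age = round(pmin(pmax(stats::rnorm(N, 42, 16), 1), 95), 1),
    sex = stats::rbinom(N, 1, 0.42))
  X1c <- as.matrix(covs[c("ndpp", "age", "sex")])
  X2c <- as.matrix(covs)
  eta1_rest <- drop(X1c %*% d$alpha[-1]) + P[prov, 1] + C[city, 1]
  # expected zero fraction as a function of the Part I intercept, given the
  # realized covariates and random effects
  f <- function(a0) mean(1 - stats::plogis(a0 + eta1_rest)) - d$zero_fraction
  if (f(-30) < 0 || f(30) > 0)
    stop("zero-fraction target unattainable for these settings", call. = FALSE)
  a0 <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  alpha <- c(a0, d$alpha[-1])
  tau <- stats::plogis(a0 + eta1_rest)
  eta2 <- d$beta[1] + drop(X2c %*% d$beta[-1]) + P[prov, 2] + C[city, 2]
  omega <- stats::rbinom(N, 1, tau)
  y <- numeric(N)
  pos <- omega == 1
  if (any(pos))
    y[pos] <- family_sample(sum(pos), exp(pmin(eta2[pos], 40)), d$psi, d$family)
  df <- cbind(data.frame(province = prov, city = city, y = y), covs)
  data <- zab_data(df, response = "y", level3 = "province", level2 = "city",
                   zero_covariates = c("ndpp", "age", "sex"),
                   mean_covariates = names(covs))
  truth <- list(family = d$family, alpha = alpha, beta = d$beta,
                Sigma1 = d$Sigma1, Sigma2 = d$Sigma2, psi = d$psi,
                p1 = P[, 1], p2 = P[, 2], c1 = C[, 1], c2 = C[, 2],
                zero_fraction = d$zero_fraction, seed = as.integer(seed))
  list(data = data, truth = truth)
}
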