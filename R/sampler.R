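#' MCMC settings
#'
#' Defaults mirror the published analysis at a reduced, desk-scale schedule
#' (2 chains of 20,000 iterations, burn-in 10,000, thinning 10). The full
#' published schedule (2 chains of 200,000, burn-in 100,000, lag 100) is
#' available by overriding these values.
#'
#' @param n_chains number of independent chains (>= 1; 2 to enable R-hat).
#' @param n_iter iterations per chain.
#' @param n_burnin burn-in iterations discarded per chain (`< n_iter`).
#' @param thin thinning lag (>= 1).
#' @param seed integer master seed; chain `k` uses `seed + k - 1`.
#' @param adapt adapt proposal scales during burn-in (Robbins-Monro toward
#'   `target`), frozen afterwards.
#' @param target target acceptance rate for adapted random-walk blocks.
#' @param s_alpha,s_beta,s_psi,s_p,s_c initial proposal standard deviations
#'   per block.
#' @return object of class `zab_control`.
#' @export
zab_control <- function(n_chains = 2, n_iter = 20000, n_burnin = 10000,
                        thin = 10, seed = 1, adapt = TRUE, target = 0.35,
                        s_alpha = 0.1, s_beta = 0.1, s_psi = 0.2,
                        s_p = 0.3, s_c = 0.3) {
  stopifnot(n_chains >= 1, n_iter > n_burnin, n_burnin >= 0, thin >= 1,
            target > 0, target < 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), adapt = isTRUE(adapt),
                 target = target, s_alpha = s_alpha, s_beta = s_beta,
                 s_psi = s_psi, s_p = s_p, s_c = s_c),
            class = "zab_control")
}

# crude two-stage starting values: logistic regression for Part I, log-linear
# least squares on the positive subset for Part II, method-of-moments psi
zab_init <- function(data, model) {
  pos <- data$omega == 1
  beta <- rep(0, ncol(data$X2))
  if (sum(pos) > ncol(data$X2)) {
    fit <- tryCatch(stats::lm.fit(data$X2[pos, , drop = FALSE], log(data$y[pos])),
                    error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$coefficients)))
      beta <- fit$coefficients
  }
  alpha <- rep(0, ncol(data$X1))
  if (!model$constant_tau && data$N > 0) {
    fit <- tryCatch(suppressWarnings(
      stats::glm.fit(data$X1, data$omega, family = stats::binomial())),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$coefficients)))
      alpha <- pmin(pmax(fit$coefficients, -5), 5)
  }
  psi <- 1
  if (sum(pos) > 2) {
    m <- mean(data$y[pos]); v <- stats::var(data$y[pos])
    psi <- if (model$family == "bp") m * (1 + m) / v else m^2 / v
    psi <- min(max(psi, 1e-2), 1e3)
  }
  tau <- min(max(mean(data$omega), 0.05), 0.95)
  if (data$N == 0L) tau <- 0.5
  list(alpha = alpha, beta = beta, psi = psi, tau = tau)
}

#' Fit a zero-augmented multilevel two-part model by MCMC
#'
#' Runs Metropolis-within-Gibbs for the two-part model described in
#' [zab_model]: componentwise random-walk Metropolis for the coefficient
#' blocks, per-cluster (bivariate, in correlated mode) random-walk Metropolis
#' for the random effects, log-scale Metropolis for `psi`, and conjugate
#' Gibbs draws for the variance components (inverse-Wishart for the level
#' covariances, inverse-gamma for independent level variances, Beta for a
#' constant `tau`). Chains are initialized from crude two-stage estimates
#' jittered independently per chain ("widely dispersed" starts).
#'
#' @param data a [zab_data] object.
#' @param model a [zab_model] object.
#' @param priors a [zab_priors] object; defaults to [zab_priors_sim()] when
#'   `model$constant_tau`, [zab_priors()] otherwise.
#' @param control a [zab_control] object.
#' @return An object of class `zab_fit` with per-chain draw matrices
#'   (`$draws`, scalar parameters, columns named), per-chain random-effect
#'   draw matrices (`$re`), acceptance rates, and the inputs.
#' @export
zab_fit <- function(data, model, priors = NULL, control = zab_control()) {
  stopifnot(inherits(data, "zab_data"), inherits(model, "zab_model"),
            inherits(control, "zab_control"))
  if (is.null(priors))
    priors <- if (model$constant_tau) zab_priors_sim() else zab_priors()
  stopifnot(inherits(priors, "zab_priors"))

  has_p <- model$include_level3 && data$n_prov > 0
  has_c <- model$include_level2 && data$n_city > 0
  init0 <- zab_init(data, model)

  prior_list <- list(
    alpha_var = priors$alpha_var, beta_var = priors$beta_var,
    psi_gamma = priors$psi_prior == "gamma",
    psi_a = priors$psi_a, psi_b = priors$psi_b,
    Omega1 = priors$Omega1, nu1 = priors$nu1,
    Omega2 = priors$Omega2, nu2 = priors$nu2,
    sigma2_a = priors$sigma2_a, sigma2_b = priors$sigma2_b,
    tau_a = priors$tau_a, tau_b = priors$tau_b)

  ctrl_list <- list(n_iter = control$n_iter, n_burnin = control$n_burnin,
                    thin = control$thin, adapt = control$adapt,
                    target = control$target,
                    s_alpha = control$s_alpha, s_beta = control$s_beta,
                    s_psi = control$s_psi, s_p = control$s_p, s_c = control$s_c)

  chains <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    set.seed(control$seed + ch - 1L)
    jit <- function(x, s) x + stats::rnorm(length(x), 0, s)
    init <- list(
      alpha = if (model$constant_tau) numeric(0) else jit(init0$alpha, 0.25),
      beta = jit(init0$beta, 0.25),
      psi = init0$psi * exp(stats::rnorm(1, 0, 0.3)),
      tau = stats::plogis(stats::qlogis(init0$tau) + stats::rnorm(1, 0, 0.3)),
      p1 = rep(0, max(data$n_prov, 1)), p2 = rep(0, max(data$n_prov, 1)),
      c1 = rep(0, max(data$n_city, 1)), c2 = rep(0, max(data$n_city, 1)),
      Sigma1 = diag(0.1, 2), Sigma2 = diag(0.1, 2),
      sigma2_p = 0.1, sigma2_c = 0.1)
    raw <- zab_mcmc_cpp(
      y = data$y, omega = data$omega,
      X1 = data$X1, X2 = data$X2,
      prov = data$prov - 1L, city = data$city - 1L,
      city_prov = data$city_prov - 1L,
      n_prov = data$n_prov, n_city = data$n_city,
      family = if (model$family == "bp") 0L else 1L,
      constant_tau = model$constant_tau,
      correlated_re = model$correlated_re,
      has_p = has_p, has_c = has_c,
      priors = prior_list, init = init, control = ctrl_list)
    chains[[ch]] <- raw
  }

  # assemble named scalar-parameter draw matrices per chain
  par_mat <- function(raw) {
    cols <- list()
    if (!model$constant_tau) {
      a <- raw$alpha; colnames(a) <- paste0("alpha_", colnames(data$X1))
      cols <- c(cols, list(a))
    }
    b <- raw$beta; colnames(b) <- paste0("beta_", colnames(data$X2))
    cols <- c(cols, list(b))
    if (model$constant_tau)
      cols <- c(cols, list(matrix(raw$tau, ncol = 1, dimnames = list(NULL, "tau"))))
    cols <- c(cols, list(matrix(raw$psi, ncol = 1, dimnames = list(NULL, "psi"))))
    if (has_p) {
      if (model$correlated_re) {
        s <- raw$Sigma1
        colnames(s) <- c("Sigma1[1,1]", "Sigma1[1,2]", "Sigma1[2,2]")
        cols <- c(cols, list(s))
      } else {
        cols <- c(cols, list(matrix(raw$sigma2_p, ncol = 1,
                                    dimnames = list(NULL, "sigma2_p"))))
      }
    }
    if (has_c) {
      if (model$correlated_re) {
        s <- raw$Sigma2
        colnames(s) <- c("Sigma2[1,1]", "Sigma2[1,2]", "Sigma2[2,2]")
        cols <- c(cols, list(s))
      } else {
        cols <- c(cols, list(matrix(raw$sigma2_c, ncol = 1,
                                    dimnames = list(NULL, "sigma2_c"))))
      }
    }
    do.call(cbind, cols)
  }
  draws <- lapply(chains, par_mat)
  re <- lapply(chains, function(raw)
    list(p1 = raw$p1, p2 = raw$p2, c1 = raw$c1, c2 = raw$c2))
  accept <- lapply(chains, `[[`, "accept")

  structure(list(draws = draws, re = re, accept = accept,
                 data = data, model = model, priors = priors,
                 control = control, has_p = has_p, has_c = has_c),
            class = "zab_fit")
}

#' @export
print.zab_fit <- function(x, ...) {
  cat("zab_fit:", toupper(x$model$family), "family,",
      length(x$draws), "chain(s),", nrow(x$draws[[1]]), "retained draws each\n")
  print(summary(x))
  invisible(x)
}

# pooled draw matrix across chains
pooled_draws <- function(fit) do.call(rbind, fit$draws)

#' Split-chain Gelman-Rubin statistic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so that within-chain trends also register. Values near 1 indicate
#' convergence.
#'
#' @param x a `zab_fit` object or a list of numeric vectors (one per chain).
#' @param param parameter name when `x` is a `zab_fit`.
#' @return a single number `>= 1` (up to floating point).
#' @export
gelman_rubin <- function(x, param = NULL) {
  if (inherits(x, "zab_fit")) {
    if (length(x$draws) < 2L)
      stop("at least 2 chains are required; refit with n_chains >= 2 ",
           "(split-chain R-hat still needs multiple chains here)", call. = FALSE)
    chains <- lapply(x$draws, function(m) m[, param])
  } else {
    chains <- x
    if (!is.list(chains) || length(chains) < 2L)
      stop("supply a list of >= 2 chains", call. = FALSE)
  }
  n <- min(lengths(chains))
  if (n < 10L) stop("need at least 10 draws per chain", call. = FALSE)
  half <- floor(n / 2)
  seqs <- unlist(lapply(chains, function(v)
    list(v[seq_len(half)], v[(half + 1):(2 * half)])), recursive = FALSE)
  m <- length(seqs)
  means <- vapply(seqs, mean, 0)
  vars <- vapply(seqs, stats::var, 0)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W < 1e-300) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Posterior summary table
#'
#' Pooled-chain posterior mean, standard deviation and equal-tail 95%
#' credible interval per scalar parameter, plus split-chain R-hat (when >= 2
#' chains) and a significance flag: an effect is flagged when its 95%
#' equal-tail credible interval excludes zero.
#'
#' @param object a `zab_fit` object.
#' @param prob interval mass (default 0.95, i.e. the 2.5% and 97.5%
#'   percentiles).
#' @param ... unused.
#' @return a data frame of class `zab_summary` with columns `mean`, `sd`,
#'   `q2.5`, `q97.5`, `rhat`, `signif`.
#' @export
summary.zab_fit <- function(object, prob = 0.95, ...) {
  pool <- pooled_draws(object)
  lo <- (1 - prob) / 2
  qs <- t(apply(pool, 2, stats::quantile, probs = c(lo, 1 - lo), names = FALSE))
  rhat <- if (length(object$draws) >= 2L)
    vapply(colnames(pool), function(p) gelman_rubin(object, p), 0)
  else rep(NA_real_, ncol(pool))
  out <- data.frame(
    parameter = colnames(pool),
    mean = colMeans(pool),
    sd = apply(pool, 2, stats::sd),
    q2.5 = qs[, 1], q97.5 = qs[, 2],
    rhat = rhat,
    signif = qs[, 1] > 0 | qs[, 2] < 0,
    row.names = NULL)
  class(out) <- c("zab_summary", "data.frame")
  out
}

#' @export
print.zab_summary <- function(x, digits = 3, ...) {
  y <- x
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  NextMethod(generic = "print", object = y)
  invisible(x)
}

#' Convergence rate across replicated fits
#'
#' Fraction of fits whose largest per-parameter split-chain R-hat falls below
#' a threshold (the "CR%" column of a simulation-study summary).
#'
#' @param fits a list of `zab_fit` / `zab_summary` objects, or a numeric
#'   vector of per-fit maximum R-hat values.
#' @param threshold convergence threshold on R-hat (default 1.1).
#' @return a proportion in \[0, 1\].
#' @export
convergence_rate <- function(fits, threshold = 1.1) {
  max_rhat <- function(f) {
    if (is.numeric(f)) return(f)
    if (inherits(f, "zab_fit")) f <- summary(f)
    max(f$rhat, na.rm = TRUE)
  }
  vals <- if (is.numeric(fits)) fits else vapply(fits, max_rhat, 0)
  mean(vals < threshold)
}
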