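test_that("links: values, monotonicity, published round-offs", {
  expect_equal(zero_prob(0), 0.5)
  expect_equal(positive_mean(0), 1)
  # probability of a zero response at the reported zero-part coefficients
  expect_equal(round(1 - zero_prob(1.645), 2), 0.16)
  expect_equal(round(1 - zero_prob(1.645 - 0.183), 2), 0.19)
  expect_equal(positive_mean(0.22), exp(0.22))
  g <- seq(-5, 5, by = 0.25)
  expect_true(all(diff(zero_prob(g)) > 0))
  expect_true(all(diff(positive_mean(g)) > 0))
  expect_warning(positive_mean(100), "capped")
})

test_that("linear predictors agree with a per-subject loop", {
  dat <- small_sim(seed = 3, n = 3)$data
  st <- random_state(dat, NULL, seed = 11)
  eta <- linear_predictors(dat, st$alpha, st$beta, st$p1, st$p2, st$c1, st$c2)
  for (k in seq_len(dat$N)) {
    e1 <- sum(dat$X1[k, ] * st$alpha) + st$p1[dat$prov[k]] + st$c1[dat$city[k]]
    e2 <- sum(dat$X2[k, ] * st$beta) + st$p2[dat$prov[k]] + st$c2[dat$city[k]]
    expect_equal(eta$eta1[k], e1)
    expect_equal(eta$eta2[k], e2)
  }
  # zero coefficients and REs give zero predictors
  z <- linear_predictors(dat, rep(0, ncol(dat$X1)), rep(0, ncol(dat$X2)))
  expect_equal(z$eta1, rep(0, dat$N))
  expect_equal(z$eta2, rep(0, dat$N))
  expect_error(linear_predictors(dat, c(1, 2, 3), st$beta), "alpha")
})

test_that("binary log-likelihood matches the per-term Bernoulli sum", {
  expect_equal(binary_loglik(c(1, 0), c(0.5, 0.5)), 2 * log(0.5))
  # degenerate consistent limit contributes ~0
  expect_equal(binary_loglik(c(1, 0), c(1 - 1e-14, 1e-14)), 0, tolerance = 1e-10)
  set.seed(8)
  om <- rbinom(20, 1, 0.5); tau <- runif(20, 0.05, 0.95)
  oracle <- sum(vapply(1:20, function(i)
    stats::dbinom(om[i], 1, tau[i], log = TRUE), 0))
  expect_equal(binary_loglik(om, tau), oracle, tolerance = 1e-12)
})

test_that("continuous log-likelihood: zeros contribute nothing", {
  expect_equal(continuous_loglik(c(0, 0), c(0, 0), mu = 1, psi = 1), 0)
  expect_equal(continuous_loglik(c(0, 1), c(0, 1), mu = c(9, 1), psi = 1),
               dbprime(1, 1, 1, log = TRUE))
  expect_error(continuous_loglik(c(0, 1), c(0, 0), mu = 1, psi = 1),
               "inconsistent")
})

test_that("mixture log-density composes the parts and stays normalized", {
  expect_equal(mixture_logpdf(0, tau = 0.2, mu = 1, psi = 1), log(0.8))
  expect_equal(mixture_logpdf(1, tau = 0.5, mu = 1, psi = 1),
               log(0.5) + dbprime(1, 1, 1, log = TRUE))
  expect_error(mixture_logpdf(-1, 0.5, 1, 1), "non-negative")
  for (tau in c(0.2, 0.7)) for (psi in c(0.8, 3)) {
    mass <- (1 - tau) + tau * stats::integrate(function(v)
      exp(mixture_logpdf(v, tau, mu = 1.4, psi = psi)) / tau, 0, Inf,
      rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-8)
  }
  # decomposition: sum of mixture terms = binary + continuous log-likelihood
  sim <- small_sim(seed = 21, n = 5)
  dat <- sim$data
  tau <- runif(dat$N, 0.1, 0.9); mu <- exp(rnorm(dat$N)); psi <- 0.7
  lhs <- sum(mixture_logpdf(dat$y, tau, mu, psi))
  rhs <- binary_loglik(dat$omega, tau) +
    continuous_loglik(dat$y, dat$omega, mu, psi)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("log prior: closed form for coefficients, support boundaries", {
  model <- zab_model("bp")
  priors <- zab_priors()
  st <- random_state(tiny_data(), model, seed = 2)
  lp <- log_prior(alpha = rep(0, 2), beta = rep(0, 2), psi = 1,
                  Sigma1 = diag(2), Sigma2 = diag(2),
                  priors = priors, model = model)
  manual <- 4 * stats::dnorm(0, 0, 100, log = TRUE) +
    zabp:::dinvgamma_log(1, 0.01, 0.01) +
    zabp:::dinvwishart_log(diag(2), diag(0.01, 2), 2) +
    zabp:::dinvwishart_log(diag(2), diag(0.01, 2), 2)
  expect_equal(lp, manual, tolerance = 1e-12)
  # non-positive-definite covariance is outside the support
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_identical(
    log_prior(alpha = rep(0, 2), beta = rep(0, 2), psi = 1,
              Sigma1 = bad, Sigma2 = diag(2), priors = priors, model = model),
    -Inf)
  # uniform tau contributes zero
  msim <- zab_model("bp", constant_tau = TRUE)
  lp1 <- log_prior(beta = 0.3, psi = 1, sigma2_p = 1, sigma2_c = 1,
                   tau = 0.37, priors = zab_priors_sim(), model = msim)
  lp2 <- log_prior(beta = 0.3, psi = 1, sigma2_p = 1, sigma2_c = 1,
                   tau = 0.81, priors = zab_priors_sim(), model = msim)
  expect_equal(lp1, lp2, tolerance = 1e-12)
})

test_that("joint log posterior decomposes into its components", {
  model <- zab_model("bp")
  priors <- zab_priors()
  for (seed in 1:3) {
    sim <- small_sim(seed = seed, n = 4)
    dat <- sim$data
    st <- random_state(dat, model, seed = seed + 100)
    lp <- log_posterior_conditional(dat, st, priors, model)
    prior_part <- log_prior(alpha = st$alpha, beta = st$beta, psi = st$psi,
                            Sigma1 = st$Sigma1, Sigma2 = st$Sigma2,
                            priors = priors, model = model)
    re_part <- zabp:::dmvnorm0_log(cbind(st$p1, st$p2), st$Sigma1) +
      zabp:::dmvnorm0_log(cbind(st$c1, st$c2), st$Sigma2)
    eta <- linear_predictors(dat, st$alpha, st$beta, st$p1, st$p2, st$c1, st$c2)
    mix <- sum(mixture_logpdf(dat$y, zero_prob(eta$eta1), exp(eta$eta2), st$psi))
    expect_equal(lp - prior_part - re_part, mix, tolerance = 1e-10)
  }
})

test_that("empty dataset: posterior equals prior plus RE terms", {
  model <- zab_model("bp", include_level3 = FALSE, include_level2 = FALSE)
  priors <- zab_priors()
  st <- list(alpha = c(0.2, -0.1), beta = c(0.5, 0.3), psi = 1.2)
  dat <- empty_data()
  lp <- log_posterior_conditional(dat, st, priors, model)
  expect_equal(lp, log_prior(alpha = st$alpha, beta = st$beta, psi = st$psi,
                             priors = priors, model = model))
})

test_that("adding a zero-response subject shifts the posterior by log(1 - tau)", {
  model <- zab_model("bp")
  priors <- zab_priors()
  df <- tiny_df()
  df2 <- rbind(df, data.frame(province = "B", city = "b2", y = 0, x = 1))
  d1 <- zab_data(df, "y", "province", "city", "x", "x")
  d2 <- zab_data(df2, "y", "province", "city", "x", "x")
  st <- random_state(d1, model, seed = 4)
  lp1 <- log_posterior_conditional(d1, st, priors, model)
  lp2 <- log_posterior_conditional(d2, st, priors, model)
  eta1_new <- sum(d2$X1[7, ] * st$alpha) + st$p1[d2$prov[7]] + st$c1[d2$city[7]]
  expect_equal(lp2 - lp1, log(1 - zero_prob(eta1_new)), tolerance = 1e-10)
})

test_that("response scaling is equivalent to pre-divided data", {
  df <- tiny_df()
  d1 <- zab_data(df, "y", "province", "city", "x", "x", response_scale = 100)
  df2 <- df; df2$y <- df2$y / 100
  d2 <- zab_data(df2, "y", "province", "city", "x", "x", response_scale = 1)
  model <- zab_model("bp"); priors <- zab_priors()
  st <- random_state(d1, model, seed = 9)
  expect_equal(log_posterior_conditional(d1, st, priors, model),
               log_posterior_conditional(d2, st, priors, model),
               tolerance = 1e-12)
})
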