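test_that("identical data, settings and seed give identical draws", {
  sim <- small_sim(seed = 13, n = 6)
  model <- zab_model("bp", constant_tau = TRUE)
  f1 <- zab_fit(sim$data, model, control = quick_control(seed = 3))
  f2 <- zab_fit(sim$data, model, control = quick_control(seed = 3))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$re, f2$re)
  f3 <- zab_fit(sim$data, model, control = quick_control(seed = 4))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("every stored draw has positive psi and positive-definite covariances", {
  sim <- simulate_pe_like(pe_like_design(n_prov = 5, n_city = 10, m = 6), seed = 2)
  fit <- zab_fit(sim$data, zab_model("bp"), control = quick_control(seed = 5))
  pool <- zabp:::pooled_draws(fit)
  expect_true(all(pool[, "psi"] > 0))
  for (lv in c("Sigma1", "Sigma2")) {
    det <- pool[, paste0(lv, "[1,1]")] * pool[, paste0(lv, "[2,2]")] -
      pool[, paste0(lv, "[1,2]")]^2
    expect_true(all(det > 0))
    expect_true(all(pool[, paste0(lv, "[1,1]")] > 0))
  }
})

test_that("no-data run recovers the prior", {
  model <- zab_model("bp", constant_tau = TRUE,
                     include_level3 = FALSE, include_level2 = FALSE)
  fit <- zab_fit(empty_data(), model, priors = zab_priors_sim(),
                 control = zab_control(n_chains = 2, n_iter = 20000,
                                       n_burnin = 4000, thin = 4, seed = 8))
  pool <- zabp:::pooled_draws(fit)
  for (b in c("beta_(Intercept)", "beta_x")) {
    x <- pool[, b]
    expect_lt(abs(mean(x) - 0), 3 * batch_se(x))     # prior mean 0
    expect_lt(abs(sd(x) - 10) / 10, 0.15)            # prior sd sqrt(100)
  }
  # tau | no data ~ Beta(1, 1)
  expect_lt(abs(mean(pool[, "tau"]) - 0.5), 3 * batch_se(pool[, "tau"]))
  expect_equal(sd(pool[, "tau"]), sqrt(1 / 12), tolerance = 0.05)
})

test_that("inverse-Wishart Gibbs draw matches the analytic posterior mean", {
  # conjugate update: RE pairs held fixed, Sigma | RE ~ IW(Omega + S, nu + n)
  set.seed(31)
  U <- matrix(rnorm(2 * 40, sd = c(1, 0.5)), 40, 2, byrow = TRUE)
  S <- crossprod(U)
  Omega <- diag(0.01, 2); nu <- 5; n <- 40
  draws <- replicate(4000, zabp:::rinvwishart2(Omega + S, nu + n))
  analytic <- (Omega + S) / (nu + n - 3)   # mean of IW_2(A, d) = A/(d - p - 1)
  mc_mean <- apply(draws, c(1, 2), mean)
  mc_se <- apply(draws, c(1, 2), sd) / sqrt(4000)
  expect_true(all(abs(mc_mean - analytic) < 4 * mc_se))
  expect_error(zabp:::rinvwishart2(diag(2), 1), "nu")
})

test_that("MCMC marginal means match grid quadrature on a reduced model", {
  # two-parameter model (log-mean intercept, psi), no random effects; tau
  # factorizes out via its conjugate Beta posterior
  set.seed(11)
  n <- 300
  om <- rbinom(n, 1, 0.5)
  y <- numeric(n)
  y[om == 1] <- rbprime(sum(om == 1), mu = exp(1), psi = 5)
  dat <- zab_data(data.frame(province = 1, city = 1, y = y),
                  "y", "province", "city")
  mod <- zab_model("bp", constant_tau = TRUE,
                   include_level3 = FALSE, include_level2 = FALSE)
  fit <- zab_fit(dat, mod, control = zab_control(n_chains = 2, n_iter = 20000,
                                                 n_burnin = 4000, thin = 4,
                                                 seed = 5))
  sm <- summary(fit)
  pos <- y[y > 0]
  b_grid <- seq(0.5, 1.5, length.out = 301)
  lp_grid <- seq(-2, 4, length.out = 301)
  lg <- outer(b_grid, lp_grid, Vectorize(function(b, lp) {
    psi <- exp(lp)
    sum(dbprime(pos, exp(b), psi, log = TRUE)) +
      stats::dnorm(b, 0, 10, log = TRUE) +
      stats::dgamma(psi, 0.01, rate = 0.01, log = TRUE) + lp
  }))
  expect_lt(max(lg[c(1, 301), ]) - max(lg), -20)  # grid wide enough
  expect_lt(max(lg[, c(1, 301)]) - max(lg), -20)
  w <- exp(lg - max(lg)); w <- w / sum(w)
  quad_b <- sum(rowSums(w) * b_grid)
  quad_psi <- sum(colSums(w) * exp(lp_grid))
  mc_b <- sm$mean[sm$parameter == "beta_(Intercept)"]
  mc_psi <- sm$mean[sm$parameter == "psi"]
  expect_lt(abs(mc_b - quad_b) / abs(quad_b), 0.02)
  expect_lt(abs(mc_psi - quad_psi) / quad_psi, 0.02)
  expect_equal(sm$mean[sm$parameter == "tau"], (1 + sum(om)) / (2 + n),
               tolerance = 0.02)
})

test_that("adapted random-walk acceptance rates land in [0.1, 0.6]", {
  sim <- small_sim(seed = 17, n = 20)
  fit <- zab_fit(sim$data, zab_model("bp", constant_tau = TRUE),
                 control = zab_control(n_iter = 3000, n_burnin = 1500,
                                       thin = 5, seed = 1))
  for (acc in fit$accept) {
    rates <- unlist(acc[c("beta", "psi", "p", "c")])
    expect_true(all(rates > 0.1 & rates < 0.6))
  }
})

test_that("split-chain R-hat: limits and direct-formula oracle", {
  expect_equal(gelman_rubin(list(rep(1, 100), rep(1, 100))), 1)
  set.seed(4)
  apart <- list(rnorm(100, 0), rnorm(100, 10))
  expect_gt(gelman_rubin(apart), 1.5)
  # direct B/W formula on a hand-built 2 x 100 fixture
  chains <- list(rnorm(100), rnorm(100, 0.3))
  halves <- list(chains[[1]][1:50], chains[[1]][51:100],
                 chains[[2]][1:50], chains[[2]][51:100])
  W <- mean(vapply(halves, var, 0))
  B <- 50 * var(vapply(halves, mean, 0))
  oracle <- sqrt((49 / 50 * W + B / 50) / W)
  expect_equal(gelman_rubin(chains), oracle, tolerance = 1e-12)
  expect_error(gelman_rubin(list(rnorm(100))), "2 chains")
  sim_fit <- zab_fit(small_sim(seed = 1, n = 4)$data,
                     zab_model("bp", constant_tau = TRUE),
                     control = quick_control(n_chains = 1))
  expect_error(gelman_rubin(sim_fit, "psi"), "chains")
})

test_that("posterior summaries match a sorted-array quantile oracle", {
  fake <- structure(list(draws = list(
    matrix(1:50, ncol = 1, dimnames = list(NULL, "x")),
    matrix(51:100, ncol = 1, dimnames = list(NULL, "x")))), class = "zab_fit")
  sm <- summary(fake)
  expect_equal(sm$mean, 50.5)
  # type-7 interpolation oracle, written out by hand
  q7 <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p
    lo <- floor(h) + 1
    x[lo] + (h - floor(h)) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(sm$q2.5, q7(1:100, 0.025))
  expect_equal(sm$q97.5, q7(1:100, 0.975))
  # symmetric draws around zero are not flagged significant
  set.seed(2)
  z <- rnorm(200)
  fake2 <- structure(list(draws = list(
    matrix(z[1:100], ncol = 1, dimnames = list(NULL, "x")),
    matrix(z[101:200], ncol = 1, dimnames = list(NULL, "x")))),
    class = "zab_fit")
  sm2 <- summary(fake2)
  expect_true(sm2$q2.5 < 0 && sm2$q97.5 > 0)
  expect_false(sm2$signif)
})

test_that("convergence rate counts fits below the R-hat threshold", {
  expect_equal(convergence_rate(c(1.0, 1.05, 1.02)), 1)
  expect_equal(convergence_rate(c(1.2, 1.5)), 0)
  expect_equal(convergence_rate(c(1.0, 1.0, 1.0, 1.3)), 0.75)
  expect_equal(convergence_rate(c(1.05, 1.2), threshold = 1.1), 0.5)
})
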