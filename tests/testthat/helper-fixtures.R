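# shared fixtures: all data built in code, no files

# 6-row dataset: 2 provinces x 2 cities each, mixed zeros and positives
tiny_df <- function() {
  data.frame(
    province = c("A", "A", "A", "B", "B", "B"),
    city = c("a1", "a1", "a2", "b1", "b1", "b2"),
    y = c(0, 2.5, 1.2, 0, 0.4, 3.1),
    x = c(0, 1, 1, 0, 1, 0))
}

tiny_data <- function() {
  zab_data(tiny_df(), response = "y", level3 = "province", level2 = "city",
           zero_covariates = "x", mean_covariates = "x")
}

# small three-level fixture with enough positives for a short fit
small_sim <- function(seed = 99, n = 20) {
  simulate_sim_design(sim_design("bp", n = n), seed = seed)
}

quick_control <- function(seed = 1, n_iter = 400, n_burnin = 200, thin = 2,
                          n_chains = 2) {
  zab_control(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
              thin = thin, seed = seed)
}

# empty dataset (prior-recovery runs)
empty_data <- function() {
  zab_data(data.frame(province = character(0), city = character(0),
                      y = numeric(0), x = numeric(0)),
           response = "y", level3 = "province", level2 = "city",
           mean_covariates = "x")
}

# batch-means Monte Carlo standard error for a correlated chain
batch_se <- function(x, n_batch = 20) {
  n <- length(x)
  bs <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  stats::sd(means) / sqrt(n_batch)
}

# random valid full-model state for property tests
random_state <- function(data, model, seed) {
  set.seed(seed)
  rcov <- function() {
    a <- stats::runif(1, 0.2, 1); b <- stats::runif(1, 0.2, 1)
    r <- stats::runif(1, -0.6, 0.6)
    matrix(c(a, r * sqrt(a * b), r * sqrt(a * b), b), 2, 2)
  }
  list(alpha = stats::rnorm(ncol(data$X1), 0, 0.5),
       beta = stats::rnorm(ncol(data$X2), 0, 0.5),
       psi = stats::runif(1, 0.2, 3),
       p1 = stats::rnorm(data$n_prov, 0, 0.5), p2 = stats::rnorm(data$n_prov, 0, 0.5),
       c1 = stats::rnorm(data$n_city, 0, 0.5), c2 = stats::rnorm(data$n_city, 0, 0.5),
       Sigma1 = rcov(), Sigma2 = rcov())
}
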