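#' Three-level dataset for two-part models
#'
#' Builds the multilevel data container used throughout the package from a
#' data frame with one row per subject. Subjects (level 1) are nested in
#' cities (level 2), which are nested in provinces (level 3); any nested
#' three-level structure fits the same mold. Grouping ids may be strings or
#' numbers; they are densified to consecutive integers at ingestion and the
#' original labels kept for reporting.
#'
#' The response must be non-negative; the zero/positive indicator
#' \eqn{\omega = I(y > 0)} is derived with threshold exactly 0 (no epsilon).
#' Each part of the model gets its own design matrix with an intercept as the
#' first column.
#'
#' @param df data frame, one row per subject.
#' @param response name of the non-negative response column.
#' @param level3,level2 names of the province-level and city-level id columns.
#' @param zero_covariates character vector of covariate columns for Part I
#'   (occurrence of a positive response); may be empty.
#' @param mean_covariates character vector of covariate columns for Part II
#'   (positive mean); may be empty.
#' @param response_scale positive divisor applied to the response before
#'   modelling (the survey analysis divides expenditure by 100 to improve
#'   MCMC mixing); default 1.
#' @param center logical; mean-center the covariates? Default `FALSE`.
#' @return An object of class `zab_data`: a list with elements `y`, `omega`,
#'   `X1`, `X2`, `prov` and `city` (1-based dense ids per subject),
#'   `city_prov` (province of each city), counts `n_prov`, `n_city`, `N`, and
#'   the original labels.
#' @export
zab_data <- function(df, response, level3, level2,
                     zero_covariates = character(),
                     mean_covariates = character(),
                     response_scale = 1, center = FALSE) {
  stopifnot(is.data.frame(df))
  need <- c(response, level3, level2, zero_covariates, mean_covariates)
  missing_cols <- setdiff(unique(need), names(df))
  if (length(missing_cols))
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!is.numeric(response_scale) || length(response_scale) != 1L || response_scale <= 0)
    stop("'response_scale' must be a single positive number", call. = FALSE)

  y <- as.numeric(df[[response]])
  if (any(!is.finite(y))) stop("response contains non-finite values", call. = FALSE)
  if (any(y < 0)) stop("response must be non-negative; found negative values", call. = FALSE)
  y <- y / response_scale

  l3 <- as.character(df[[level3]])
  l2 <- as.character(df[[level2]])
  # a city must belong to exactly one province
  map <- unique(data.frame(l2 = l2, l3 = l3, stringsAsFactors = FALSE))
  dup <- map$l2[duplicated(map$l2)]
  if (length(dup))
    stop("level-2 unit(s) listed under more than one level-3 unit: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)

  prov_levels <- unique(l3)
  city_levels <- unique(l2)
  prov <- match(l3, prov_levels)
  city <- match(l2, city_levels)
  city_prov <- match(map$l3[match(city_levels, map$l2)], prov_levels)

  make_X <- function(covs) {
    if (length(covs) == 0L) {
      X <- matrix(1, nrow(df), 1L, dimnames = list(NULL, "(Intercept)"))
      return(X)
    }
    Xc <- as.matrix(as.data.frame(lapply(df[covs], as.numeric)))
    if (any(!is.finite(Xc))) stop("covariates contain non-finite values", call. = FALSE)
    if (center && nrow(Xc) > 0L) Xc <- scale(Xc, center = TRUE, scale = FALSE)
    X <- cbind("(Intercept)" = rep(1, nrow(df)), Xc)
    colnames(X) <- c("(Intercept)", covs)
    X
  }
  X1 <- make_X(zero_covariates)
  X2 <- make_X(mean_covariates)
  if (nrow(df) > 0L) {
    for (nm in c("X1", "X2")) {
      X <- get(nm)
      if (qr(X)$rank < ncol(X))
        stop("design matrix ", nm, " is rank deficient", call. = FALSE)
    }
  }

  structure(list(
    y = y, omega = as.integer(y > 0),
    X1 = X1, X2 = X2,
    prov = prov, city = city, city_prov = city_prov,
    n_prov = length(prov_levels), n_city = length(city_levels),
    N = length(y),
    prov_labels = prov_levels, city_labels = city_levels,
    response_scale = response_scale
  ), class = "zab_data")
}

#' @export
print.zab_data <- function(x, ...) {
  cat("Three-level dataset:", x$N, "subjects in", x$n_city, "level-2 units in",
      x$n_prov, "level-3 units\n")
  cat(sprintf("  zero fraction: %.3f  (response scale 1/%g)\n",
              mean(x$omega == 0), x$response_scale))
  cat("  Part I covariates: ", paste(colnames(x$X1), collapse = ", "), "\n")
  cat("  Part II covariates:", paste(colnames(x$X2), collapse = ", "), "\n")
  invisible(x)
}

#' Model specification for the two-part multilevel model
#'
#' @param family positive-part family: `"bp"` (beta-prime, the ZABP-RE model)
#'   or `"gamma"` (the ZAG-RE comparator).
#' @param constant_tau logical. If `TRUE`, Part I is a single probability
#'   `tau` shared by all subjects (no covariates, no Part-I random effects),
#'   as in the simulation design. If `FALSE`, Part I is a logistic mixed
#'   model.
#' @param correlated_re logical. If `TRUE`, each grouping level carries a
#'   bivariate normal random effect (one coordinate per model part) with an
#'   unstructured 2x2 covariance. If `FALSE`, each level carries a single
#'   normal random effect entering Part II only (the reduced design used in
#'   the simulation study). Forced `FALSE` when `constant_tau = TRUE`.
#' @param include_level3,include_level2 logical; include random effects at
#'   that level. Dropping both gives a single-level two-part GLM, handy for
#'   validation against quadrature.
#' @return object of class `zab_model`.
#' @export
zab_model <- function(family = c("bp", "gamma"),
                      constant_tau = FALSE,
                      correlated_re = !constant_tau,
                      include_level3 = TRUE,
                      include_level2 = TRUE) {
  family <- match.arg(family)
  if (constant_tau) correlated_re <- FALSE
  structure(list(family = family, constant_tau = constant_tau,
                 correlated_re = correlated_re,
                 include_level3 = include_level3,
                 include_level2 = include_level2),
            class = "zab_model")
}

#' Prior specification
#'
#' Independent priors for the model parameters. Defaults follow the survey
#' analysis: coefficients `N(0, 1e4)`, precision `psi ~ IG(0.01, 0.01)`,
#' level covariances `Sigma ~ Inverse-Wishart(0.01 I2, 2)`. For the
#' simulation design ([zab_model] with `constant_tau = TRUE`) use
#' [zab_priors_sim()], which matches the stated simulation priors:
#' coefficients `N(0, 100)`, `psi ~ Gamma(0.01, 0.01)`,
#' `sigma^2 ~ IG(0.01, 0.01)` per level and `tau ~ U(0, 1)`.
#'
#' @param alpha_var,beta_var prior variance (diagonal) of the Part I / Part II
#'   coefficients; prior means are zero.
#' @param psi_prior `"invgamma"` or `"gamma"`.
#' @param psi_a,psi_b hyperparameters of the `psi` prior (shape, rate for the
#'   gamma; shape, scale for the inverse gamma).
#' @param Omega1,Omega2 inverse-Wishart scale matrices (correlated mode).
#' @param nu1,nu2 inverse-Wishart degrees of freedom, `>= 2`.
#' @param sigma2_a,sigma2_b inverse-gamma hyperparameters for the per-level
#'   variances (independent mode).
#' @param tau_a,tau_b beta prior for constant `tau`; `(1, 1)` is uniform.
#' @return object of class `zab_priors`.
#' @export
zab_priors <- function(alpha_var = 1e4, beta_var = 1e4,
                       psi_prior = c("invgamma", "gamma"),
                       psi_a = 0.01, psi_b = 0.01,
                       Omega1 = diag(0.01, 2), nu1 = 2,
                       Omega2 = diag(0.01, 2), nu2 = 2,
                       sigma2_a = 0.01, sigma2_b = 0.01,
                       tau_a = 1, tau_b = 1) {
  psi_prior <- match.arg(psi_prior)
  stopifnot(alpha_var > 0, beta_var > 0, psi_a > 0, psi_b > 0,
            nu1 >= 2, nu2 >= 2, sigma2_a > 0, sigma2_b > 0,
            tau_a > 0, tau_b > 0)
  for (Om in list(Omega1, Omega2)) {
    stopifnot(is.matrix(Om), nrow(Om) == 2, ncol(Om) == 2)
    if (min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("inverse-Wishart scale matrix must be positive definite", call. = FALSE)
  }
  structure(list(alpha_var = alpha_var, beta_var = beta_var,
                 psi_prior = psi_prior, psi_a = psi_a, psi_b = psi_b,
                 Omega1 = Omega1, nu1 = nu1, Omega2 = Omega2, nu2 = nu2,
                 sigma2_a = sigma2_a, sigma2_b = sigma2_b,
                 tau_a = tau_a, tau_b = tau_b),
            class = "zab_priors")
}

#' @rdname zab_priors
#' @export
zab_priors_sim <- function() {
  zab_priors(alpha_var = 100, beta_var = 100,
             psi_prior = "gamma", psi_a = 0.01, psi_b = 0.01,
             sigma2_a = 0.01, sigma2_b = 0.01, tau_a = 1, tau_b = 1)
}
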