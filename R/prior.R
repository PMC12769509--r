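#' Uniform prior over a discrete grid
#' @param n Number of grid points.
#' @return Vector of masses `1/n`.
#' @export
uniform_prior <- function(n) rep(1 / n, n)

# multivariate normal log-density (no external dependency)
.dmvnorm_log <- function(x, mean, sigma) {
  L <- chol(sigma)
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(L))) - 0.5 * length(mean) * log(2 * pi)
}

#' Synthetic population-based length-resolved rate estimates
#'
#' Generates length-stratified rate estimates on an exact power law
#' `rate(L) = c (L/9)^tau` with optional log-normal noise and a log-scale
#' standard error per point; stands in for mid-length population-based
#' instability rate estimates when constructing informative priors.
#'
#' @param c_rate Rate at L = 9.
#' @param tau Power-law exponent.
#' @param L Lengths covered (default 11..29).
#' @param se_log Log-scale standard error attached to each estimate.
#' @param noise_sd Log-normal noise actually added (0 = noiseless).
#' @param seed Integer seed.
#' @return Data frame with `tract_length_units`, `rate`, `se_log`.
#' @export
synth_population_rates <- function(c_rate, tau, L = 11:29, se_log = 0.2,
                               noise_sd = 0, seed = 1L) {
  withr_seed(seed)
  rate <- c_rate * (L / 9)^tau * exp(stats::rnorm(length(L), 0, noise_sd))
  data.frame(tract_length_units = L, rate = rate, se_log = se_log)
}

# weighted log-log power-law fit; returns estimates and covariance of
# (log c, tau) with c the rate at L = 9
.fit_loglog <- function(tab, inflate_range = c(13, 21),
                        inflate_var_outside = 100) {
  if (sum(is.finite(tab$rate) & tab$rate > 0) < 3L)
    stop("fit error: need at least 3 usable lengths", call. = FALSE)
  keep <- is.finite(tab$rate) & tab$rate > 0
  tab <- tab[keep, ]
  se <- tab$se_log
  out_rng <- tab$tract_length_units < inflate_range[1L] |
    tab$tract_length_units > inflate_range[2L]
  se[out_rng] <- se[out_rng] * sqrt(inflate_var_outside)
  x <- log(tab$tract_length_units / 9)
  y <- log(tab$rate)
  fit <- stats::lm(y ~ x, weights = 1 / se^2)
  list(logc = unname(stats::coef(fit)[1L]), tau = unname(stats::coef(fit)[2L]),
       vcov = stats::vcov(fit))
}

#' Informative prior from mid-length population rate estimates
#'
#' Fits power laws to expansion-like and contraction rate estimates in
#' log-log space (weighted by approximately symmetric log-scale errors, with
#' the variance inflated outside the well-calibrated length range 13-21),
#' evaluates the best fit and its uncertainty at L = 9, assembles a
#' block-diagonal covariance over (log c_eps, tau_eps, log c_kap, tau_kap)
#' (expansion independent of contraction), inflates it by a constant
#' (100-fold "restrictive", 1000-fold "permissive"), and evaluates the
#' resulting multivariate normal on the model grid, renormalizing.  Nested
#' families evaluate the same four-dimensional density at their induced
#' coordinates.
#'
#' @param expansion,contraction Data frames as from [synth_population_rates()]
#'   (columns `tract_length_units`, `rate`, `se_log`), covering roughly
#'   L = 11..29.
#' @param family Parameterization family of the grid.
#' @param grid Data frame of grid coordinates for `family`.
#' @param inflation Variance inflation (100 restrictive, 1000 permissive).
#' @param emp_rates Empirical low-length rates (to map multiplier families
#'   onto rate constants at L = 9).
#' @param inflate_range,inflate_var_outside Well-calibrated length range
#'   and the variance inflation applied outside it during the fit.
#' @return Normalized prior masses over the grid rows; the fitted means and
#'   covariance are attached as attributes `fit_mean`, `fit_cov`.
#' @export
fit_informative_prior <- function(expansion, contraction, family, grid,
                                  inflation = 100,
                                  emp_rates = empirical_rates_mono_a(),
                                  inflate_range = c(13, 21),
                                  inflate_var_outside = 100) {
  fe <- .fit_loglog(expansion, inflate_range, inflate_var_outside)
  fk <- .fit_loglog(contraction, inflate_range, inflate_var_outside)
  mean4 <- c(fe$logc, fe$tau, fk$logc, fk$tau)
  cov4 <- matrix(0, 4, 4)
  cov4[1:2, 1:2] <- fe$vcov
  cov4[3:4, 3:4] <- fk$vcov
  cov4 <- cov4 * inflation
  coords <- .grid_to_logc_tau(family, grid, emp_rates)
  logd <- apply(coords, 1L, .dmvnorm_log, mean = mean4, sigma = cov4)
  w <- exp(logd - max(logd))
  prior <- w / sum(w)
  attr(prior, "fit_mean") <- mean4
  attr(prior, "fit_cov") <- cov4
  prior
}

# map a family grid onto (log c_eps, tau_eps, log c_kap, tau_kap)
.grid_to_logc_tau <- function(family, grid, emp_rates) {
  n <- nrow(grid)
  g <- function(col) grid[[col]]
  switch(family,
    symmetric_power = ,
    symmetric_log = cbind(log(g("c")), g("tau"), log(g("c")), g("tau")),
    decoupled_power = ,
    decoupled_log = cbind(log(g("c_eps")), g("tau_eps"),
                          log(g("c_kap")), g("tau_kap")),
    shared_exponent_power = cbind(log(g("c_eps")), g("tau"),
                                  log(g("c_kap")), g("tau")),
    shared_constant_power = cbind(log(g("c")), g("tau_eps"),
                                  log(g("c")), g("tau_kap")),
    multiplier_coupled_power = ,
    multiplier_coupled_log = cbind(log(g("m") * emp_rates$eps[8L]),
                                   g("tau_eps"),
                                   log(g("m") * emp_rates$kap[8L]),
                                   g("tau_kap")),
    stop("no informative prior mapping for family '", family, "'",
         call. = FALSE))
}

#' Informative prior for the fully parameterized (pure power-law) family
#'
#' Fits `rate(L) = anchor (L / lambda)^tau` to combined rate estimates at
#' L = 4..15 for expansion (anchor `mu`) and contraction (anchor `nu`),
#' propagates the fit covariance to `(lambda, tau)` by the delta method,
#' inflates it 100-fold, and evaluates the 4-dimensional normal over the
#' grid.
#'
#' @param expansion,contraction Data frames (`tract_length_units`, `rate`,
#'   `se_log`) covering roughly L = 4..15.
#' @param grid Data frame with columns `lambda_eps`, `lambda_kap`,
#'   `tau_eps`, `tau_kap`.
#' @param subst [substitution_rates()] supplying `mu` and `nu`.
#' @param inflation Variance inflation factor.
#' @return Normalized prior masses over the grid rows.
#' @export
fit_pure_power_prior <- function(expansion, contraction, grid,
                                 subst = substitution_rates(),
                                 inflation = 100) {
  fit1 <- function(tab, anchor) {
    keep <- is.finite(tab$rate) & tab$rate > 0
    tab <- tab[keep, ]
    if (nrow(tab) < 3L) stop("fit error: need >= 3 usable lengths", call. = FALSE)
    x <- log(tab$tract_length_units)
    y <- log(tab$rate)
    fit <- stats::lm(y ~ x, weights = 1 / tab$se_log^2)
    b0 <- unname(stats::coef(fit)[1L]); tau <- unname(stats::coef(fit)[2L])
    V <- stats::vcov(fit)
    lambda <- exp((log(anchor) - b0) / tau)
    # delta method for (lambda, tau) from (b0, tau)
    dl_db0 <- -lambda / tau
    dl_dtau <- -lambda * (log(anchor) - b0) / tau^2
    J <- matrix(c(dl_db0, dl_dtau, 0, 1), 2, 2, byrow = TRUE)
    list(mean = c(lambda, tau), vcov = J %*% V %*% t(J))
  }
  fe <- fit1(expansion, subst$mu)
  fk <- fit1(contraction, subst$nu)
  mean4 <- c(fe$mean[1L], fk$mean[1L], fe$mean[2L], fk$mean[2L])
  cov4 <- matrix(0, 4, 4)
  cov4[c(1, 3), c(1, 3)] <- fe$vcov
  cov4[c(2, 4), c(2, 4)] <- fk$vcov
  cov4 <- cov4 * inflation
  coords <- cbind(grid$lambda_eps, grid$lambda_kap,
                  grid$tau_eps, grid$tau_kap)
  logd <- apply(coords, 1L, .dmvnorm_log, mean = mean4, sigma = cov4)
  w <- exp(logd - max(logd))
  w / sum(w)
}
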