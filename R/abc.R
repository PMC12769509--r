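#' Inference configuration
#'
#' @param L_min Lower summation bound of the KL divergence (default 4; the
#'   lowest bins are sensitive to assembly artifacts and to the ordering of
#'   within-clade divergences).
#' @param L_max_kl Upper summation bound (default 200, the longest modeled
#'   bin).
#' @param pseudocount Count added to every length class of both
#'   distributions before renormalization (default 1), avoiding divergence
#'   of the statistic on empty bins.
#' @param sigma Gaussian soft-rejection scale for the ABC kernel (set from
#'   an ensemble with [primate_sigma()], or supplied directly).
#' @export
inference_config <- function(L_min = 4L, L_max_kl = 200L, pseudocount = 1,
                             sigma = NULL) {
  stopifnot(pseudocount > 0, L_min < L_max_kl)
  structure(list(L_min = as.integer(L_min), L_max_kl = as.integer(L_max_kl),
                 pseudocount = pseudocount, sigma = sigma),
            class = "inference_config")
}

.kl_prep <- function(counts, cfg) {
  x <- numeric(cfg$L_max_kl)
  n <- min(length(counts), cfg$L_max_kl)
  if (n > 0) x[seq_len(n)] <- counts[seq_len(n)]
  x <- x + cfg$pseudocount
  x <- x[cfg$L_min:cfg$L_max_kl]
  x / sum(x)
}

#' Kullback-Leibler divergence between two DRLs
#'
#' Both distributions receive the pseudocount in the counts domain on every
#' length class 1..`L_max_kl`, are then conditionally renormalized on
#' `[L_min, L_max_kl]`, and the natural-log divergence
#' `sum P_emp log(P_emp / P_model)` is returned.  Zero iff the restricted
#' distributions coincide; asymmetric in its arguments.
#'
#' @param model,empirical [drl()] objects (counts at comparable scale) or
#'   bare count vectors.
#' @param cfg An [inference_config()].
#' @return Nonnegative divergence in nats.
#' @export
kl_divergence <- function(model, empirical, cfg = inference_config()) {
  cm <- if (inherits(model, "drl")) model$counts else as.numeric(model)
  ce <- if (inherits(empirical, "drl")) empirical$counts else as.numeric(empirical)
  pm <- .kl_prep(cm, cfg)
  pe <- .kl_prep(ce, cfg)
  sum(pe * log(pe / pm))
}

#' ABC rejection scale from an ensemble of related DRLs
#'
#' Computes the KL divergence of each ensemble member against the reference
#' distribution, discards the largest `ceiling(0.05 n)` values (2 for an
#' ensemble of 36), and sets `sigma` to half the largest retained
#' divergence, so that the Gaussian rejection kernel treats the spread of
#' the ensemble as the tolerated model-data discrepancy.
#'
#' @param ensemble List of [drl()] objects.
#' @param reference The reference [drl()] (plays the empirical role in the
#'   divergence).
#' @param cfg An [inference_config()].
#' @return The scale `sigma` (may be 0 for a degenerate ensemble of copies,
#'   in which case downstream rejection is hard; documented degenerate
#'   case).
#' @export
primate_sigma <- function(ensemble, reference, cfg = inference_config()) {
  n <- length(ensemble)
  if (n < 3L) stop("degenerate ensemble: need at least 3 members", call. = FALSE)
  kls <- vapply(ensemble, function(m) kl_divergence(m, reference, cfg),
                numeric(1))
  drop <- ceiling(0.05 * n)
  retained <- sort(kls)[seq_len(n - drop)]
  max(retained) / 2
}

#' Soft-rejection ABC posterior on a parameter grid
#'
#' posterior_i = prior_i exp(-D_i^2 / (2 sigma^2)), normalized over the
#' grid.  Computed in log space so that uniformly poor fits degrade
#' gracefully instead of producing NaN.
#'
#' @param grid Data frame of grid coordinates (one parameter per column).
#' @param kl Vector of KL divergences per grid point.
#' @param prior Vector of prior masses (normalized; see
#'   [uniform_prior()] / [fit_informative_prior()]).
#' @param sigma Positive rejection scale.
#' @return An object of class `posterior_grid` with fields `grid`, `prior`,
#'   `kl`, `posterior`, `log_weight`, `sigma`, plus `max_posterior` and
#'   `mean_posterior` summaries.  Ties for the maximum are broken towards
#'   the lexicographically smallest coordinates.
#' @export
posterior_grid <- function(grid, kl, prior, sigma) {
  stopifnot(nrow(grid) == length(kl), length(prior) == length(kl),
            sigma > 0)
  lw <- log(prior) - kl^2 / (2 * sigma^2)
  m <- max(lw)
  w <- exp(lw - m)
  post <- w / sum(w)
  best <- which(post == max(post))
  if (length(best) > 1L)
    best <- best[do.call(order, as.list(grid[best, , drop = FALSE]))][1L]
  mean_post <- vapply(grid, function(col) sum(col * post), numeric(1))
  max_post <- lapply(as.list(grid[best, , drop = FALSE]),
                     function(x) as.numeric(x))
  structure(list(grid = grid, prior = prior, kl = kl, posterior = post,
                 log_weight = lw, sigma = sigma,
                 max_posterior = max_post,
                 max_index = best,
                 mean_posterior = mean_post),
            class = "posterior_grid")
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat("<posterior_grid> ", nrow(x$grid), " cells; max posterior at (",
      paste(signif(unlist(x$max_posterior), 3), collapse = ", "),
      "), mass ", signif(max(x$posterior), 3), "\n", sep = "")
  invisible(x)
}

#' Bayes factor of a parameterization (grid quadrature)
#'
#' `BF = sum_i prior_i exp(-D_i^2 / (2 sigma^2))`.  Comparable across
#' models only at a common `sigma` and empirical target; the ratio of two
#' Bayes factors (BFR) measures relative support, interpreted on Jeffreys'
#' scale by the caller.
#'
#' @inheritParams posterior_grid
#' @return A list with `bf` and `log_bf` (the log value survives underflow).
#' @export
bayes_factor <- function(kl, prior, sigma) {
  stopifnot(sigma > 0)
  lw <- log(prior) - kl^2 / (2 * sigma^2)
  m <- max(lw)
  log_bf <- m + log(sum(exp(lw - m)))
  list(bf = exp(log_bf), log_bf = log_bf, sigma = sigma)
}

#' @rdname bayes_factor
#' @param m1,m2 Results of [bayes_factor()] for the two models (must share
#'   `sigma`).
#' @export
bayes_factor_ratio <- function(m1, m2) {
  if (!isTRUE(all.equal(m1$sigma, m2$sigma)))
    stop("comparison error: Bayes factors computed under different sigma",
         call. = FALSE)
  exp(m1$log_bf - m2$log_bf)
}

#' Highest density regions on the grid
#'
#' Grid cells are sorted by posterior mass (stable sort, so ties at the cut
#' resolve deterministically by grid order) and accumulated until each
#' requested level is reached.
#'
#' @param posterior Normalized posterior vector (or `posterior_grid`).
#' @param levels Probability levels.
#' @return A named list of logical masks, one per level.
#' @export
hdr <- function(posterior, levels = c(0.68, 0.95, 0.997)) {
  p <- if (inherits(posterior, "posterior_grid")) posterior$posterior
       else posterior
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  out <- lapply(levels, function(lv) {
    k <- which(cum >= lv - 1e-12)[1L]
    if (is.na(k)) k <- length(p)
    mask <- logical(length(p))
    mask[ord[seq_len(k)]] <- TRUE
    mask
  })
  names(out) <- as.character(levels)
  out
}

#' Posterior-weighted expectation
#'
#' `E[f(theta)] = sum_i f(theta_i) posterior_i`, for scalar- or
#' vector-valued `f` (e.g. the late-time DRL or the rate curve per grid
#' point).
#'
#' @param pg A [posterior_grid()].
#' @param f Either a function of a one-row grid data frame, or a matrix
#'   with one row (or column vector entry) per grid point.
#' @return The probability-weighted sum.
#' @export
posterior_expectation <- function(pg, f) {
  stopifnot(inherits(pg, "posterior_grid"))
  if (is.function(f)) {
    vals <- lapply(seq_len(nrow(pg$grid)), function(i)
      f(pg$grid[i, , drop = FALSE]))
    acc <- vals[[1L]] * pg$posterior[1L]
    for (i in seq_along(vals)[-1L]) acc <- acc + vals[[i]] * pg$posterior[i]
    acc
  } else {
    f <- as.matrix(f)
    stopifnot(nrow(f) == length(pg$posterior))
    drop(crossprod(f, pg$posterior))
  }
}

#' Grid ABC over a rate parameterization
#'
#' The full inference loop: for every grid point, build the rate table,
#' evolve the DRL to late times, rescale to genome-scale counts, and score
#' against the empirical DRL by KL divergence; then form the soft-rejection
#' posterior under the given prior.
#'
#' @param family Parameterization family (see [param_spec()]).
#' @param grid Data frame of parameter combinations (columns named as the
#'   family's parameters).
#' @param empirical Target [drl()] (genome-scale counts).
#' @param prior Prior masses over the grid (default uniform).
#' @param sigma Rejection scale (e.g. from [primate_sigma()]).
#' @param cfg An [inference_config()].
#' @param init Initial [sim_state()] (shared across grid points).
#' @param subst,emp_rates Substitution rates and empirical low-length rates.
#' @param sim Simulation [sim_config()].
#' @param keep_drls Keep each grid point's late-time DRL (needed for
#'   posterior-weighted DRLs).
#' @return A `posterior_grid` with extra fields `bf`, `drls` (optional) and
#'   `diverged` (logical per grid point).
#' @export
infer_grid <- function(family, grid, empirical, prior = NULL, sigma,
                       cfg = inference_config(),
                       init, subst = substitution_rates(),
                       emp_rates = empirical_rates_mono_a(),
                       sim = sim_config(), keep_drls = FALSE) {
  n <- nrow(grid)
  if (is.null(prior)) prior <- uniform_prior(n)
  kl <- numeric(n)
  div <- logical(n)
  drls <- if (keep_drls) vector("list", n) else NULL
  for (i in seq_len(n)) {
    spec <- param_spec(family, unlist(grid[i, , drop = TRUE]))
    curve <- build_rate_table(spec, emp_rates, L_bound = sim$L_cap,
                              subst = subst)
    ev <- evolve(init, subst, curve, sim)
    div[i] <- ev$diverged || ev$boundary_growing
    model <- drl(ev$state$a, motif = empirical$motif, source = "model")
    kl[i] <- kl_divergence(model, empirical, cfg)
    if (div[i]) kl[i] <- max(kl[i], 1e3 * max(sigma, 1e-12)) # hard-rejected
    if (keep_drls) drls[[i]] <- model
  }
  pg <- posterior_grid(grid, kl, prior, sigma)
  pg$bf <- bayes_factor(kl, prior, sigma)
  pg$diverged <- div
  pg$drls <- drls
  pg
}
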