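#' Simulation state: paired A-repeat and B-string length histograms
#'
#' @param a Numeric vector; `a[L]` is the (possibly fractional, expected)
#'   count of repeat tracts of length `L` units.
#' @param b Numeric vector; `b[k]` the count of non-repeat ("B") strings of
#'   length `k` nt.
#' @param generation Generations elapsed.
#' @param r Current speed-up exponent (rates multiplied by `10^r`).
#' @export
sim_state <- function(a, b, generation = 0, r = 0L) {
  stopifnot(all(a >= 0), all(b >= 0), !anyNA(a), !anyNA(b))
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 generation = generation, r = as.integer(r)),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat("<sim_state> ", length(x$a), " A bins (", format(sum(x$a), digits = 4),
      " tracts), ", length(x$b), " B bins; generation ",
      format(x$generation, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Simulation configuration
#'
#' @param schedule Data frame with columns `r` (nonincreasing speed-up
#'   exponents) and `iterations` per stage.  The default is the four-stage
#'   schedule r = 3, 2, 1, 0 with 1e6 iterations each (1.111e9 generations
#'   in total when all stages run).
#' @param saturation_threshold Per-repeat total mutation probability above
#'   which a length bin leaves the single-event ("linear") regime.
#' @param L_cap Hard cap on the modeled length range.
#' @param stochastic Poisson-sample per-bin fluxes instead of applying the
#'   deterministic expectation.
#' @param seed Seed used when `stochastic = TRUE`.
#' @param conv_tol If positive, a stage stops early once the largest
#'   per-bin net-to-gross flux ratio over bins with at least
#'   `conv_min_count` counts falls below this value (steady-state detection).
#'   0 disables early stopping (full schedule, as in a reference run).
#' @param check_every Iterations between convergence/divergence checks.
#' @param conv_min_count Minimum bin count for the convergence criterion.
#' @param diverge_factor Declare divergence when total tract count exceeds
#'   this multiple of its initial value (non-equilibrating parameters grow
#'   without bound; stopping early keeps them finite).
#' @param fast_generations Generations to run when a single-stage fast path
#'   applies (see [evolve()]).
#' @param r_max Largest speed-up exponent ever considered.
#' @param context_lengthening Use the context-exact aggregate target for
#'   lengthening substitutions (the number of BBA contexts, i.e. twice the
#'   number of B strings of length >= 2); `FALSE` uses a flat target of two
#'   per tract.  See the methods vignette.
#' @param fusion_subtract "uniform" (evenly across eligible bins) or
#'   "weighted" (proportional to bin occupancy) for the counts consumed by
#'   fusion.
#' @param conv_support_tol Relative occupancy below which bins are dropped
#'   from the fusion pairing convolution (a pure speed knob; 0 = exact).
#' @export
sim_config <- function(schedule = data.frame(r = 3:0, iterations = 1e6),
                       saturation_threshold = 0.1,
                       L_cap = 200L,
                       stochastic = FALSE,
                       seed = NULL,
                       conv_tol = 0,
                       check_every = 200L,
                       conv_min_count = 1,
                       diverge_factor = 100,
                       fast_generations = 1e9,
                       r_max = 5L,
                       context_lengthening = TRUE,
                       fusion_subtract = c("uniform", "weighted"),
                       conv_support_tol = 1e-14) {
  stopifnot(all(diff(schedule$r) <= 0), saturation_threshold > 0,
            saturation_threshold < 1)
  structure(list(schedule = schedule,
                 saturation_threshold = saturation_threshold,
                 L_cap = as.integer(L_cap), stochastic = stochastic,
                 seed = seed, conv_tol = conv_tol,
                 check_every = as.integer(check_every),
                 conv_min_count = conv_min_count,
                 diverge_factor = diverge_factor,
                 fast_generations = fast_generations,
                 r_max = as.integer(r_max),
                 context_lengthening = context_lengthening,
                 fusion_subtract = match.arg(fusion_subtract),
                 conv_support_tol = conv_support_tol),
            class = "sim_config")
}

# total per-repeat mutation probability at lengths L (no speed-up applied)
per_repeat_prob <- function(curve, subst, L = seq_along(curve$eps)) {
  eps <- curve$eps[L]; kap <- curve$kap[L]; iota <- curve$iota[L]
  2 * subst$lengthen +
    ifelse(L >= 2, 2 * subst$shorten, subst$destroy_a1) +
    pmax(L - 2, 0) * subst$fission +
    eps * L + ifelse(L >= 2, kap * L, 0) + iota * pmax(L - 1, 0)
}

#' Saturation length under a speed-up factor
#'
#' The smallest length at which the speed-up-rescaled total per-repeat
#' mutation probability exceeds the saturation threshold; `Inf` if it never
#' does within the table.  The modeled range is then
#' `L_bound = min(L_max, L_cap)`.
#'
#' @param curve A [rate_curve()].
#' @param subst A [substitution_rates()].
#' @param r Speed-up exponent (rates scaled by `10^r`).
#' @param threshold Saturation threshold (default 0.1).
#' @return Integer length, or `Inf`.
#' @export
compute_Lmax <- function(curve, subst, r = 0L, threshold = 0.1) {
  p <- 10^r * per_repeat_prob(curve, subst)
  idx <- which(p > threshold)
  if (!length(idx)) Inf else idx[1L]
}

.kernel_opts <- function(config) {
  list(context = isTRUE(config$context_lengthening),
       uniform = identical(config$fusion_subtract, "uniform"),
       ctol = config$conv_support_tol)
}

# resize a histogram to n bins; surplus mass is lumped into the last bin
.resize_hist <- function(x, n) {
  if (length(x) == n) return(x)
  if (length(x) > n) {
    y <- x[seq_len(n)]
    y[n] <- y[n] + sum(x[(n + 1L):length(x)])
    y
  } else c(x, numeric(n - length(x)))
}

#' Apply the deterministic mutation kernel for one iteration
#'
#' Computes every per-bin flux from the start-of-generation state and applies
#' them simultaneously: local lengthening/shortening substitutions,
#' fission/fusion substitutions, expansions/contractions, non-motif
#' insertions, B-string bookkeeping, and the reflective boundary at the last
#' bin.  One iteration represents `10^r` generations.
#'
#' @param state A [sim_state()].
#' @param subst A [substitution_rates()].
#' @param curve A [rate_curve()] with at least as many lengths as `state$a`.
#' @param r Speed-up exponent (defaults to the state's).
#' @param config A [sim_config()] supplying kernel options.
#' @param check Verify the single-event (saturation) precondition and raise
#'   an error naming the offending bin if violated.
#' @return The updated [sim_state()].
#' @export
kernel_step <- function(state, subst, curve, r = state$r,
                        config = sim_config(), check = TRUE) {
  La <- length(state$a)
  if (check) {
    p <- 10^r * per_repeat_prob(curve, subst, seq_len(max(1L, La - 1L)))
    bad <- which(p > config$saturation_threshold)
    if (length(bad))
      stop("saturation error: per-repeat mutation probability ",
           signif(p[bad[1L]], 3), " > ", config$saturation_threshold,
           " at bin L = ", bad[1L], call. = FALSE)
  }
  o <- .kernel_opts(config)
  fl <- cpp_kernel_fluxes(state$a, state$b, subst,
                          curve$eps[seq_len(La)], curve$kap[seq_len(La)],
                          curve$iota[seq_len(La)],
                          10^r, o$context, o$uniform, o$ctol, FALSE)
  a <- pmax(state$a + fl$a_in - fl$a_out, 0)
  b <- pmax(state$b + fl$b_in - fl$b_out, 0)
  sim_state(a, b, generation = state$generation + 10^r, r = r)
}

#' Poisson-stochastic kernel iteration
#'
#' As [kernel_step()], but the number of mutations in and out of each length
#' bin is separately Poisson-sampled around its expectation; counts are
#' floored at zero.
#'
#' @inheritParams kernel_step
#' @param rng_seed Optional seed set before sampling.
#' @export
poisson_step <- function(state, subst, curve, r = state$r,
                         config = sim_config(), check = TRUE,
                         rng_seed = NULL) {
  if (!is.null(rng_seed)) withr_seed(rng_seed)
  La <- length(state$a)
  if (check) {
    p <- 10^r * per_repeat_prob(curve, subst, seq_len(max(1L, La - 1L)))
    bad <- which(p > config$saturation_threshold)
    if (length(bad))
      stop("saturation error at bin L = ", bad[1L], call. = FALSE)
  }
  o <- .kernel_opts(config)
  res <- cpp_evolve(state$a, state$b, subst,
                    curve$eps[seq_len(La)], curve$kap[seq_len(La)],
                    curve$iota[seq_len(La)],
                    10^r, 1L, o$context, o$uniform, o$ctol,
                    TRUE, 0L, 0, 1, 0, 10L)
  sim_state(res$a, res$b, generation = state$generation + 10^r, r = r)
}

#' Analytic random-genome initial state, optionally substitution-equilibrated
#'
#' Builds the expected tract/B-string histograms of an i.i.d. random genome
#' of length `G` with unit fraction `p = mu/(mu+nu)`
#' (`a[L] = G (1-p)^2 p^L`, `b` mirrored), then, by default, pre-runs the
#' kernel under substitutions alone at the largest allowable speed-up
#' (r = 5) for the equivalent of 1e10 generations, so that the
#' slowly-equilibrating short bins start at the substitution-only steady
#' state.
#'
#' @param G Genome length (nt).
#' @param subst A [substitution_rates()].
#' @param L_bound,L_bound_b Histogram supports.
#' @param pre_run Run the substitution-only pre-simulation.
#' @param pre_generations Generations of pre-simulation.
#' @param pre_r Speed-up used for the pre-run.
#' @param initializer "geometric" (default) or "geometric_uniform" (adds a
#'   small uniform occupancy, for robustness tests of the final state's
#'   independence of the start).
#' @return A [sim_state()].
#' @export
initialize_state <- function(G, subst = substitution_rates(),
                             L_bound = 200L, L_bound_b = 200L,
                             pre_run = TRUE, pre_generations = 1e10,
                             pre_r = 5L,
                             initializer = c("geometric", "geometric_uniform")) {
  stopifnot(G > 0)
  initializer <- match.arg(initializer)
  p <- p_repeat_unit(subst)
  q <- 1 - p
  L <- seq_len(L_bound)
  K <- seq_len(L_bound_b)
  a <- G * q^2 * p^L
  b <- G * p^2 * q^K
  if (initializer == "geometric_uniform") {
    a <- a + sum(a) * 1e-6 / L_bound
    b <- b + sum(b) * 1e-6 / L_bound_b
  }
  st <- sim_state(a, b, generation = 0, r = 0L)
  if (pre_run) {
    zero <- rate_curve(numeric(L_bound), numeric(L_bound), numeric(L_bound))
    sub0 <- subst
    sub0$b_insert <- 0; sub0$b_delete <- 0; sub0$b1_delete <- 0
    res <- cpp_evolve(st$a, st$b, sub0,
                      zero$eps, zero$kap, zero$iota,
                      10^pre_r, as.integer(pre_generations / 10^pre_r),
                      TRUE, TRUE, 1e-14,
                      FALSE, 500L, 1e-10, 1, 0, 10L)
    st <- sim_state(res$a, res$b, generation = 0, r = 0L)
  }
  st
}

#' Evolve a repeat length distribution to late times
#'
#' Runs the deterministic (or Poisson-stochastic) mutation kernel under the
#' step-wise speed-up procedure: if the saturation length at some speed-up
#' `r >= 3` already exceeds the length cap, a single stage at the largest
#' allowed `r` covers `fast_generations`; otherwise stages at r = 3, 2, 1, 0
#' run in turn, each with the per-stage iteration budget, re-deriving the
#' reflective boundary `L_bound = min(L_max, L_cap)` per stage and stopping
#' once a stage's saturation length reaches the cap.  When the final stage
#' ran at r = 0 with `L_max < L_cap`, counts between `L_max` and the cap are
#' zeroed before analysis.  Divergent (non-equilibrating) parameter
#' combinations are detected and flagged, not raised as errors.
#'
#' @param state A [sim_state()] (see [initialize_state()]).
#' @param subst A [substitution_rates()].
#' @param curve A [rate_curve()] covering `L = 1..L_cap`.
#' @param config A [sim_config()].
#' @return A list of class `drl_evolution`: `state` (final), `stages`
#'   (per-stage diagnostics), `equilibrated`, `diverged`,
#'   `boundary_growing`, `zeroed_above` and `generations`.
#' @export
evolve <- function(state, subst, curve, config = sim_config()) {
  cap <- min(config$L_cap, length(curve$eps))
  o <- .kernel_opts(config)
  if (config$stochastic && !is.null(config$seed)) withr_seed(config$seed)

  lmax_r <- vapply(0:config$r_max, function(r)
    compute_Lmax(curve, subst, r, config$saturation_threshold), numeric(1))
  names(lmax_r) <- as.character(0:config$r_max)

  run_stage <- function(st, r, iters, L_bound) {
    a <- .resize_hist(st$a, L_bound)
    b <- .resize_hist(st$b, min(config$L_cap, length(st$b)))
    res <- cpp_evolve(a, b, subst,
                      curve$eps[seq_len(L_bound)], curve$kap[seq_len(L_bound)],
                      curve$iota[seq_len(L_bound)],
                      10^r, as.integer(iters), o$context, o$uniform, o$ctol,
                      config$stochastic,
                      config$check_every, config$conv_tol,
                      config$conv_min_count, config$diverge_factor, 50L)
    list(state = sim_state(res$a, res$b,
                           generation = st$generation + res$iterations * 10^r,
                           r = r),
         meta = res)
  }

  stages <- list()
  st <- state
  diverged <- FALSE
  boundary_growing <- FALSE
  last_r <- NA_integer_

  fast_r <- suppressWarnings(max(c(-1L,
    (3:config$r_max)[lmax_r[as.character(3:config$r_max)] >= cap])))
  if (fast_r >= 3L) {
    iters <- ceiling(config$fast_generations / 10^fast_r)
    res <- run_stage(st, fast_r, iters, cap)
    st <- res$state
    stages[[1L]] <- data.frame(r = fast_r, L_bound = cap,
                               iterations = res$meta$iterations,
                               converged = res$meta$converged,
                               residual = res$meta$residual,
                               diverged = res$meta$diverged)
    diverged <- res$meta$diverged
    boundary_growing <- res$meta$boundary_growing
    last_r <- fast_r
  } else {
    for (i in seq_len(nrow(config$schedule))) {
      r <- config$schedule$r[i]
      iters <- config$schedule$iterations[i]
      L_bound <- min(lmax_r[as.character(r)], cap)
      res <- run_stage(st, r, iters, L_bound)
      st <- res$state
      stages[[length(stages) + 1L]] <-
        data.frame(r = r, L_bound = L_bound,
                   iterations = res$meta$iterations,
                   converged = res$meta$converged,
                   residual = res$meta$residual,
                   diverged = res$meta$diverged)
      last_r <- r
      diverged <- diverged || res$meta$diverged
      boundary_growing <- res$meta$boundary_growing
      if (diverged) break
      if (L_bound >= cap) break # equilibration criterion: L_max reached cap
    }
  }

  zeroed_above <- NA_real_
  if (!diverged && !is.na(last_r) && last_r == 0L &&
      is.finite(lmax_r[["0"]]) && lmax_r[["0"]] < cap) {
    zr <- as.integer(lmax_r[["0"]])
    a <- st$a
    if (zr < length(a)) a[(zr + 1L):length(a)] <- 0
    st <- sim_state(a, st$b, generation = st$generation, r = st$r)
    zeroed_above <- zr
  }

  structure(list(state = st,
                 stages = do.call(rbind, stages),
                 equilibrated = !diverged && !boundary_growing,
                 diverged = diverged,
                 boundary_growing = boundary_growing,
                 zeroed_above = zeroed_above,
                 generations = st$generation,
                 L_max_by_r = lmax_r),
            class = "drl_evolution")
}

#' @export
print.drl_evolution <- function(x, ...) {
  cat("<drl_evolution> ", format(x$generations, digits = 4), " generations, ",
      nrow(x$stages), " stage(s); ",
      if (x$diverged) "DIVERGED (non-equilibrating)"
      else if (x$equilibrated) "equilibrated" else "not equilibrated",
      "\n", sep = "")
  invisible(x)
}

#' Per-bin, per-process flux decomposition
#'
#' Applies the mutation kernel for a single generation (no speed-up) and
#' reports the flux into and out of every length bin split by mutational
#' process: local substitutions, local indels (expansion/contraction),
#' fission by substitution, fission by non-motif insertion, fusion by
#' substitution, and fusion by B1 deletion.  At steady state the raw net
#' flux vanishes bin by bin.  The normalized view rescales each bin so that
#' total influx and total outflux each have magnitude one (bins with no flux
#' are left unnormalized).
#'
#' @param state A [sim_state()].
#' @param subst,curve Rates.
#' @param config Kernel options.
#' @return A list of class `flux_table`: matrices `influx` and `outflux`
#'   (bins x process), their normalized counterparts, and per-bin `net` and
#'   `gross` totals.
#' @export
flux_decomposition <- function(state, subst, curve, config = sim_config()) {
  La <- length(state$a)
  o <- .kernel_opts(config)
  fl <- cpp_kernel_fluxes(state$a, state$b, subst,
                          curve$eps[seq_len(La)], curve$kap[seq_len(La)],
                          curve$iota[seq_len(La)],
                          1, o$context, o$uniform, o$ctol, TRUE)
  infl <- fl$a_in_by_process
  outf <- fl$a_out_by_process
  tin <- rowSums(infl)
  tout <- rowSums(outf)
  norm_in <- infl
  norm_out <- outf
  pos_in <- tin > 0
  pos_out <- tout > 0
  norm_in[pos_in, ] <- infl[pos_in, , drop = FALSE] / tin[pos_in]
  norm_out[pos_out, ] <- outf[pos_out, , drop = FALSE] / tout[pos_out]
  net <- tin - tout
  # uniform exponential growth mode (indels do not conserve genome size):
  # the shape-steady state has net[L] = g a[L]; the residual after removing
  # that common mode measures per-bin detailed balance of the distribution.
  g <- if (sum(state$a) > 0) sum(net) / sum(state$a) else 0
  structure(list(influx = infl, outflux = outf,
                 influx_normalized = norm_in, outflux_normalized = norm_out,
                 net = net, gross = (tin + tout) / 2,
                 growth_rate = g, net_shape = net - g * state$a),
            class = "flux_table")
}
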