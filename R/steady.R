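#' Geometric short-repeat law
#'
#' Under two-way substitutions alone the steady-state tract length
#' distribution is geometric with ratio `rho = mu / (mu + nu)`; the
#' normalization is fixed by anchoring the curve at one length (typically
#' the L = 1 bin of a reference distribution).
#'
#' @param subst A [substitution_rates()] (uses `mu`, `nu`).
#' @param anchor_L,anchor_value Anchor length and value.
#' @param L_max Largest length returned.
#' @return Numeric vector `P[1..L_max]` with `P[anchor_L] == anchor_value`.
#' @export
geometric_short <- function(subst, anchor_L = 1L, anchor_value = 1,
                            L_max = 30L) {
  if (subst$mu + subst$nu <= 0)
    stop("undefined: mu + nu must be positive", call. = FALSE)
  rho <- subst$mu / (subst$mu + subst$nu)
  anchor_value * rho^(seq_len(L_max) - anchor_L)
}

#' Length at which contraction overtakes expansion
#'
#' For power-law families the crossing has the closed form
#' `L* = 9 (c_eps / c_kap)^(1 / delta_tau)`; generically it is the crossing
#' of the two rate curves at `L >= 8` (possibly non-integer, found on a log
#' grid).  `NA` marks an undefined crossing (symmetric rates, or
#' `delta_tau <= 0`).
#'
#' @param x A [param_spec()] (closed form) or [rate_curve()] (numeric
#'   crossing).
#' @param emp_rates Empirical rates (multiplier families).
#' @return The crossing length, or `NA_real_`.
#' @export
find_Lstar <- function(x, emp_rates = empirical_rates_mono_a()) {
  if (inherits(x, "param_spec")) {
    dt <- delta_tau(x)
    if (dt <= 0) return(NA_real_)
    if (x$family %in% c("symmetric_power", "symmetric_log")) return(NA_real_)
    if (x$family == "pure_power") {
      # mu (L/le)^te = nu (L/lk)^tk
      th <- x$theta
      s <- substitution_rates()
      num <- log(s$nu) - log(s$mu) +
        th[["tau_eps"]] * log(th[["lambda_eps"]]) -
        th[["tau_kap"]] * log(th[["lambda_kap"]])
      return(unname(exp(-num / (th[["tau_eps"]] - th[["tau_kap"]]))))
    }
    cc <- rate_constants_at_9(x, emp_rates)
    if (cc[["c_eps"]] < cc[["c_kap"]]) return(NA_real_)
    return(unname(9 * (cc[["c_eps"]] / cc[["c_kap"]])^(1 / dt)))
  }
  stopifnot(inherits(x, "rate_curve"))
  L <- seq_along(x$eps)
  d <- log(x$kap) - log(x$eps)
  ok <- L >= 8 & is.finite(d)
  idx <- which(ok & d >= 0)
  idx <- idx[idx > 8]
  if (!length(idx)) return(NA_real_)
  i2 <- idx[1L]
  i1 <- i2 - 1L
  if (i1 < 8 || !is.finite(d[i1]) || d[i1] > 0) return(as.numeric(i2))
  # log-linear interpolation of the sign change
  i1 + (0 - d[i1]) / (d[i2] - d[i1])
}

#' Truncation length of a genome-scale DRL
#'
#' The smallest length at which the expected tract count drops below one,
#' log-interpolated between the bracketing integer bins.  If the count never
#' drops below one within the support, `Inf` is returned (boundary marker).
#'
#' @param counts A [drl()] or numeric count vector at genome scale.
#' @return Truncation length (possibly non-integer), or `Inf`.
#' @export
find_Ltrunc <- function(counts) {
  x <- if (inherits(counts, "drl")) counts$counts else as.numeric(counts)
  below <- which(x < 1)
  below <- below[below > 1]
  if (!length(below)) return(Inf)
  i2 <- below[1L]
  i1 <- i2 - 1L
  if (i1 < 1 || x[i1] < 1) return(as.numeric(i2))
  if (x[i2] <= 0) return(as.numeric(i2))
  i1 + log(x[i1]) / (log(x[i1]) - log(x[i2]))
}

# continuum per-target rate functions and derivatives for a power-law spec:
# eps(L) = eps0 L^te, kap(L) = kap0 L^tk, iota(L) = iota0 L^te
.continuum_rates <- function(spec, emp_rates = empirical_rates_mono_a()) {
  if (!spec$family %in% c("symmetric_power", "decoupled_power",
                          "shared_exponent_power", "shared_constant_power",
                          "multiplier_coupled_power", "pure_power"))
    stop("continuum steady-state solutions require a power-law family",
         call. = FALSE)
  th <- spec$theta
  if (spec$family == "pure_power") {
    s <- substitution_rates()
    te <- th[["tau_eps"]]; tk <- th[["tau_kap"]]
    eps0 <- s$mu / th[["lambda_eps"]]^te
    kap0 <- s$nu / th[["lambda_kap"]]^tk
  } else {
    cc <- rate_constants_at_9(spec, emp_rates)
    te <- if ("tau_eps" %in% names(th)) th[["tau_eps"]] else th[["tau"]]
    tk <- if ("tau_kap" %in% names(th)) th[["tau_kap"]] else th[["tau"]]
    eps0 <- cc[["c_eps"]] / 9^te
    kap0 <- cc[["c_kap"]] / 9^tk
  }
  list(eps0 = unname(eps0), kap0 = unname(kap0), iota0 = unname(eps0) / 100,
       te = unname(te), tk = unname(tk))
}

#' Numerical steady-state solutions of the long-repeat balance
#'
#' Solves, on `[9, L_end]`, the continuum steady-state equation for the
#' long-repeat distribution under three nested approximations:
#' \describe{
#'   \item{local_only}{diffusion + directional flux from expansions and
#'     contractions only (second order);}
#'   \item{local_plus_fission_out}{adds the loss of length-L tracts to
#'     fission by interior substitution and non-motif insertion (second
#'     order);}
#'   \item{full_no_fusion}{also includes the gain from fissions of longer
#'     tracts, recast as a third-order ODE by one overall length
#'     derivative, closed with the zero-net-flux constraint.}
#' }
#' The equations are linear in P, so the boundary-value problem is solved
#' exactly by superposing basis solutions of initial-value integrations and
#' matching the point constraints (values taken from a reference DRL at
#' `round(L*)`, the integer bracketing `L_trunc`, and — for the third-order
#' equation — at `L_trunc - 1`).
#'
#' @param spec A power-law [param_spec()].
#' @param subst A [substitution_rates()] (`fission` enters the fission
#'   terms as the interior-substitution rate).
#' @param approximation One of "local_only", "local_plus_fission_out",
#'   "full_no_fusion".
#' @param constraints A data frame / list with `L` and `value` (2 rows for
#'   the second-order equations, 3 for the third-order one).
#' @param L_end Upper end of the solution domain.
#' @param n_grid Output grid resolution.
#' @param emp_rates Empirical rates (for multiplier families).
#' @return A list with `L`, `P`, `constraint_error` (max relative error at
#'   the constraints) and `approximation`.
#' @export
solve_steady_ode <- function(spec, subst,
                             approximation = c("local_only",
                                               "local_plus_fission_out",
                                               "full_no_fusion"),
                             constraints, L_end = NULL, n_grid = 200L,
                             emp_rates = empirical_rates_mono_a()) {
  approximation <- match.arg(approximation)
  cr <- .continuum_rates(spec, emp_rates)
  if (cr$tk <= cr$te)
    stop("steady-state solutions require delta_tau > 0", call. = FALSE)
  nu_f <- subst$fission
  Lc <- constraints$L
  vc <- constraints$value
  order_needed <- if (approximation == "full_no_fusion") 3L else 2L
  if (length(Lc) != order_needed)
    stop("need ", order_needed, " constraints for ", approximation,
         call. = FALSE)
  if (is.null(L_end)) L_end <- max(Lc) + 2
  L0 <- 9

  e0 <- cr$eps0; k0 <- cr$kap0; i0 <- cr$iota0; te <- cr$te; tk <- cr$tk
  A  <- function(L) e0 * L^(1 + te) + k0 * L^(1 + tk)
  A1 <- function(L) e0 * (1 + te) * L^te + k0 * (1 + tk) * L^tk
  A2 <- function(L) e0 * (1 + te) * te * L^(te - 1) +
                    k0 * (1 + tk) * tk * L^(tk - 1)
  A3 <- function(L) e0 * (1 + te) * te * (te - 1) * L^(te - 2) +
                    k0 * (1 + tk) * tk * (tk - 1) * L^(tk - 2)
  B  <- function(L) e0 * L^(1 + te) - k0 * L^(1 + tk)
  B1 <- function(L) e0 * (1 + te) * L^te - k0 * (1 + tk) * L^tk
  B2 <- function(L) e0 * (1 + te) * te * L^(te - 1) -
                    k0 * (1 + tk) * tk * L^(tk - 1)
  has_fission <- approximation != "local_only"
  Cf <- function(L) if (has_fission) (nu_f + i0 * L^te) * L else 0 * L
  C1 <- function(L) if (has_fission) nu_f + i0 * (1 + te) * L^te else 0 * L
  Dt <- function(L) 2 * (nu_f + i0 * L^te)

  if (order_needed == 2L) {
    deriv <- function(L, y, parms) {
      P <- y[1L]; dP <- y[2L]
      d2 <- (2 * (B(L) - A1(L)) * dP +
               (2 * B1(L) + 2 * Cf(L) - A2(L)) * P) / A(L)
      list(c(dP, d2))
    }
  } else {
    deriv <- function(L, y, parms) {
      P <- y[1L]; dP <- y[2L]; d2P <- y[3L]
      d3 <- ((2 * B(L) - 3 * A1(L)) * d2P +
             (4 * B1(L) + 2 * Cf(L) - 3 * A2(L)) * dP +
             (2 * B2(L) + 2 * C1(L) + 2 * Dt(L) - A3(L)) * P) / A(L)
      list(c(dP, d2P, d3))
    }
  }

  times <- sort(unique(c(seq(L0, L_end, length.out = n_grid), Lc)))
  scale0 <- max(vc)
  basis <- lapply(seq_len(order_needed), function(j) {
    y0 <- numeric(order_needed)
    y0[j] <- scale0
    sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12 * scale0)
    sol
  })
  # match constraints: columns are basis P-values at the constraint lengths
  M <- vapply(basis, function(sol) {
    stats::approx(sol[, 1L], sol[, 2L], xout = Lc)$y
  }, numeric(length(Lc)))
  M <- matrix(M, nrow = length(Lc))
  coef <- tryCatch(solve(M, vc), error = function(e)
    stop("solver non-convergence: constraint system singular (",
         conditionMessage(e), ")", call. = FALSE))
  P <- Reduce(`+`, Map(function(sol, cf) cf * sol[, 2L], basis,
                       as.list(coef)))
  Pc <- stats::approx(times, P, xout = Lc)$y
  cerr <- max(abs(Pc - vc) / pmax(abs(vc), 1e-300))
  list(L = times, P = P, constraint_error = cerr,
       approximation = approximation, coefficients = coef)
}

#' Default constraints for the steady-state solver from a reference DRL
#'
#' Values are read from the reference (computational) DRL at `round(L*)`
#' and at the integer just below `L_trunc`; the third-order equation adds
#' the bin one below that.
#'
#' @param ref_counts Genome-scale reference counts (e.g. the late-time
#'   kernel DRL).
#' @param L_star,L_trunc Diagnostics (see [find_Lstar()], [find_Ltrunc()]).
#' @param order 2 or 3 constraints.
#' @return Data frame with `L`, `value`.
#' @export
ode_constraints <- function(ref_counts, L_star, L_trunc, order = 2L) {
  x <- if (inherits(ref_counts, "drl")) ref_counts$counts else ref_counts
  L1 <- max(10L, round(L_star))
  L2 <- floor(L_trunc)
  Ls <- if (order == 3L) c(L1, L2, L2 - 1L) else c(L1, L2)
  Ls <- pmin(pmax(Ls, 10L), length(x))
  data.frame(L = Ls, value = x[Ls])
}

#' Dynamical regime classification
#'
#' Classifies a parameter combination by `delta_tau = tau_kap - tau_eps`
#' using the empirical regime boundaries established for multiplier ~4:
#' non-equilibrating for `delta_tau <= 0` (including the symmetric edge
#' case, which is asymptotically expansion-biased), weak contraction bias
#' below 0.7, moderate up to 1.5, strong above.  Also reports `L*`,
#' `delta_tau`, and (when a genome-scale DRL is supplied) `L_trunc`.
#'
#' @param spec A [param_spec()].
#' @param drl_counts Optional genome-scale counts for `L_trunc`.
#' @param thresholds Regime boundaries `c(weak_upper, strong_lower)`.
#' @param emp_rates Empirical rates.
#' @return A list with `regime`, `delta_tau`, `L_star`, `L_trunc`.
#' @export
classify_regime <- function(spec, drl_counts = NULL,
                            thresholds = c(0.7, 1.5),
                            emp_rates = empirical_rates_mono_a()) {
  dt <- delta_tau(spec)
  regime <- if (dt <= 0) "non_equilibrating"
            else if (dt < thresholds[1L]) "weak_contraction"
            else if (dt < thresholds[2L]) "moderate_contraction"
            else "strong_contraction"
  list(regime = regime, delta_tau = dt,
       L_star = find_Lstar(spec, emp_rates),
       L_trunc = if (is.null(drl_counts)) NA_real_
                 else find_Ltrunc(drl_counts))
}
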