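#' Context-dependent substitution rates for the binary repeat genome
#'
#' Per-generation, per-target substitution rates classified by trinucleotide
#' context for a focal motif ("A" = a motif unit, "B" = anything else):
#' repeat-lengthening (BBA>BAA / ABB>AAB), repeat-shortening (AAB>ABB /
#' BAA>BBA), fusion (ABA>AAA), fission (AAA>ABA), single-unit creation
#' (BBB>BAB) and loss (BAB>BBB); plus B-string indel rates: BB>BBB insertion,
#' BBB>BB deletion, and ABA>AA deletion of a single interrupting unit (a
#' fusion-causing indel).  Defaults are the mono-A estimates from pooled
#' parent-offspring trio data.  All rates are length independent.
#'
#' `mu` and `nu` denote the unit-adding (lengthening) and unit-removing
#' (shortening) substitution rates; their ratio sets the geometric short-
#' repeat law P(L) proportional to (mu/(mu+nu))^L.
#'
#' @param lengthen,shorten,fission,fusion,create_a1,destroy_a1 Substitution
#'   rates per target per generation.
#' @param b_insert,b_delete,b1_delete B-string indel rates per target per
#'   generation.
#' @return A `subst_rates` object (named list; also carries `mu`, `nu`).
#' @export
substitution_rates <- function(lengthen = 4.58e-9,
                               shorten = 7.74e-9,
                               fusion = 2.74e-9,
                               fission = 4.35e-9,
                               create_a1 = 3.80e-9,
                               destroy_a1 = 6.17e-9,
                               b_insert = 1.38e-10,
                               b_delete = 4.37e-12,
                               b1_delete = 2.76e-10) {
  x <- list(lengthen = lengthen, shorten = shorten, fission = fission,
            fusion = fusion, create_a1 = create_a1, destroy_a1 = destroy_a1,
            b_insert = b_insert, b_delete = b_delete, b1_delete = b1_delete)
  bad <- vapply(x, function(v) !is.numeric(v) || length(v) != 1L ||
                  is.na(v) || v < 0 || v > 1, logical(1))
  if (any(bad))
    stop("substitution rates must be single values in [0, 1]: ",
         paste(names(x)[bad], collapse = ", "), call. = FALSE)
  x$mu <- x$lengthen
  x$nu <- x$shorten
  class(x) <- "subst_rates"
  x
}

#' Uniform two-way substitution model
#'
#' A `subst_rates` object in which every A->B context has rate `alpha` and
#' every B->A context rate `beta`, with B-indel rates zero.  Under this model
#' the binary genome evolves as independent two-way point mutation and the
#' steady-state tract length distribution is exactly geometric with ratio
#' `beta / (alpha + beta)`.
#'
#' @param alpha A->B substitution rate per site per generation.
#' @param beta B->A substitution rate per site per generation.
#' @export
two_way_rates <- function(alpha = 7.74e-9, beta = 4.58e-9) {
  substitution_rates(lengthen = beta, shorten = alpha,
                     fusion = beta, fission = alpha,
                     create_a1 = beta, destroy_a1 = alpha,
                     b_insert = 0, b_delete = 0, b1_delete = 0)
}

#' Equilibrium motif-unit fraction implied by substitution rates
#' @param subst A [substitution_rates()] object.
#' @return `mu / (mu + nu)`.
#' @export
p_repeat_unit <- function(subst) subst$mu / (subst$mu + subst$nu)

#' Length-dependent instability rate curves
#'
#' Per-target, per-generation rates of expansion (`eps`), contraction
#' (`kap`) and non-motif insertion (`iota`) at tract lengths 1..`L_bound`.
#'
#' @param eps,kap,iota Numeric vectors of equal length (rate at `L = i`).
#' @param provenance Character vector ("empirical", "parameterized",
#'   "interpolated") per length.
#' @export
rate_curve <- function(eps, kap, iota = eps / 100,
                       provenance = rep("parameterized", length(eps))) {
  stopifnot(length(kap) == length(eps), length(iota) == length(eps))
  if (any(eps < 0) || any(kap < 0) || any(iota < 0) ||
      anyNA(eps) || anyNA(kap) || anyNA(iota))
    stop("rates must be nonnegative and finite", call. = FALSE)
  structure(list(eps = as.numeric(eps), kap = as.numeric(kap),
                 iota = as.numeric(iota),
                 provenance = rep(provenance, length.out = length(eps))),
            class = "rate_curve")
}

#' @export
print.rate_curve <- function(x, ...) {
  cat("<rate_curve> L = 1..", length(x$eps), "; eps(9) = ",
      signif(x$eps[min(9L, length(x$eps))], 3), ", kap(9) = ",
      signif(x$kap[min(9L, length(x$kap))], 3), "\n", sep = "")
  invisible(x)
}

#' Synthetic stand-in for the empirical mono-A indel rate estimates (L = 1-8)
#'
#' The low-length expansion/contraction/non-motif-insertion rates that anchor
#' every parameterization are estimated from trio sequencing in the source
#' datasets; those per-length tables are not redistributable here, so the
#' package ships a synthetic stand-in constructed from printed constraints:
#' a rapid rise between roughly L = 5 and 10, a slight expansion bias at
#' L = 8 (eps(8) = 1.1e-8 vs kap(8) = 7.0e-9, consistent with the
#' maximum-posterior rate constants at L = 9 via the multiplier coupling),
#' non-motif insertion at 1% of expansion, and no contraction or interruption
#' of a single-unit tract (kap(1) = iota(1) = 0).
#'
#' @return A [rate_curve()] covering L = 1..8 with provenance "empirical".
#' @export
empirical_rates_mono_a <- function() {
  path <- system.file("extdata", "synthetic_mono_a_empirical_rates.tsv",
                      package = "drldyn")
  tab <- utils::read.delim(path, comment.char = "#")
  tab <- tab[order(tab$tract_length_units), ]
  rate_curve(eps = tab$expansion, kap = tab$contraction,
             iota = tab$non_motif_insertion,
             provenance = rep("empirical", nrow(tab)))
}

.families <- c("symmetric_power", "decoupled_power", "shared_exponent_power",
               "shared_constant_power", "multiplier_coupled_power",
               "symmetric_log", "decoupled_log", "multiplier_coupled_log",
               "pure_power")

.family_params <- list(
  symmetric_power = c("c", "tau"),
  decoupled_power = c("c_eps", "c_kap", "tau_eps", "tau_kap"),
  shared_exponent_power = c("c_eps", "c_kap", "tau"),
  shared_constant_power = c("c", "tau_eps", "tau_kap"),
  multiplier_coupled_power = c("m", "tau_eps", "tau_kap"),
  symmetric_log = c("c", "tau"),
  decoupled_log = c("c_eps", "c_kap", "tau_eps", "tau_kap"),
  multiplier_coupled_log = c("m", "tau_eps", "tau_kap"),
  pure_power = c("lambda_eps", "lambda_kap", "tau_eps", "tau_kap"))

#' Parameter specification for an instability-rate family
#'
#' @param family One of the nested rate parameterization families:
#'   `r paste0('"', .families, '"', collapse = ", ")`.
#' @param theta Named (or positional) numeric parameter vector; see
#'   [build_rate_table()] for the functional forms.
#' @export
param_spec <- function(family, theta) {
  family <- match.arg(family, .families)
  wanted <- .family_params[[family]]
  if (is.null(names(theta))) names(theta) <- wanted
  if (length(theta) != length(wanted) || !all(wanted %in% names(theta)))
    stop("family '", family, "' needs parameters (",
         paste(wanted, collapse = ", "), ")", call. = FALSE)
  theta <- theta[wanted]
  consts <- setdiff(wanted, c("tau", "tau_eps", "tau_kap"))
  if (any(theta[consts] <= 0))
    stop("constants must be > 0", call. = FALSE)
  structure(list(family = family, theta = theta), class = "param_spec")
}

#' Contraction-minus-expansion exponent difference
#' @param spec A [param_spec()].
#' @return `tau_kap - tau_eps` (0 for symmetric families).
#' @export
delta_tau <- function(spec) {
  th <- spec$theta
  if (all(c("tau_eps", "tau_kap") %in% names(th)))
    unname(th[["tau_kap"]] - th[["tau_eps"]])
  else 0
}

#' Build a full length-dependent rate table from a parameterization
#'
#' Combines empirical rates at L = 1..8 with the family's functional form at
#' L > 8 (power laws in L/9 or in log2(L-7), with shared, decoupled or
#' multiplier-coupled constants/exponents).  The `pure_power` family ignores
#' the empirical rates and parameterizes all lengths via the lengths
#' `lambda_eps`, `lambda_kap` at which each rate crosses the corresponding
#' substitution rate: eps(L) = mu (L/lambda_eps)^tau_eps and
#' kap(L) = nu (L/lambda_kap)^tau_kap.  Non-motif insertion is tied to
#' expansion at 1% of its rate wherever parameterized (empirical values are
#' kept below L = 9).
#'
#' @param spec A [param_spec()].
#' @param empirical A [rate_curve()] covering at least L = 1..8 (ignored by
#'   `pure_power`).
#' @param L_bound Largest tract length of the table.
#' @param subst A [substitution_rates()] supplying `mu`, `nu` for
#'   `pure_power`.
#' @return A [rate_curve()] of length `L_bound`.
#' @export
build_rate_table <- function(spec, empirical = empirical_rates_mono_a(),
                             L_bound = 200L,
                             subst = substitution_rates()) {
  stopifnot(inherits(spec, "param_spec"))
  th <- spec$theta
  L <- seq_len(L_bound)
  fam <- spec$family

  if (fam == "pure_power") {
    eps <- subst$mu * (L / th[["lambda_eps"]])^th[["tau_eps"]]
    kap <- subst$nu * (L / th[["lambda_kap"]])^th[["tau_kap"]]
    return(rate_curve(eps, kap, iota = eps / 100,
                      provenance = rep("parameterized", L_bound)))
  }

  if (!inherits(empirical, "rate_curve") || length(empirical$eps) < 8L)
    stop("configuration error: family '", fam,
         "' requires empirical rates for L = 1..8", call. = FALSE)
  eps <- kap <- iota <- numeric(L_bound)
  n0 <- min(8L, L_bound)
  eps[1:n0] <- empirical$eps[1:n0]
  kap[1:n0] <- empirical$kap[1:n0]
  iota[1:n0] <- empirical$iota[1:n0]
  prov <- c(rep("empirical", n0), rep("parameterized", max(0L, L_bound - n0)))
  if (L_bound > 8L) {
    Lhi <- 9:L_bound
    g <- switch(fam,
      symmetric_power = ,
      decoupled_power = ,
      shared_exponent_power = ,
      shared_constant_power = ,
      multiplier_coupled_power = (Lhi / 9),
      symmetric_log = ,
      decoupled_log = ,
      multiplier_coupled_log = log(Lhi - 7) / log(2))
    ehi <- switch(fam,
      symmetric_power = th[["c"]] * g^th[["tau"]],
      decoupled_power = th[["c_eps"]] * g^th[["tau_eps"]],
      shared_exponent_power = th[["c_eps"]] * g^th[["tau"]],
      shared_constant_power = th[["c"]] * g^th[["tau_eps"]],
      multiplier_coupled_power = empirical$eps[8L] * th[["m"]] * g^th[["tau_eps"]],
      symmetric_log = th[["c"]] * g^th[["tau"]],
      decoupled_log = th[["c_eps"]] * g^th[["tau_eps"]],
      multiplier_coupled_log = empirical$eps[8L] * th[["m"]] * g^th[["tau_eps"]])
    khi <- switch(fam,
      symmetric_power = ehi,
      decoupled_power = th[["c_kap"]] * g^th[["tau_kap"]],
      shared_exponent_power = th[["c_kap"]] * g^th[["tau"]],
      shared_constant_power = th[["c"]] * g^th[["tau_kap"]],
      multiplier_coupled_power = empirical$kap[8L] * th[["m"]] * g^th[["tau_kap"]],
      symmetric_log = ehi,
      decoupled_log = th[["c_kap"]] * g^th[["tau_kap"]],
      multiplier_coupled_log = empirical$kap[8L] * th[["m"]] * g^th[["tau_kap"]])
    eps[Lhi] <- ehi
    kap[Lhi] <- khi
    iota[Lhi] <- ehi / 100
  }
  rate_curve(eps, kap, iota, provenance = prov)
}

#' Effective rate constants at L = 9 for a parameterization
#'
#' Returns `c(c_eps, c_kap)`, the expansion and contraction rates the family
#' prescribes at L = 9 (the first parameterized bin), used by the
#' steady-state machinery and the priors.
#' @param spec A [param_spec()].
#' @param empirical Empirical rates (for multiplier families).
#' @export
rate_constants_at_9 <- function(spec, empirical = empirical_rates_mono_a()) {
  th <- spec$theta
  switch(spec$family,
    symmetric_power = ,
    symmetric_log = c(c_eps = unname(th[["c"]]), c_kap = unname(th[["c"]])),
    shared_constant_power = c(c_eps = unname(th[["c"]]), c_kap = unname(th[["c"]])),
    decoupled_power = ,
    decoupled_log = ,
    shared_exponent_power = c(c_eps = unname(th[["c_eps"]]),
                              c_kap = unname(th[["c_kap"]])),
    multiplier_coupled_power = ,
    multiplier_coupled_log = c(c_eps = unname(th[["m"]]) * empirical$eps[8L],
                               c_kap = unname(th[["m"]]) * empirical$kap[8L]),
    pure_power = stop("pure_power has no L = 9 anchor constants", call. = FALSE))
}

#' Smooth the empirical-to-parameterized rate jump by interpolation
#'
#' Replaces the rates at L = 9..(8 + `join_window`) with a monotone log-log
#' interpolation between the empirical value at L = 8 and the parameterized
#' value at L = 9 + `join_window`, removing the discrete jump the multiplier
#' introduces.  If there is no jump (the rate at 9 already equals the rate at
#' 8) or the window has width zero, the curve is returned unchanged.
#'
#' @param curve A [rate_curve()].
#' @param join_window Width (number of bins at and above L = 9) to replace.
#' @return A [rate_curve()].
#' @export
interpolate_rates <- function(curve, join_window = 4L) {
  stopifnot(inherits(curve, "rate_curve"))
  w <- as.integer(join_window)
  if (w <= 0L || length(curve$eps) < 9L + w) return(curve)
  smooth1 <- function(rate) {
    if (rate[9L] <= 0 || rate[8L] <= 0) return(rate)
    if (abs(log(rate[9L] / rate[8L])) < 1e-12) return(rate)
    Lrep <- 9:(8L + w)
    lr <- log(rate[8L]) +
      (log(rate[9L + w]) - log(rate[8L])) *
      (log(Lrep) - log(8)) / (log(9 + w) - log(8))
    rate[Lrep] <- exp(lr)
    rate
  }
  eps <- smooth1(curve$eps)
  kap <- smooth1(curve$kap)
  iota <- curve$iota
  changed <- which(eps != curve$eps | kap != curve$kap)
  iota[changed] <- eps[changed] / 100
  prov <- curve$provenance
  prov[changed] <- "interpolated"
  rate_curve(eps, kap, iota, provenance = prov)
}

#' Default inference grids
#'
#' Log-spaced rate constants over 1e-9..1e-6, linear exponent grids on 0..4
#' (step 0.1 by default), the multiplier ladder 1, 1.6, 2.5, 4, 6.4, 10, and
#' integer onset lengths 4..20 for the pure-power family.  All grids are
#' plain numeric vectors and can be replaced freely.
#'
#' @param what One of "constant", "tau", "m", "lambda".
#' @param n For "constant", number of log-spaced points.
#' @param step For "tau", grid step.
#' @export
default_grid <- function(what = c("constant", "tau", "m", "lambda"),
                         n = 25L, step = 0.1) {
  what <- match.arg(what)
  switch(what,
         constant = 10^seq(-9, -6, length.out = n),
         tau = seq(0, 4, by = step),
         m = c(1.0, 1.6, 2.5, 4.0, 6.4, 10),
         lambda = 4:20)
}
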