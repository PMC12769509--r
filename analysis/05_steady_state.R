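#!/usr/bin/env Rscript
# Stage 5: analytic characterization of the steady state.
#
# Solves the three nested continuum approximations of the long-repeat
# balance against the kernel's late-time DRL in each contraction-bias
# regime, and writes the composite (geometric + continuum) reconstruction.
library(drldyn)
dir.create("results", showWarnings = FALSE)

subst <- substitution_rates()
emp <- empirical_rates_mono_a()
init <- initialize_state(3.1e9, subst)
cfg <- sim_config(conv_tol = 1e-4, check_every = 2000)

sets <- list(strong = c(m = 4, tau_eps = 0.25, tau_kap = 3.25),
             moderate = c(m = 4, tau_eps = 1.25, tau_kap = 2.25),
             weak = c(m = 4, tau_eps = 1.6, tau_kap = 1.9))

rows <- list()
for (nm in names(sets)) {
  spec <- param_spec("multiplier_coupled_power", sets[[nm]])
  curve <- build_rate_table(spec, emp, 200, subst)
  ev <- evolve(init, subst, curve, cfg)
  a <- ev$state$a
  Lstar <- find_Lstar(spec, emp)
  Ltr <- find_Ltrunc(a)
  Lint <- 10:floor(Ltr)
  out <- data.frame(L = Lint, kernel = a[Lint])
  for (ap in c("local_only", "local_plus_fission_out", "full_no_fusion")) {
    ord <- if (ap == "full_no_fusion") 3L else 2L
    sol <- solve_steady_ode(spec, subst, ap,
                            ode_constraints(a, Lstar, Ltr, ord))
    out[[ap]] <- approx(sol$L, sol$P, xout = Lint)$y
    rows[[paste(nm, ap)]] <- data.frame(
      set = nm, approximation = ap,
      max_rel_dev = max(abs(out[[ap]] - a[Lint]) / a[Lint]))
  }
  # composite: geometric law below the instability onset
  geo <- geometric_short(subst, 1, a[1], 9)
  write.table(rbind(data.frame(L = 1:9, kernel = a[1:9], local_only = NA,
                               local_plus_fission_out = NA,
                               full_no_fusion = NA, geometric = geo),
                    cbind(out, geometric = NA)),
              sprintf("results/05_steady_state_%s.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
sm <- do.call(rbind, rows)
write.table(sm, "results/05_approximation_accuracy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(sm, row.names = FALSE)
cat("\nThe nested pattern: the full (third-order) balance tracks the kernel\n",
    "in every equilibrating regime; dropping fission-in fails in the weak\n",
    "regime; dropping all fission also fails in the moderate regime.\n")
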