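test_that("KL divergence matches hand computation and is asymmetric", {
  cfg <- inference_config(L_min = 1, L_max_kl = 2, pseudocount = 1e-12)
  emp <- c(0.5, 0.5)
  model <- c(0.25, 0.75)
  expect_equal(kl_divergence(model, emp, cfg),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-9)
  expect_equal(kl_divergence(emp, emp, cfg), 0)
  expect_false(isTRUE(all.equal(kl_divergence(model, emp, cfg),
                                kl_divergence(emp, model, cfg))))
})

test_that("KL pseudocounting renormalizes on [L_min, L_max]", {
  cfg <- inference_config(L_min = 4, L_max_kl = 50, pseudocount = 1)
  a <- drl(c(1e6, 1e5, 1e4, 5e3, 2e3, 1e3))
  # identical distributions at different overall scale are NOT zero-divergence
  # (pseudocounts weigh differently), but the same counts are
  expect_equal(kl_divergence(a, a, cfg), 0)
  b <- drl(c(1e6, 1e5, 1e4, 5e3, 2e3, 1e3, 10))
  expect_gt(kl_divergence(b, a, cfg), 0)
})

test_that("ensemble sigma follows the drop-the-worst rule", {
  base <- drl(1e4 * 0.4^(1:30) * 1e3)
  ens <- generate_primate_ensemble(base, n = 36, dispersion = 50, seed = 5,
                                   truncate_threshold = NULL)
  cfg <- inference_config(L_min = 4, L_max_kl = 30)
  kls <- vapply(ens, function(m) kl_divergence(m, base, cfg), numeric(1))
  sig <- primate_sigma(ens, base, cfg)
  expect_equal(sig, max(sort(kls)[1:34]) / 2)
  # invariant to ensemble ordering
  expect_equal(primate_sigma(rev(ens), base, cfg), sig)
  # degenerate ensemble of copies collapses sigma to zero
  copies <- replicate(5, base, simplify = FALSE)
  expect_equal(primate_sigma(copies, base, cfg), 0)
  expect_error(primate_sigma(copies[1:2], base, cfg), "degenerate")
})

test_that("the soft-rejection posterior concentrates, normalizes, flattens", {
  grid <- data.frame(tau = seq(0, 1, 0.1))
  kl <- c(0, rep(10, 10))
  pg <- posterior_grid(grid, kl, uniform_prior(11), sigma = 1)
  expect_gt(pg$posterior[1], 0.999)
  expect_equal(sum(pg$posterior), 1)
  # doubling sigma never decreases the entropy
  set.seed(4)
  kl2 <- runif(11, 0, 3)
  ent <- function(sig) {
    p <- posterior_grid(grid, kl2, uniform_prior(11), sig)$posterior
    -sum(p * log(p))
  }
  sigs <- c(0.2, 0.4, 0.8, 1.6)
  es <- vapply(sigs, ent, numeric(1))
  expect_true(all(diff(es) >= -1e-12))
  # underflow-proof: uniformly terrible fits still normalize
  pg3 <- posterior_grid(grid, rep(1e4, 11), uniform_prior(11), sigma = 1)
  expect_equal(sum(pg3$posterior), 1)
  expect_false(anyNA(pg3$posterior))
})

test_that("Bayes factors compare models consistently", {
  kl <- c(0.1, 0.2, 0.5)
  pr <- uniform_prior(3)
  bf <- bayes_factor(kl, pr, sigma = 0.3)
  expect_equal(bayes_factor_ratio(bf, bf), 1)
  expect_error(bayes_factor_ratio(bf, bayes_factor(kl, pr, sigma = 0.4)),
               "comparison error")
  # nesting: a restricted grid with the same prior weights gives the same BF
  grid4 <- expand.grid(c_eps = c(1e-8, 2e-8), c_kap = c(1e-8, 2e-8))
  kl4 <- c(0.1, 0.4, 0.4, 0.2)
  diag_cells <- grid4$c_eps == grid4$c_kap
  bf_diag <- bayes_factor(kl4[diag_cells], uniform_prior(2), sigma = 0.3)
  bf_sym <- bayes_factor(c(0.1, 0.2), uniform_prior(2), sigma = 0.3)
  expect_equal(bf_diag$bf, bf_sym$bf)
  # all divergences far beyond sigma: evidence vanishes
  expect_lt(bayes_factor(rep(100, 3), pr, sigma = 0.1)$bf, 1e-300)
})

test_that("highest density regions nest and handle ties", {
  p <- c(0.5, 0.3, 0.1, 0.06, 0.04)
  hs <- hdr(p)
  expect_true(all(hs[["0.68"]] <= hs[["0.95"]]))
  expect_true(all(hs[["0.95"]] <= hs[["0.997"]]))
  expect_equal(sum(hs[["0.68"]]), 2)
  # point mass: every level is that single cell
  hp <- hdr(c(1, 0, 0))
  expect_true(all(vapply(hp, function(m) identical(which(m), 1L), logical(1))))
  # uniform posterior: 0.95 level needs ceiling(0.95 n) cells
  hu <- hdr(rep(1 / 20, 20), levels = 0.95)
  expect_equal(sum(hu[["0.95"]]), 19)
})

test_that("posterior expectations are probability-weighted sums", {
  grid <- data.frame(x = c(1, 2, 3))
  pg <- posterior_grid(grid, c(0, 10, 10), uniform_prior(3), 1)
  expect_equal(posterior_expectation(pg, function(g) g$x), 1,
               tolerance = 1e-6)
  expect_equal(posterior_expectation(pg, function(g) 1), 1)
  # two-point posterior: convex combination of the two member vectors
  pg2 <- posterior_grid(data.frame(x = 1:2), c(0.1, 0.1), uniform_prior(2), 1)
  f <- matrix(c(1, 0, 0, 1), nrow = 2, byrow = TRUE)
  expect_equal(posterior_expectation(pg2, f), c(0.5, 0.5))
})

test_that("model comparison prefers the generating family", {
  # data generated under decoupled rates with delta_tau > 0: the decoupled
  # family must dominate the symmetric null by a large Bayes factor ratio
  s <- substitution_rates()
  emp <- empirical_rates_mono_a()
  init <- initialize_state(3.1e9, s)
  sim <- sim_config(schedule = data.frame(r = 3:0,
                                          iterations = c(1e6, 1e5, 1e5, 1e5)),
                    conv_tol = 1e-4, check_every = 2000, diverge_factor = 10)
  truth_cv <- build_rate_table(param_spec("decoupled_power",
                                          c(c_eps = 4.4e-8, c_kap = 2.8e-8,
                                            tau_eps = 1.6, tau_kap = 2.0)),
                               emp, 200, s)
  tev <- evolve(init, s, truth_cv, sim)
  target <- drl(tev$state$a, "A", "decoupled truth")
  ens <- generate_primate_ensemble(target, n = 12, dispersion = 100, seed = 2)
  cfg <- inference_config()
  sigma <- primate_sigma(ens, target, cfg)
  taus <- c(1.2, 1.6, 2.0, 2.4)
  gde <- expand.grid(c_eps = 4.4e-8, c_kap = 2.8e-8,
                     tau_eps = taus, tau_kap = taus)
  gsy <- data.frame(c = c(2.8e-8, 4.4e-8, 6e-8))
  gsy <- merge(gsy, data.frame(tau = taus))
  pde <- infer_grid("decoupled_power", gde, target, sigma = sigma,
                    cfg = cfg, init = init, subst = s, emp_rates = emp,
                    sim = sim)
  psy <- infer_grid("symmetric_power", gsy, target, sigma = sigma,
                    cfg = cfg, init = init, subst = s, emp_rates = emp,
                    sim = sim)
  expect_equal(unlist(pde$max_posterior[c("tau_eps", "tau_kap")]),
               c(tau_eps = 1.6, tau_kap = 2.0))
  expect_gt(exp(pde$bf$log_bf - psy$bf$log_bf), 1e3)
})
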