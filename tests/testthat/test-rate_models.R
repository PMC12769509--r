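test_that("rate table families follow their functional forms", {
  emp <- empirical_rates_mono_a()
  # multiplier coupling: eps(9) = m eps(8)
  sp <- param_spec("multiplier_coupled_power", c(m = 4, tau_eps = 1.6, tau_kap = 2.0))
  cv <- build_rate_table(sp, emp, 30)
  expect_equal(cv$eps[9], 4 * emp$eps[8])
  expect_equal(cv$kap[9], 4 * emp$kap[8])
  expect_equal(cv$eps[1:8], emp$eps[1:8])
  # symmetric power law: eps == kap above 8
  sy <- build_rate_table(param_spec("symmetric_power", c(c = 3e-8, tau = 1.5)),
                         emp, 40)
  expect_equal(sy$eps[9:40], sy$kap[9:40])
  expect_equal(sy$eps[9], 3e-8)
  # pure power law hits the substitution rate at lambda
  s <- substitution_rates()
  pp <- build_rate_table(param_spec("pure_power",
                                    c(lambda_eps = 9, lambda_kap = 13,
                                      tau_eps = 3.6, tau_kap = 4.0)),
                         emp, 40, subst = s)
  expect_equal(pp$eps[9], s$mu)
  expect_equal(pp$kap[13], s$nu)
  # iota tied at 1% of expansion where parameterized
  expect_equal(cv$iota[9:30], cv$eps[9:30] / 100)
  # log families anchor their constant at L = 9 (log2(9-7)/log2 = 1)
  lg <- build_rate_table(param_spec("symmetric_log", c(c = 2e-8, tau = 0.9)),
                         emp, 30)
  expect_equal(lg$eps[9], 2e-8)
  expect_error(param_spec("symmetric_power", c(c = -1, tau = 1)), "> 0")
  expect_error(param_spec("multiplier_coupled_power", c(m = 4)), "needs")
  expect_error(build_rate_table(sp, rate_curve(1e-9, 1e-9, 1e-11), 30),
               "empirical")
})

test_that("families nest: decoupled with equal parameters = symmetric", {
  emp <- empirical_rates_mono_a()
  de <- build_rate_table(param_spec("decoupled_power",
                                    c(c_eps = 3e-8, c_kap = 3e-8,
                                      tau_eps = 1.7, tau_kap = 1.7)), emp, 60)
  sy <- build_rate_table(param_spec("symmetric_power",
                                    c(c = 3e-8, tau = 1.7)), emp, 60)
  expect_equal(de$eps, sy$eps)
  expect_equal(de$kap, sy$kap)
  # multiplier model is the decoupled model at c = m * rate(8)
  m <- 3.2
  mu <- build_rate_table(param_spec("multiplier_coupled_power",
                                    c(m = m, tau_eps = 1.2, tau_kap = 2.2)),
                         emp, 60)
  de2 <- build_rate_table(param_spec("decoupled_power",
                                     c(c_eps = m * emp$eps[8],
                                       c_kap = m * emp$kap[8],
                                       tau_eps = 1.2, tau_kap = 2.2)), emp, 60)
  expect_equal(mu$eps, de2$eps)
  expect_equal(mu$kap, de2$kap)
  # delta_tau accessor
  expect_equal(delta_tau(param_spec("multiplier_coupled_power",
                                    c(m = 4, tau_eps = 1.6, tau_kap = 2.0))),
               0.4)
  expect_equal(delta_tau(param_spec("symmetric_power", c(c = 1e-8, tau = 2))), 0)
  # grid-wide sanity: tables stay finite and nonnegative
  for (tau in c(0, 2, 4)) {
    cv <- build_rate_table(param_spec("shared_constant_power",
                                      c(c = 1e-6, tau_eps = tau, tau_kap = tau)),
                           emp, 200)
    expect_true(all(is.finite(cv$eps)) && all(cv$eps >= 0))
    expect_true(all(is.finite(cv$kap)) && all(cv$kap >= 0))
  }
})

test_that("interpolation smooths the empirical-parameterized jump", {
  emp <- empirical_rates_mono_a()
  sp4 <- param_spec("multiplier_coupled_power", c(m = 4, tau_eps = 1.6, tau_kap = 2.0))
  cv <- build_rate_table(sp4, emp, 60)
  sm <- interpolate_rates(cv, join_window = 4)
  # endpoints preserved, interior replaced, monotone across the window
  expect_equal(sm$eps[8], cv$eps[8])
  expect_equal(sm$eps[13], cv$eps[13])
  win <- sm$eps[8:13]
  expect_true(all(diff(win) > 0))
  expect_true(all(sm$eps[9:12] < cv$eps[9:12])) # jump pulled down
  expect_equal(sm$provenance[9], "interpolated")
  # no jump (m = 1): curve unchanged
  sp1 <- param_spec("multiplier_coupled_power", c(m = 1, tau_eps = 1.6, tau_kap = 2.0))
  cv1 <- build_rate_table(sp1, emp, 60)
  sm1 <- interpolate_rates(cv1, join_window = 4)
  expect_equal(sm1$eps, cv1$eps, tolerance = 1e-12)
  # zero-width window: unchanged
  expect_equal(interpolate_rates(cv, join_window = 0)$eps, cv$eps)
})

test_that("indel events are classified by tract context", {
  # expansion: insert one A into an A x 8 tract
  r <- classify_indel_event("insertion", "", "A",
                            "CCAAAA", "AAAACC", "A")
  expect_equal(r$category, "expansion")
  expect_equal(r$unit_delta, 1L)
  expect_equal(r$parent_tract_length, 8L)
  # contraction: delete one A from A x 8
  r <- classify_indel_event("deletion", "A", "",
                            "CCAAAA", "AAACC", "A")
  expect_equal(r$category, "contraction")
  expect_equal(r$unit_delta, -1L)
  expect_equal(r$parent_tract_length, 8L)
  # interior non-motif insertion = fission
  r <- classify_indel_event("insertion", "", "G",
                            "CCAAAA", "AAAACC", "A")
  expect_equal(r$category, "non_motif_insertion")
  expect_equal(r$parent_tract_length, 8L)
  # boundary insertion of a non-motif base does not split anything
  r <- classify_indel_event("insertion", "", "G", "CCCC", "AAAACC", "A")
  expect_equal(r$category, "other")
  # multi-unit motif: expansion and interruption of (CAG)n
  r <- classify_indel_event("insertion", "", "CAG",
                            "TTCAGCAG", "CAGCAGTT", "CAG")
  expect_equal(r$category, "expansion")
  expect_equal(r$unit_delta, 1L)
  expect_equal(r$parent_tract_length, 4L)
  r <- classify_indel_event("deletion", "CAG", "",
                            "TTCAGCAG", "CAGTT", "CAG")
  expect_equal(r$category, "contraction")
  expect_equal(r$parent_tract_length, 4L)
  r <- classify_indel_event("insertion", "", "T",
                            "TTCAGCAG", "CAGCAGTT", "CAG")
  expect_equal(r$category, "non_motif_insertion")
  # partial deletion of a unit
  r <- classify_indel_event("deletion", "CA", "",
                            "TTCAGCAG", "GCAGTT", "CAG")
  expect_equal(r$category, "partial_deletion")
})

test_that("classification round-trips generated events", {
  emp <- empirical_rates_mono_a()
  cv <- build_rate_table(param_spec("multiplier_coupled_power",
                                    c(m = 4, tau_eps = 1.6, tau_kap = 2.0)),
                         emp, 60)
  denom <- drl(3.1e9 * 0.4^2 * 0.372^(1:40))
  ev <- generate_trio_events(cv, genome = denom, n_genomes = 1e4, seed = 3)
  expect_gt(nrow(ev), 1000)
  got <- classify_indel_events(ev, "A")
  ok <- got$category == ev$truth_category &
    got$unit_delta == ev$truth_unit_delta &
    got$parent_tract_length == ev$truth_parent
  expect_gte(mean(ok), 0.999)
})

test_that("zero-rate processes yield zero events", {
  cv <- rate_curve(eps = rep(1e-7, 20), kap = rep(0, 20), iota = rep(0, 20))
  ev <- generate_trio_events(cv, genome = drl(rep(1e5, 20)),
                             n_genomes = 100, seed = 1)
  expect_true(all(ev$truth_category == "expansion"))
})

test_that("length-stratified rate estimation divides by the right targets", {
  # 10 expansions at L = 8, 1e6 repeats, 2e3 genomes, target 8
  ev <- data.frame(category = rep("expansion", 10),
                   parent_tract_length = rep(8L, 10))
  denom <- drl(c(rep(0, 7), 1e6))
  est <- estimate_length_stratified_rates(ev, denom, 2e3)
  r8 <- est$rate[est$process == "expansion" & est$tract_length_units == 8]
  expect_equal(r8, 10 / (1e6 * 2e3 * 8))
  # zero counts give rate 0 with CI lower bound 0
  r0 <- est[est$process == "contraction" & est$tract_length_units == 8, ]
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_lo, 0)
  # zero denominator is undefined, not zero
  expect_true(is.na(est$rate[est$tract_length_units == 3][1]))
  expect_true(all(est$ci_lo <= est$rate | is.na(est$rate), na.rm = TRUE))
})

test_that("estimator recovers generating rates on synthetic events", {
  emp <- empirical_rates_mono_a()
  cv <- build_rate_table(param_spec("multiplier_coupled_power",
                                    c(m = 4, tau_eps = 1.6, tau_kap = 2.0)),
                         emp, 60)
  denom <- drl(3.1e9 * 0.4^2 * 0.372^(1:50))
  ev <- generate_trio_events(cv, genome = denom, n_genomes = 2e3, seed = 8)
  est <- estimate_length_stratified_rates(
    data.frame(category = ev$truth_category,
               parent_tract_length = ev$truth_parent),
    denom, 2e3, seed = 9)
  for (p in c("expansion", "contraction")) {
    sub <- est[est$process == p & est$count >= 30, ]
    truth <- if (p == "expansion") cv$eps else cv$kap
    inside <- truth[sub$tract_length_units] >= sub$ci_lo &
      truth[sub$tract_length_units] <= sub$ci_hi
    expect_gte(mean(inside), 0.9)
  }
})

test_that("informative priors concentrate around the generating power law", {
  emp <- empirical_rates_mono_a()
  pe <- synth_population_rates(4e-8, 1.8, noise_sd = 1e-4)
  pk <- synth_population_rates(2.5e-8, 2.2, noise_sd = 1e-4, seed = 2)
  # noiseless fit recovers the generating parameters to < 1%
  f <- drldyn:::.fit_loglog(pe)
  expect_lt(abs(exp(f$logc) / 4e-8 - 1), 0.01)
  expect_lt(abs(f$tau / 1.8 - 1), 0.01)
  grid <- expand.grid(c_eps = 10^seq(-8.5, -6.5, 0.25),
                      c_kap = 10^seq(-8.5, -6.5, 0.25),
                      tau_eps = seq(0.5, 3.5, 0.5),
                      tau_kap = seq(0.5, 3.5, 0.5))
  pr <- fit_informative_prior(pe, pk, "decoupled_power", grid, inflation = 100)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  best <- grid[which.max(pr), ]
  expect_lt(abs(log(best$c_eps / 4e-8)), log(10^0.3))
  expect_lt(abs(best$tau_eps - 1.8), 0.3)
  # uniform prior alternative
  expect_equal(uniform_prior(10), rep(0.1, 10))
  expect_error(drldyn:::.fit_loglog(data.frame(tract_length_units = 1:2,
                                               rate = c(1e-8, 1e-8),
                                               se_log = 0.1)[0, ]), "fit error")
})
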