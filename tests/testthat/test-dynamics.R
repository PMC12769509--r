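test_that("fission substitution spreads fragments evenly (forced example)", {
  # single occupied bin L = 6, only the fission rate nonzero:
  # events = f * (L-2) * N; each adds 2 counts spread over bins 1..4
  f <- 1e-6
  N <- 1e4
  s <- substitution_rates(lengthen = 0, shorten = 0, fission = f, fusion = 0,
                          create_a1 = 0, destroy_a1 = 0, b_insert = 0,
                          b_delete = 0, b1_delete = 0)
  zero <- rate_curve(numeric(10), numeric(10), numeric(10))
  st <- sim_state(c(0, 0, 0, 0, 0, N, 0, 0, 0, 0), c(N, numeric(9)))
  st1 <- kernel_step(st, s, zero)
  d <- st1$a - st$a
  expect_equal(d[6], -4 * f * N)
  expect_equal(d[1:4], rep(2 * f * N, 4))
  expect_equal(d[c(5, 7:10)], numeric(5))
  # B side gains one new single-unit string per fission event
  expect_equal((st1$b - st$b)[1], 4 * f * N)
})

test_that("substitutions conserve total genome length to machine precision", {
  s <- substitution_rates(b_insert = 0, b_delete = 0, b1_delete = 0)
  # support wide enough that reflective-boundary clamping is below
  # double precision for the geometric occupancies
  st <- initialize_state(1e6, s, L_bound = 150, L_bound_b = 150,
                         pre_run = FALSE)
  zero <- rate_curve(numeric(150), numeric(150), numeric(150))
  cfg <- sim_config(conv_support_tol = 0) # exact fusion pairing
  cur <- st
  for (i in 1:5) cur <- kernel_step(cur, s, zero, r = 4, config = cfg)
  expect_equal(total_length(cur), total_length(st),
               tolerance = 1e-13)
})

test_that("expansions and contractions conserve the number of tracts", {
  s <- substitution_rates(lengthen = 0, shorten = 0, fission = 0, fusion = 0,
                          create_a1 = 0, destroy_a1 = 0, b_insert = 0,
                          b_delete = 0, b1_delete = 0)
  cv <- rate_curve(eps = rep(2e-6, 40), kap = c(0, rep(1.5e-6, 39)),
                   iota = numeric(40))
  st <- toy_state()
  cur <- st
  for (i in 1:5) cur <- kernel_step(cur, s, cv, r = 2,
                                    config = sim_config(conv_support_tol = 0))
  expect_equal(sum(cur$a), sum(st$a), tolerance = 1e-13)
  # but total length is not conserved (net expansion bias here)
  expect_gt(total_length(cur), total_length(st))
})

test_that("the geometric distribution is a fixed point under two-way rates", {
  s <- two_way_rates(alpha = 7.74e-9, beta = 4.58e-9)
  st <- initialize_state(1e9, s, L_bound = 60, L_bound_b = 60, pre_run = FALSE)
  zero <- rate_curve(numeric(60), numeric(60), numeric(60))
  st1 <- kernel_step(st, s, zero, r = 5,
                     config = sim_config(conv_support_tol = 0))
  rel <- abs(st1$a - st$a) / st$a
  expect_lt(max(rel[1:25]), 1e-9) # populated bins unchanged
})

test_that("kernel saturation precondition raises a named error", {
  s <- substitution_rates()
  cv <- rate_curve(eps = rep(1e-3, 20), kap = rep(1e-3, 20),
                   iota = numeric(20))
  st <- sim_state(rep(10, 20), rep(10, 20))
  expect_error(kernel_step(st, s, cv, r = 2), "saturation")
})

test_that("saturation length L_max behaves as specified", {
  emp <- empirical_rates_mono_a()
  cv <- build_rate_table(param_spec("multiplier_coupled_power",
                                    c(m = 4, tau_eps = 1.6, tau_kap = 2.0)),
                         emp, 200)
  s <- substitution_rates()
  lm <- vapply(0:5, function(r) compute_Lmax(cv, s, r), numeric(1))
  # raising r never increases L_max
  expect_false(is.unsorted(rev(lm)))
  expect_equal(lm[1], Inf) # unbounded at r = 0 for these rates
  # threshold crossing is the first bin over the limit
  p <- 10^3 * drldyn:::per_repeat_prob(cv, s)
  expect_equal(compute_Lmax(cv, s, 3), which(p > 0.1)[1])
})

test_that("Poisson stochastic stepping is unbiased and reproducible", {
  s <- substitution_rates(lengthen = 0, shorten = 0, fission = 1e-4,
                          fusion = 0, create_a1 = 0, destroy_a1 = 0,
                          b_insert = 0, b_delete = 0, b1_delete = 0)
  zero <- rate_curve(numeric(10), numeric(10), numeric(10))
  st <- sim_state(c(0, 0, 0, 0, 0, 1e4, 0, 0, 0, 0), c(1e4, numeric(9)))
  # all rates zero: state unchanged
  s0 <- substitution_rates(lengthen = 0, shorten = 0, fission = 0, fusion = 0,
                           create_a1 = 0, destroy_a1 = 0, b_insert = 0,
                           b_delete = 0, b1_delete = 0)
  expect_equal(poisson_step(st, s0, zero, rng_seed = 1)$a, st$a)
  # mean over replicates matches the deterministic expectation within 4 sigma
  det <- kernel_step(st, s, zero)
  nrep <- 3000
  acc <- numeric(10)
  set.seed(42)
  for (i in seq_len(nrep)) acc <- acc + poisson_step(st, s, zero)$a
  m <- acc / nrep
  lam_out <- 4e-4 * 1e4            # fission events per generation
  for (b in c(1:4, 6)) {
    expected <- det$a[b]
    sd_bin <- sqrt(if (b == 6) lam_out else lam_out / 2) / sqrt(nrep)
    expect_lt(abs(m[b] - expected), 4 * sd_bin + 1e-9)
  }
  # seeded reproducibility
  expect_equal(poisson_step(st, s, zero, rng_seed = 7)$a,
               poisson_step(st, s, zero, rng_seed = 7)$a)
})

test_that("initial state is geometric and scales linearly with genome size", {
  s <- substitution_rates()
  st1 <- initialize_state(1e8, s, pre_run = FALSE)
  st2 <- initialize_state(2e8, s, pre_run = FALSE)
  expect_equal(st2$a, 2 * st1$a)
  p <- p_repeat_unit(s)
  expect_equal(st1$a[2:10] / st1$a[1:9], rep(p, 9))
  # substitution-equilibrated start matches the geometric ratio closely
  st3 <- initialize_state(1e8, s, L_bound = 60, L_bound_b = 60)
  rat <- st3$a[2:10] / st3$a[1:9]
  expect_lt(max(abs(rat - rat[1])), 0.02)
})

test_that("evolve flags non-equilibrating (expansion-biased) parameters", {
  emp <- empirical_rates_mono_a()
  s <- substitution_rates()
  init <- initialize_state(3.1e9, s, pre_run = FALSE)
  cv <- build_rate_table(param_spec("multiplier_coupled_power",
                                    c(m = 4, tau_eps = 2.0, tau_kap = 1.5)),
                         emp, 200)
  ev <- evolve(init, s, cv, sim_config(
    schedule = data.frame(r = 3:0, iterations = 1e6),
    conv_tol = 1e-4, check_every = 1000))
  expect_true(ev$diverged)
  expect_true(ev$boundary_growing)
  expect_false(ev$equilibrated)
})

test_that("step-wise speed-up matches a constant speed-up", {
  emp <- empirical_rates_mono_a()
  s <- substitution_rates()
  init <- initialize_state(3.1e9, s, pre_run = FALSE)
  cv <- build_rate_table(param_spec("multiplier_coupled_power",
                                    c(m = 4, tau_eps = 1.25, tau_kap = 2.25)),
                         emp, 200)
  staged <- evolve(init, s, cv, sim_config(conv_tol = 1e-4, check_every = 1000))
  const <- evolve(init, s, cv, sim_config(
    schedule = data.frame(r = 2, iterations = 1e7),
    conv_tol = 1e-4, check_every = 2000))
  n <- max(length(staged$state$a), length(const$state$a))
  a1 <- drldyn:::.resize_hist(staged$state$a, n)
  a2 <- drldyn:::.resize_hist(const$state$a, n)
  pop <- which(a1 >= 1 & a2 >= 1)
  pop <- pop[pop < length(a1)]
  expect_lt(max(abs(a1[pop] - a2[pop]) / a1[pop]), 0.02)
})

test_that("flux decomposition localizes each process and balances at steady state", {
  # expansion contributes only to influx of L+1 / outflux of L
  s0 <- substitution_rates(lengthen = 0, shorten = 0, fission = 0, fusion = 0,
                           create_a1 = 0, destroy_a1 = 0, b_insert = 0,
                           b_delete = 0, b1_delete = 0)
  cv <- rate_curve(eps = c(0, 0, 0, 1e-6, numeric(6)), kap = numeric(10),
                   iota = numeric(10))
  st <- sim_state(c(numeric(3), 100, numeric(6)), c(100, numeric(9)))
  fx <- flux_decomposition(st, s0, cv)
  expect_equal(unname(fx$outflux[4, "local_indel"]), 4e-6 * 100)
  expect_equal(unname(fx$influx[5, "local_indel"]), 4e-6 * 100)
  expect_equal(unname(sum(fx$influx) - fx$influx[5, "local_indel"]), 0)
  # normalized view: per-bin totals are one where flux exists
  expect_equal(sum(fx$influx_normalized[5, ]), 1)
  # equilibrated run: growth-corrected net flux is far below gross flux
  emp <- empirical_rates_mono_a()
  s <- substitution_rates()
  init <- initialize_state(3.1e9, s, pre_run = TRUE)
  cvm <- build_rate_table(param_spec("multiplier_coupled_power",
                                     c(m = 4, tau_eps = 1.25, tau_kap = 2.25)),
                          emp, 200)
  ev <- evolve(init, s, cvm, sim_config(conv_tol = 1e-4, check_every = 1000))
  fx2 <- flux_decomposition(ev$state, s, cvm)
  pop <- which(ev$state$a >= 1)
  expect_lt(max(abs(fx2$net_shape[pop]) / fx2$gross[pop]), 0.01)
})

test_that("a stronger contraction exponent thins the equilibrium tail", {
  emp <- empirical_rates_mono_a()
  s <- substitution_rates()
  init <- initialize_state(3.1e9, s, pre_run = TRUE)
  cfg <- sim_config(schedule = data.frame(r = 3:0, iterations = c(2e5, 3e4, 3e4, 3e4)),
                    conv_tol = 1e-4, check_every = 1000)
  tails <- lapply(c(1.9, 2.2, 2.5), function(tk) {
    cv <- build_rate_table(param_spec("multiplier_coupled_power",
                                      c(m = 4, tau_eps = 1.6, tau_kap = tk)),
                           emp, 200)
    ev <- evolve(init, s, cv, cfg)
    p <- ev$state$a / sum(ev$state$a)
    rev(cumsum(rev(p))) # upper tail mass per length
  })
  for (L in c(15, 20, 30)) {
    expect_gt(tails[[1]][L], tails[[2]][L])
    expect_gt(tails[[2]][L], tails[[3]][L])
  }
})
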