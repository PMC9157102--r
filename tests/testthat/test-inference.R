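test_that("state reconstruction preserves within-phenotype proportions", {
  p <- measured_params()
  st <- next_generation(founder_state(0.3, p), p)
  cf <- carrier_frequency(st)
  # matching observation: unchanged
  same <- reconstruct_state(cf, st)
  expect_equal(unclass(same), unclass(st), tolerance = 1e-12)
  # rescaled observation: carrier mass moves, within-class ratios do not
  re <- reconstruct_state(0.6, st)
  expect_equal(carrier_frequency(re), 0.6, tolerance = 1e-9)
  ratio <- function(s) {
    df <- as.data.frame(s)
    a <- sum(df$frequency[df$genotype_drive == "DRIVE/DRIVE"])
    b <- sum(df$frequency[df$genotype_drive == "WT/DRIVE"])
    a / b
  }
  expect_equal(ratio(re), ratio(st), tolerance = 1e-9)
  # zero observation: all mass on non-carriers
  zero <- reconstruct_state(0, st)
  expect_equal(carrier_frequency(zero), 0)
  expect_error(reconstruct_state(0.5, founder_state(0, p)),
               "carrier mass is zero")
})

test_that("a T-generation trajectory contributes T - 2 binomial terms", {
  obs3 <- cage_observations(data.frame(generation = 0:2,
                                       carriers = c(50, 70, 90),
                                       noncarriers = c(450, 430, 410)))
  fit <- fit_fitness_model(obs3, measured_params(), "NEUTRAL")
  expect_equal(fit$n_transitions, 1)
  # and the log-likelihood agrees with a step-by-step recomputation from
  # the public single-generation operations
  p <- measured_params()
  spec <- fitness_spec()
  obs <- make_cage_obs(seed = 101, spec = spec, n_generations = 6)
  n <- obs$carriers + obs$noncarriers
  f <- obs$carriers / n
  st <- founder_state(f[1], p)
  ll <- 0
  for (i in 1:(nrow(obs) - 1)) {
    pred <- next_generation(st, p, spec)
    pc <- carrier_frequency(pred)
    if (i >= 2) ll <- ll + dbinom(obs$carriers[i + 1], n[i + 1], pc, log = TRUE)
    st <- reconstruct_state(f[i + 1], pred)
  }
  expect_equal(trajectory_loglik(obs, p, spec), ll, tolerance = 1e-9)
})

test_that("the generating parameters beat perturbed ones on most datasets", {
  p <- measured_params()
  spec <- fitness_spec("DIRECT_VIABILITY", 0.8)
  wins <- 0
  for (s in 1:8) {
    obs <- make_cage_obs(seed = 200 + s, spec = spec)
    l_true <- trajectory_loglik(obs, p, spec)
    l_pert <- trajectory_loglik(obs, p, fitness_spec("DIRECT_VIABILITY", 0.55))
    wins <- wins + (l_true > l_pert)
  }
  expect_gte(wins, 6)
})

test_that("fitting recovers a known viability cost", {
  p <- measured_params()
  spec <- fitness_spec("DIRECT_VIABILITY", 0.8)
  for (s in 1:3) {
    fit <- fit_fitness_model(make_cage_obs(seed = 300 + s, spec = spec),
                             p, "DIRECT_VIABILITY")
    expect_lt(abs(fit$mle_fitness - 0.8), 0.1)
    expect_true(fit$ci95[1] <= fit$mle_fitness &&
                fit$mle_fitness <= fit$ci95[2])
    expect_lte(fit$loglik, 0)
    expect_true(is.finite(fit$aicc))
  }
})

test_that("neutral data yield a fitness estimate near 1", {
  p <- measured_params()
  fit <- fit_fitness_model(make_cage_obs(seed = 77, spec = fitness_spec()),
                           p, "DIRECT_VIABILITY")
  expect_lt(abs(fit$mle_fitness - 1), 0.1)
})

test_that("scaling all counts narrows the CI but keeps the argmax", {
  p <- measured_params()
  obs <- make_cage_obs(seed = 55, spec = fitness_spec("DIRECT_VIABILITY", 0.8))
  obs10 <- cage_observations(data.frame(generation = obs$generation,
                                        carriers = obs$carriers * 10,
                                        noncarriers = obs$noncarriers * 10))
  f1 <- fit_fitness_model(obs, p, "DIRECT_VIABILITY")
  f10 <- fit_fitness_model(obs10, p, "DIRECT_VIABILITY")
  expect_lt(abs(f10$mle_fitness - f1$mle_fitness), 0.01)
  expect_false(isTRUE(all.equal(f10$loglik, f1$loglik)))
  expect_lt(diff(f10$ci95), diff(f1$ci95))
})

test_that("AICc ranking identifies the generating model more often than not", {
  p <- measured_params()
  spec <- fitness_spec("DIRECT_VIABILITY", 0.65)  # strong, detectable cost
  top <- character(10)
  for (s in 1:10) {
    cmp <- compare_models(make_cage_obs(seed = 400 + s, spec = spec), p,
                          models = c("NEUTRAL", "DIRECT_VIABILITY",
                                     "SOMATIC_HET_FECUNDITY"))
    top[s] <- cmp[[1]]$model
  }
  expect_gte(sum(top == "DIRECT_VIABILITY"), 6)
})

test_that("the neutral model has k = 0 so AICc = -2 lnL", {
  p <- measured_params()
  obs <- make_cage_obs(seed = 12, spec = fitness_spec())
  fit <- fit_fitness_model(obs, p, "NEUTRAL")
  expect_equal(fit$aicc, -2 * fit$loglik)
})

test_that("pooling cages sums their transitions and log-likelihoods", {
  p <- measured_params()
  spec <- fitness_spec("DIRECT_VIABILITY", 0.8)
  o1 <- make_cage_obs(seed = 21, spec = spec, n_generations = 8)
  o2 <- make_cage_obs(seed = 22, spec = spec, n_generations = 5, init = 0.413)
  fit <- fit_fitness_model(list(o1, o2), p, "DIRECT_VIABILITY")
  expect_equal(fit$n_transitions, (8 - 1) + (5 - 1))
  w <- fit$mle_fitness
  s <- fitness_spec("DIRECT_VIABILITY", w)
  expect_equal(fit$loglik,
               trajectory_loglik(o1, p, s) + trajectory_loglik(o2, p, s),
               tolerance = 1e-9)
})

test_that("r1-free data keep the r1 estimate at the zero boundary", {
  # the relative r1 rate sits on the boundary of its parameter space, so on
  # noisy data its MLE is exactly 0 in about half of replicates (whenever
  # the observations do not run above the one-step predictions on average);
  # on noise-free data it must be 0 with a finite upper bound
  p <- measured_params()
  spec <- fitness_spec("DIRECT_VIABILITY", 0.8)

  # deterministic limit: counts taken from the exact trajectory at large N
  st <- founder_state(0.088, p)
  cf <- 0.088
  for (g in 1:9) { st <- next_generation(st, p, spec); cf <- c(cf, carrier_frequency(st)) }
  N <- 1e6
  det_obs <- cage_observations(data.frame(generation = 0:9,
                                          carriers = round(N * cf),
                                          noncarriers = N - round(N * cf)))
  r1_det <- fit_relative_r1(det_obs, p, best_model = "DIRECT_VIABILITY")
  expect_equal(r1_det$mle, 0)
  expect_false(r1_det$at_boundary)
  expect_lt(r1_det$upper95, 0.02)
  expect_equal(r1_det$germline_rate,
               r1_det$upper95 * p$germline_resistance_total)
  expect_equal(r1_det$embryo_rate, r1_det$upper95 * p$embryo_cut_rate)
  # on zero-MLE data the extra parameter cannot improve the AICc
  base <- fit_fitness_model(det_obs, p, "DIRECT_VIABILITY")
  expect_gt(r1_det$aicc, base$aicc)

  # stochastic replicates: the zero boundary is hit in a sizeable fraction
  mles <- vapply(1:6, function(s) {
    o1 <- make_cage_obs(seed = 30 + 2 * s, spec = spec, n_generations = 8)
    o2 <- make_cage_obs(seed = 31 + 2 * s, spec = spec, n_generations = 5,
                        init = 0.413)
    fit_relative_r1(list(o1, o2), p, best_model = "DIRECT_VIABILITY")$mle
  }, numeric(1))
  expect_gte(sum(mles == 0), 2)
  expect_true(all(mles >= 0 & mles <= 0.05))
})

test_that("relative r1 bounds convert to absolute germline and embryo rates", {
  ab <- r1_absolute_rates(0.003, measured_params())
  expect_equal(ab$germline, 0.003 * 0.222)
  expect_equal(ab$embryo, 0.003 * 0.522)
})

test_that("observation tables are validated row by row", {
  expect_error(cage_observations(data.frame(generation = c(0, 2, 3),
                                            carriers = 1, noncarriers = 1)),
               "consecutive")
  expect_error(cage_observations(data.frame(generation = 0:2,
                                            carriers = c(1, -1, 1),
                                            noncarriers = 1)),
               "nonnegative")
  expect_error(cage_observations(data.frame(generation = 0:1,
                                            carriers = c(0, 0),
                                            noncarriers = c(5, 0))),
               "at least one phenotyped")
  expect_error(fit_fitness_model(
    cage_observations(data.frame(generation = 0:1, carriers = c(5, 5),
                                 noncarriers = c(5, 5))),
    measured_params(), "NEUTRAL"), "at least 3 generations")
})
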