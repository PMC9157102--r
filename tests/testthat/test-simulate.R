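test_that("a fixed seed fully determines simulator output", {
  p <- measured_params()
  cfg <- sim_config(population_size = 800, n_generations = 5,
                    init_carrier_freq = 0.2, seed = 99)
  a <- simulate_cage(p, fitness_spec(), cfg)
  b <- simulate_cage(p, fitness_spec(), cfg)
  expect_identical(a, b)
  scfg <- sim_config(population_size = 100, n_generations = 6,
                     init_carrier_freq = 1, seed = 7,
                     discard_noncarriers = TRUE)
  sa <- simulate_artificial_selection(p, cfg = scfg)
  sb <- simulate_artificial_selection(p, cfg = scfg)
  expect_identical(sa, sb)
  da <- generate_cross_dataset(p, seed = 5)
  db <- generate_cross_dataset(p, seed = 5)
  expect_identical(da, db)
})

test_that("large simulated cages track the deterministic recursion", {
  p <- measured_params()
  spec <- fitness_spec()
  st <- founder_state(0.088, p)
  for (g in 1:10) st <- next_generation(st, p, spec)
  target <- carrier_frequency(st)
  R <- 30
  cf <- vapply(seq_len(R), function(s) {
    out <- simulate_cage(p, spec, sim_config(population_size = 1e5,
                                             n_generations = 10,
                                             init_carrier_freq = 0.088,
                                             seed = 1000 + s))
    tail(out$generations$carriers / out$generations$popsize, 1)
  }, numeric(1))
  se <- sd(cf) / sqrt(R)
  expect_lt(abs(mean(cf) - target), 3 * se + 1e-4)
})

test_that("cages released at 8.8% rise in carrier frequency", {
  p <- measured_params()
  spec <- fitness_spec("DIRECT_VIABILITY", 0.8)
  rises <- vapply(1:20, function(s) {
    out <- simulate_cage(p, spec, sim_config(population_size = 4000,
                                             n_generations = 6,
                                             init_carrier_freq = 0.088,
                                             seed = 2000 + s))
    g <- out$generations
    g$carriers[7] / g$popsize[7] > g$carriers[1] / g$popsize[1]
  }, logical(1))
  expect_gte(mean(rises), 0.95)
})

test_that("the artificial-selection protocol collapses small cages", {
  p <- measured_params()
  spec <- fitness_spec("DIRECT_VIABILITY", 0.8)
  extinct_by_5 <- vapply(1:6, function(s) {
    out <- simulate_artificial_selection(
      p, spec, sim_config(population_size = 100, n_generations = 8,
                          init_carrier_freq = 1, seed = 3000 + s,
                          discard_noncarriers = TRUE))
    out$termination == "EXTINCT" && max(out$generations$generation) <= 5
  }, logical(1))
  expect_gte(sum(extinct_by_5), 4)
})

test_that("selection keeps the realized genetic load above the open cage's", {
  p <- measured_params()
  spec <- fitness_spec("DIRECT_VIABILITY", 0.8)
  sel <- simulate_artificial_selection(
    p, spec, sim_config(population_size = 400, n_generations = 6,
                        init_carrier_freq = 1, seed = 11,
                        discard_noncarriers = TRUE))
  open <- simulate_cage(p, spec, sim_config(population_size = 4000,
                                            n_generations = 6,
                                            init_carrier_freq = 0.088,
                                            seed = 11))
  expect_gt(mean(sel$generations$load), mean(open$generations$load))
})

test_that("r1-free simulations never produce functional resistance alleles", {
  p <- drive_params(relative_r1_rate = 0)
  out <- simulate_cage(p, fitness_spec(), sim_config(population_size = 2000,
                                                     n_generations = 8,
                                                     init_carrier_freq = 0.3,
                                                     seed = 4))
  r1_rows <- grepl("R1", enumerate_genotypes()$genotype_drive[1:30])
  for (tal in out$tallies) expect_equal(sum(tal[r1_rows, ]), 0)
})

test_that("cross datasets let the estimators recover their generating rates", {
  p <- measured_params()
  d <- generate_cross_dataset(p, n_parents = 50, offspring_per_parent = 100,
                              seed = 8, n_assessed = 500, n_baseline = 500)
  for (sex in c("female", "male")) {
    ir <- inheritance_rate(d[[sex]])
    chat <- conversion_from_inheritance(unname(ir["rate"]))
    expect_lt(abs(chat - 0.767), 2 * 2 * unname(ir["sem"]))  # 2 SE on 2i-1
  }
  ehat <- embryo_rate_from_sterility(d$sterility)
  expect_lt(abs(ehat - 0.522), 0.06)
  # Mendelian control
  d0 <- generate_cross_dataset(drive_params(cas9_present = FALSE),
                               n_parents = 50, offspring_per_parent = 100,
                               seed = 9)
  expect_lt(abs(unname(inheritance_rate(d0$female)["rate"]) - 0.5), 0.02)
})
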