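# Shared fixtures, all generated in code.

measured_params <- function(...) drive_params(...)

# drive-allele frequency of a state (pooled over sexes), computed from the
# serialized table so it does not depend on package internals
drive_allele_freq <- function(state) {
  df <- as.data.frame(state)
  n_drive <- vapply(strsplit(df$genotype_drive, "/", fixed = TRUE),
                    function(x) sum(x == "DRIVE"), numeric(1))
  sum(df$frequency * n_drive / 2) / 2  # /2: two sexes each summing to 1
}

# synthetic cage study under known parameters, returned as observations
make_cage_obs <- function(seed, spec = fitness_spec("DIRECT_VIABILITY", 0.8),
                          n_generations = 8, N = 4000, init = 0.088,
                          p = drive_params()) {
  out <- simulate_cage(p, spec,
                       sim_config(population_size = N,
                                  n_generations = n_generations,
                                  init_carrier_freq = init, seed = seed))
  as_cage_observations(out)
}

# uniform random valid parameter draws for property-style loops
random_params <- function() {
  conv_f <- runif(1, 0, 0.9)
  conv_m <- runif(1, 0, 0.9)
  drive_params(
    conversion_female = conv_f,
    conversion_male = conv_m,
    germline_resistance_total = runif(1, 0, 1 - max(conv_f, conv_m)),
    embryo_cut_rate = runif(1),
    relative_r1_rate = runif(1, 0, 0.1),
    offtarget_germline_cut_rate = runif(1),
    initial_offtarget_cut_fraction = runif(1)
  )
}
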