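# Stochastic simulators of the two experimental designs.  They double as
# the synthetic-data generators for the inference and estimator modules:
# observation noise is pure multinomial sampling of adults from the
# deterministic next-generation distribution (no phenotyping error).

#' Simulation configuration
#'
#' @param population_size Adults per generation for the large-cage design;
#'   for the artificial-selection design this is the founder adult count
#'   and later sizes are offspring-determined.
#' @param n_generations Number of generations to simulate after the
#'   founder release (generation 0).
#' @param init_carrier_freq Founder drive-carrier frequency.
#' @param seed Integer seed; together with the configuration it fully
#'   determines the output.
#' @param discard_noncarriers If `TRUE`, all non-carrier adults are
#'   removed before mating each generation (artificial-selection
#'   protocol).
#' @param eggs_per_female Mean eggs per fertile female (offspring-
#'   determined sizes only).
#' @param egg_to_adult_survival Egg-to-adult survival probability.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(population_size = 4000, n_generations = 10,
                       init_carrier_freq = 0.088, seed = 1,
                       discard_noncarriers = FALSE,
                       eggs_per_female = 20, egg_to_adult_survival = 0.8) {
  stopifnot(population_size >= 2, n_generations >= 1,
            init_carrier_freq >= 0, init_carrier_freq <= 1,
            eggs_per_female > 0,
            egg_to_adult_survival > 0, egg_to_adult_survival <= 1)
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 init_carrier_freq = init_carrier_freq,
                 seed = as.integer(seed),
                 discard_noncarriers = isTRUE(discard_noncarriers),
                 eggs_per_female = eggs_per_female,
                 egg_to_adult_survival = egg_to_adult_survival),
            class = "sim_config")
}

.sim_output <- function(rows, tallies, termination) {
  df <- do.call(rbind, rows)
  structure(list(generations = df, tallies = tallies,
                 termination = termination),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> %s after %d generations\n",
              x$termination, max(x$generations$generation)))
  print.data.frame(x$generations, row.names = FALSE, digits = 4)
  invisible(x)
}

.gen_row <- function(generation, counts, load) {
  carriers <- sum(counts[.carrier30, ])
  data.frame(generation = generation, carriers = carriers,
             noncarriers = sum(counts) - carriers, load = load,
             popsize = sum(counts))
}

# multinomial draw of N adults from a per-sex frequency matrix
.sample_adults <- function(N, m) {
  draw <- stats::rmultinom(1, N, c(0.5 * m[, 1], 0.5 * m[, 2]))
  matrix(draw, .N_GENO, 2L)
}

#' Simulate a large-cage population study
#'
#' Wright-Fisher style simulation of the cage design: each generation, `N`
#' adults are drawn multinomially from the deterministic next-generation
#' genotype distribution conditioned on the realized current tallies.
#' Founders follow [founder_state()].  The output converts directly to
#' [cage_observations()] via [as_cage_observations()].
#'
#' @param p A [drive_params()] object.
#' @param spec A [fitness_spec()].
#' @param cfg A [sim_config()] with `discard_noncarriers = FALSE`.
#' @return A `sim_output`: per-generation table (`generation`, `carriers`,
#'   `noncarriers`, `load`, `popsize`), genotype tallies, and a
#'   termination flag (`COMPLETED` or `EXTINCT`).
#' @examples
#' out <- simulate_cage(drive_params(), fitness_spec(),
#'                      sim_config(population_size = 500, n_generations = 4))
#' out$generations
#' @export
simulate_cage <- function(p, spec = fitness_spec(), cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$discard_noncarriers)
    stop("use simulate_artificial_selection() for the discard protocol")
  .validate_drive_params(p)
  ctx <- .model_context(p)
  fv <- .fitness_vectors(spec)
  set.seed(cfg$seed)
  N <- cfg$population_size
  counts <- .sample_adults(N, unclass(founder_state(cfg$init_carrier_freq, p)))
  rows <- list()
  tallies <- list(counts)
  termination <- "COMPLETED"
  for (g in 0:(cfg$n_generations - 1L)) {
    cs <- colSums(counts)
    if (any(cs == 0)) { termination <- "EXTINCT"; rows[[g + 1L]] <- .gen_row(g, counts, 1); break }
    m <- sweep(counts, 2, cs, "/")
    nxt <- tryCatch(.next_gen_mat(m, ctx, fv), drive_extinction = function(e) NULL)
    load <- .load_mat(m, ctx, fv)$load
    rows[[g + 1L]] <- .gen_row(g, counts, load)
    if (is.null(nxt)) { termination <- "EXTINCT"; break }
    counts <- .sample_adults(N, nxt)
    tallies[[g + 2L]] <- counts
  }
  if (termination == "COMPLETED") {
    g <- cfg$n_generations
    m <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
    load <- .load_mat(m, ctx, fv)$load
    rows[[g + 1L]] <- .gen_row(g, counts, load)
  }
  .sim_output(rows, tallies, termination)
}

#' Simulate the artificial-selection small-cage protocol
#'
#' Individual-level simulation of the functional-resistance detection
#' design: every generation all non-carrier adults are discarded, each
#' remaining fertile female draws a mate (proportional to male frequency
#' times mating success) and a Poisson number of eggs
#' (`eggs_per_female` times her fecundity multiplier); each egg's genotype
#' is drawn from the pair's gamete-and-embryo-cutting model and survives
#' to adulthood with probability `egg_to_adult_survival` times its
#' viability multiplier, with sexes 1:1.  Population size is therefore
#' offspring-determined, and extinction is an expected outcome.
#'
#' @inheritParams simulate_cage
#' @param cfg A [sim_config()] with `discard_noncarriers = TRUE`.
#' @return A `sim_output`; the per-generation `load` column is the
#'   deterministic genetic load of the realized post-discard mating
#'   population.
#' @export
simulate_artificial_selection <- function(p, spec = fitness_spec("DIRECT_VIABILITY", 0.8),
                                          cfg = sim_config(population_size = 100,
                                                           init_carrier_freq = 1,
                                                           discard_noncarriers = TRUE)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!cfg$discard_noncarriers)
    stop("the artificial-selection protocol requires discard_noncarriers = TRUE")
  .validate_drive_params(p)
  ctx <- .model_context(p)
  fv <- .fitness_vectors(spec)
  set.seed(cfg$seed)
  counts <- .sample_adults(cfg$population_size,
                           unclass(founder_state(cfg$init_carrier_freq, p)))
  rows <- list()
  tallies <- list(counts)
  termination <- "COMPLETED"
  surv <- cfg$egg_to_adult_survival * fv$via
  for (g in 0:(cfg$n_generations - 1L)) {
    # discard non-carriers, then record the pre-mating census
    kept <- counts
    kept[!.carrier30, ] <- 0
    if (sum(kept) == 0 || sum(kept[, 1]) == 0 || sum(kept[, 2]) == 0) {
      rows[[g + 1L]] <- .gen_row(g, counts, 1)
      termination <- "EXTINCT"
      break
    }
    mkept <- sweep(kept, 2, colSums(kept), "/")
    load <- .load_mat(mkept, ctx, fv)$load
    rows[[g + 1L]] <- .gen_row(g, counts, load)
    # mate and reproduce
    wm <- kept[, 2] * fv$mat
    offspring <- matrix(0L, .N_GENO, 2L)
    for (gi in which(kept[, 1] > 0L & !.sterile30)) {
      nf <- kept[gi, 1]
      mates <- stats::rmultinom(1, nf, wm)[, 1]
      Og <- matrix(ctx$O2[gi, ], .N_GENO, 8L)
      for (gj in which(mates > 0L)) {
        dist <- as.vector(Og %*% ctx$Gm[gj, ])
        eggs <- stats::rpois(1, cfg$eggs_per_female * fv$fec[gi] * mates[gj])
        if (eggs == 0) next
        geno <- stats::rmultinom(1, eggs, dist)[, 1]
        adults <- stats::rbinom(.N_GENO, geno, surv)
        daughters <- stats::rbinom(.N_GENO, adults, 0.5)
        offspring[, 1] <- offspring[, 1] + daughters
        offspring[, 2] <- offspring[, 2] + (adults - daughters)
      }
    }
    counts <- offspring
    tallies[[g + 2L]] <- counts
    if (sum(counts) == 0) {
      rows[[g + 2L]] <- .gen_row(g + 1L, counts, 1)
      termination <- "EXTINCT"
      break
    }
  }
  if (termination == "COMPLETED") {
    g <- cfg$n_generations
    kept <- counts
    kept[!.carrier30, ] <- 0
    load <- if (sum(kept[, 1]) > 0 && sum(kept[, 2]) > 0)
      .load_mat(sweep(kept, 2, colSums(kept), "/"), ctx, fv)$load else 1
    rows[[g + 1L]] <- .gen_row(g, counts, load)
  }
  .sim_output(rows, tallies, termination)
}

#' Convert simulator output to cage observations
#'
#' @param out A `sim_output` from [simulate_cage()].
#' @return A [cage_observations()] table.
#' @export
as_cage_observations <- function(out) {
  stopifnot(inherits(out, "sim_output"))
  cage_observations(out$generations[c("generation", "carriers", "noncarriers")])
}

#' Generate a synthetic cross dataset
#'
#' Samples offspring phenotype counts for drive/wild-type heterozygote x
#' wild-type crosses for both parent sexes (one vial per parent), and a
#' sterility assay of drive-carrier daughters of drive mothers, from the
#' gamete and embryo-cutting model.  Used to exercise the rate estimators.
#'
#' @param p A [drive_params()] object.
#' @param n_parents Drive-heterozygous parents per sex.
#' @param offspring_per_parent Phenotyped offspring per parent.
#' @param seed Integer seed.
#' @param n_assessed,n_baseline Females assessed for sterility in the
#'   drive-mother and baseline groups.
#' @param baseline_sterility Background sterility probability.
#' @return A list with elements `female` and `male` ([cross_counts()]) and
#'   `sterility` ([sterility_counts()]).
#' @export
generate_cross_dataset <- function(p, n_parents = 10, offspring_per_parent = 100,
                                   seed = 1, n_assessed = 22, n_baseline = 20,
                                   baseline_sterility = 0.05) {
  .validate_drive_params(p)
  stopifnot(n_parents > 0, offspring_per_parent > 0)
  set.seed(as.integer(seed))
  one_sex <- function(sex) {
    conv <- if (sex == "FEMALE") p$conversion_female else p$conversion_male
    pd <- if (p$cas9_present) 0.5 + 0.5 * conv else 0.5  # P(offspring inherits drive)
    wd <- stats::rbinom(n_parents, offspring_per_parent, pd)
    cross_counts(sex, sum(wd), n_parents * offspring_per_parent - sum(wd),
                 batches = data.frame(vial = seq_len(n_parents),
                                      with_drive = wd,
                                      without_drive = offspring_per_parent - wd))
  }
  female <- one_sex("FEMALE")
  male <- one_sex("MALE")
  # drive-carrier daughters of drive mothers: paternal WT allele cut to r2
  # in the embryo with probability e * (1 - rho); sterile then, or at the
  # background rate otherwise
  p_sterile <- if (p$cas9_present)
    baseline_sterility + (1 - baseline_sterility) *
      p$embryo_cut_rate * (1 - p$relative_r1_rate)
  else baseline_sterility
  sterile <- stats::rbinom(1, n_assessed, p_sterile)
  base_sterile <- stats::rbinom(1, n_baseline, baseline_sterility)
  list(female = female, male = male,
       sterility = sterility_counts(sterile, n_assessed,
                                    base_sterile, n_baseline))
}
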