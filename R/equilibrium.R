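# Equilibrium and genetic-load calculators built on the recursion.

#' Equilibrium drive-carrier frequency
#'
#' Iterates the deterministic recursion from a founder release until the
#' per-generation change in carrier frequency falls below `tol` (or
#' `max_gens` is reached).  With the measured drive parameters and no
#' fitness cost the model converges near a 90% carrier frequency, the
#' textbook expectation for a one-gRNA homing suppression drive with these
#' rates.
#'
#' @param p A [drive_params()] object.
#' @param spec A [fitness_spec()].
#' @param init_carrier_freq Release carrier frequency in `(0, 1)`.
#' @param tol Convergence tolerance on the carrier-frequency change.
#' @param max_gens Iteration cap.
#' @return The final carrier frequency, with attributes `converged`
#'   (logical) and `generations`.
#' @examples
#' equilibrium_carrier_frequency(drive_params())  # ~ 0.90
#' @export
equilibrium_carrier_frequency <- function(p, spec = fitness_spec(),
                                          init_carrier_freq = 0.05,
                                          tol = 1e-6, max_gens = 1000) {
  if (init_carrier_freq <= 0 || init_carrier_freq >= 1)
    stop("init_carrier_freq must be strictly between 0 and 1")
  .validate_drive_params(p)
  ctx <- .model_context(p)
  fv <- .fitness_vectors(spec)
  m <- unclass(founder_state(init_carrier_freq, p))
  cf <- 0.5 * sum(m[.carrier30, 1]) + 0.5 * sum(m[.carrier30, 2])
  converged <- FALSE
  gens <- max_gens
  for (t in seq_len(max_gens)) {
    m <- .next_gen_mat(m, ctx, fv)
    cf2 <- 0.5 * sum(m[.carrier30, 1]) + 0.5 * sum(m[.carrier30, 2])
    if (abs(cf2 - cf) < tol) {
      converged <- TRUE
      gens <- t
      cf <- cf2
      break
    }
    cf <- cf2
  }
  if (!converged)
    warning("carrier frequency did not converge within ", max_gens, " generations")
  structure(cf, converged = converged, generations = gens)
}

#' Homozygote fitness cost matching a target equilibrium
#'
#' Finds, by bisection, the drive-homozygote fitness cost `1 - w` at which
#' the equilibrium carrier frequency equals `target_carrier_freq`.  The
#' equilibrium is monotone decreasing in the cost, so the root is unique;
#' a target above the zero-cost equilibrium is unachievable and raises an
#' error.
#'
#' @param target_carrier_freq Target equilibrium carrier frequency.
#' @param p A [drive_params()] object.
#' @param model Fitness-model name for the cost (default direct viability,
#'   the best-fitting model for the larger cage).
#' @param cost_tol Bisection tolerance on the cost.
#' @param ... Passed to [equilibrium_carrier_frequency()].
#' @return The fitness cost in `[0, 1)`.
#' @examples
#' \donttest{
#' solve_homozygote_cost_for_equilibrium(0.70, drive_params())  # ~ 0.19
#' }
#' @export
solve_homozygote_cost_for_equilibrium <- function(target_carrier_freq, p,
                                                  model = "DIRECT_VIABILITY",
                                                  cost_tol = 1e-4, ...) {
  model <- match.arg(model, setdiff(FITNESS_MODELS, "NEUTRAL"))
  eq_at <- function(cost)
    as.numeric(equilibrium_carrier_frequency(
      p, fitness_spec(model, 1 - cost), ...))
  e0 <- eq_at(0)
  if (target_carrier_freq > e0 + 1e-9)
    stop("target carrier frequency ", target_carrier_freq,
         " exceeds the zero-cost equilibrium ", signif(e0, 4),
         " and is unachievable")
  if (abs(target_carrier_freq - e0) <= 1e-9) return(0)
  lo <- 0; hi <- 1 - 1e-6
  while (hi - lo > cost_tol) {
    mid <- (lo + hi) / 2
    if (eq_at(mid) > target_carrier_freq) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Genetic load required to shrink a population
#'
#' With `b` eggs per female and egg-to-adult survival `s`, each female slot
#' produces `b * s / 2` daughters (1:1 sex ratio).  The population stops
#' replacing itself once the load exceeds `1 - 2 / (b * s)`.
#'
#' @param eggs_per_female Mean eggs laid per female.
#' @param egg_to_adult_survival Egg-to-adult survival probability.
#' @return The required genetic load in `[0, 1)`.
#' @examples
#' required_genetic_load(20, 0.8)  # 0.875
#' @export
required_genetic_load <- function(eggs_per_female, egg_to_adult_survival) {
  stopifnot(is.numeric(eggs_per_female), eggs_per_female > 0,
            is.numeric(egg_to_adult_survival),
            egg_to_adult_survival > 0, egg_to_adult_survival <= 1)
  prod <- eggs_per_female * egg_to_adult_survival
  if (prod < 2)
    stop("eggs_per_female * egg_to_adult_survival = ", prod,
         " < 2: the population is not self-sustaining even without load")
  1 - 2 / prod
}

# zero out non-carriers and renormalize each sex (the artificial-selection
# discard step); signals extinction if no carriers remain
.discard_noncarriers_mat <- function(m) {
  m[!.carrier30, ] <- 0
  cs <- colSums(m)
  if (any(cs <= 0)) .signal_extinction("no drive carriers left after discard")
  sweep(m, 2, cs, "/")
}

#' Deterministic genetic-load trajectory of the artificial-selection protocol
#'
#' In the small-cage protocol, all non-drive-carrying adults are discarded
#' each generation before mating, which drives the genetic load far above
#' what the free-running cage reaches.  This function iterates the
#' deterministic recursion with the discard step and reports the load of
#' each generation's mating (post-discard) population.  Under the measured
#' drive parameters and the cage-fitted fitness cost the load equilibrates
#' near 1 within two generations.
#'
#' @param p A [drive_params()] object.
#' @param spec A [fitness_spec()]; default the cage-fitted direct-viability
#'   cost (w = 0.8).
#' @param n_generations Number of generations to iterate.
#' @param init_carrier_freq Carrier frequency of the founder adults
#'   (default 1: all founders are drive heterozygotes).
#' @return Numeric vector of genetic loads, one per generation, with
#'   attribute `equilibrium` (the final value).
#' @examples
#' \donttest{
#' selection_load_trajectory(drive_params())  # -> ~ 0.998
#' }
#' @export
selection_load_trajectory <- function(p, spec = fitness_spec("DIRECT_VIABILITY", 0.8),
                                      n_generations = 20,
                                      init_carrier_freq = 1) {
  .validate_drive_params(p)
  ctx <- .model_context(p)
  fv <- .fitness_vectors(spec)
  m <- unclass(founder_state(init_carrier_freq, p))
  loads <- numeric(n_generations)
  for (t in seq_len(n_generations)) {
    m <- .discard_noncarriers_mat(m)
    loads[t] <- .load_mat(m, ctx, fv)$load
    m <- .next_gen_mat(m, ctx, fv)
  }
  structure(loads, equilibrium = loads[n_generations])
}
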