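# Maximum-likelihood inference of fitness costs and of the relative r1
# rate from per-generation drive-carrier counts.
#
# The likelihood conditions each transition on the observed carrier
# frequency at the earlier generation: the model-predicted genotype
# distribution is rescaled so its carrier mass matches the observation
# (within-phenotype genotype proportions preserved), advanced one
# generation, and the observed carrier/non-carrier counts at the next
# generation scored with a binomial.  The transition out of the founder
# generation is excluded (founder adults had atypical fitness), but the
# founder state still seeds the reconstruction chain.

.CHISQ95_1DF_DROP <- stats::qchisq(0.95, df = 1) / 2  # 1.9207 log units

#' Per-generation carrier counts from a cage population
#'
#' Validates and packages a table of phenotype counts: one row per
#' discrete, nonoverlapping generation with the number of drive-carrier
#' (DsRed) and non-carrier adults.  Generation indices must be consecutive
#' integers starting anywhere at or above 0; generation 0 is the founder
#' release in which all carriers are drive/wild-type heterozygotes and the
#' Cas9 allele is fixed.
#'
#' @param x A data frame with columns `generation`, `carriers`,
#'   `noncarriers`.
#' @param founders_heterozygous,cas9_fixed Initial-composition flags,
#'   stored as attributes.
#' @return A data frame of class `cage_observations`.
#' @seealso [read_cage_observations()]
#' @export
cage_observations <- function(x, founders_heterozygous = TRUE,
                              cas9_fixed = TRUE) {
  need <- c("generation", "carriers", "noncarriers")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("cage observations need columns ", paste(need, collapse = ", "))
  x <- x[need]
  for (cc in need) {
    bad <- which(!is.finite(x[[cc]]) | x[[cc]] < 0 | x[[cc]] != round(x[[cc]]))
    if (length(bad))
      stop("column '", cc, "' must hold nonnegative integers; bad row ", bad[1])
  }
  if (nrow(x) < 2) stop("need at least 2 generations of observations")
  dg <- diff(x$generation)
  if (any(dg != 1))
    stop("generations must be strictly increasing and consecutive; ",
         "violation after row ", which(dg != 1)[1])
  if (any(x$carriers + x$noncarriers == 0))
    stop("every generation must have at least one phenotyped adult; bad row ",
         which(x$carriers + x$noncarriers == 0)[1])
  structure(x, class = c("cage_observations", "data.frame"),
            founders_heterozygous = isTRUE(founders_heterozygous),
            cas9_fixed = isTRUE(cas9_fixed))
}

.as_obs_list <- function(obs) {
  if (inherits(obs, "cage_observations")) return(list(obs))
  if (is.list(obs) && all(vapply(obs, inherits, TRUE, "cage_observations")))
    return(obs)
  stop("obs must be a cage_observations object or a list of them")
}

#' Rescale a predicted state to an observed carrier frequency
#'
#' Phenotyping observes only carrier vs non-carrier.  This rescales the
#' model-predicted genotype distribution so that the pooled carrier mass
#' equals the observed carrier frequency while the genotype proportions
#' within each phenotype class are untouched; each sex's distribution is
#' then renormalized.
#'
#' @param observed_carrier_freq Observed carrier frequency in `[0, 1]`.
#' @param predicted A normalized [population_state()].
#' @return A `population_state`.
#' @export
reconstruct_state <- function(observed_carrier_freq, predicted) {
  m <- .check_state(predicted)
  f <- observed_carrier_freq
  if (!is.numeric(f) || f < 0 || f > 1)
    stop("observed_carrier_freq must be in [0, 1]")
  pred <- 0.5 * sum(m[.carrier30, 1]) + 0.5 * sum(m[.carrier30, 2])
  if (f > 0 && pred <= 0)
    stop("carriers observed but predicted carrier mass is zero")
  if (f < 1 && pred >= 1)
    stop("non-carriers observed but predicted non-carrier mass is zero")
  .new_state(.reconstruct_mat(f, m))
}

.reconstruct_mat <- function(f, m) {
  pred <- 0.5 * sum(m[.carrier30, 1]) + 0.5 * sum(m[.carrier30, 2])
  a <- if (f > 0) f / pred else 0
  b <- if (f < 1) (1 - f) / (1 - pred) else 0
  m[.carrier30, ] <- m[.carrier30, ] * a
  m[!.carrier30, ] <- m[!.carrier30, ] * b
  sweep(m, 2, colSums(m), "/")
}

# core likelihood on one cage; returns -Inf for data impossible under the
# model (including model-predicted extinction while observations continue)
.traj_ll <- function(obs, ctx, fv) {
  n <- obs$carriers + obs$noncarriers
  f <- obs$carriers / n
  m <- unclass(founder_state(f[1], ctx$p))
  ll <- 0
  for (i in seq_len(nrow(obs) - 1L)) {
    m2 <- tryCatch(.next_gen_mat(m, ctx, fv),
                   drive_extinction = function(e) NULL)
    if (is.null(m2)) return(-Inf)
    pc <- 0.5 * sum(m2[.carrier30, 1]) + 0.5 * sum(m2[.carrier30, 2])
    if (i >= 2L) {
      term <- stats::dbinom(obs$carriers[i + 1L], n[i + 1L], pc, log = TRUE)
      if (!is.finite(term)) return(-Inf)
      ll <- ll + term
    } else if ((pc <= 0 && f[i + 1L] > 0) || (pc >= 1 && f[i + 1L] < 1)) {
      return(-Inf)
    }
    m <- .reconstruct_mat(f[i + 1L], m2)
  }
  ll
}

#' Trajectory log-likelihood of cage observations
#'
#' Sum of log binomial probabilities of the observed carrier/non-carrier
#' counts across generation transitions, conditioning each transition on
#' the observed carrier frequency at the earlier generation.  The
#' transition out of generation 0 contributes nothing; a dataset of `T`
#' generations therefore contributes `T - 2` transitions.  Impossible data
#' (a phenotype observed where the model puts zero mass) yields `-Inf`,
#' not an error.
#'
#' @param obs A [cage_observations()] table (or list of them, summed).
#' @param p A [drive_params()] object.
#' @param spec A [fitness_spec()].
#' @return The log-likelihood (a nonpositive number or `-Inf`).
#' @export
trajectory_loglik <- function(obs, p, spec = fitness_spec()) {
  obs_list <- .as_obs_list(obs)
  .validate_drive_params(p)
  ctx <- .model_context(p)
  fv <- .fitness_vectors(spec)
  sum(vapply(obs_list, .traj_ll, numeric(1), ctx = ctx, fv = fv))
}

.n_transitions <- function(obs_list)
  sum(vapply(obs_list, function(o) nrow(o) - 2L, integer(1)))

.aicc <- function(loglik, k, n) {
  if (k == 0) return(-2 * loglik)
  if (n - k - 1 <= 0) return(Inf)
  2 * k - 2 * loglik + 2 * k * (k + 1) / (n - k - 1)
}

# deterministic bracketed 1-D maximization of the fitness parameter:
# coarse grid, then golden-section refinement in the bracketing interval
.max_ll_w <- function(ll_fun, w_range, n_grid = 30) {
  ws <- seq(w_range[1], w_range[2], length.out = n_grid)
  lls <- vapply(ws, ll_fun, numeric(1))
  if (all(!is.finite(lls)))
    return(list(mle = NA_real_, loglik = -Inf, grid_w = ws, grid_ll = lls,
                identifiable = FALSE))
  i <- which.max(lls)
  lo <- ws[max(i - 1L, 1L)]
  hi <- ws[min(i + 1L, n_grid)]
  opt <- stats::optimize(ll_fun, c(lo, hi), maximum = TRUE, tol = 1e-5)
  mle <- opt$maximum
  llmax <- opt$objective
  if (lls[i] > llmax) { mle <- ws[i]; llmax <- lls[i] }
  fin <- lls[is.finite(lls)]
  list(mle = mle, loglik = llmax, grid_w = ws, grid_ll = lls,
       identifiable = diff(range(fin)) > 1e-6)
}

# profile-likelihood 95% CI by the 1.92 log-unit drop; boundary values of
# the search range are reported when the likelihood never crosses
.profile_ci <- function(ll_fun, mle, llmax, grid_w, grid_ll, w_range) {
  thr <- llmax - .CHISQ95_1DF_DROP
  g <- function(w) {
    v <- ll_fun(w) - thr
    if (is.finite(v)) v else -1e10  # keep uniroot endpoints finite
  }
  root_between <- function(a, b) stats::uniroot(g, c(a, b), tol = 1e-5)$root
  below <- grid_w < mle & (grid_ll < thr | !is.finite(grid_ll))
  lower <- if (any(below)) root_between(max(grid_w[below]), mle) else w_range[1]
  above <- grid_w > mle & (grid_ll < thr | !is.finite(grid_ll))
  upper <- if (any(above)) root_between(mle, min(grid_w[above])) else w_range[2]
  c(lower, upper)
}

#' Fit a fitness-cost model to cage observations
#'
#' Maximizes the trajectory log-likelihood over the homozygote fitness
#' parameter (deterministic bracketed search over `w_range`), computes the
#' small-sample-corrected Akaike information criterion
#' `AICc = 2k - 2lnL + 2k(k+1)/(n-k-1)` with `n` the number of transitions
#' used, and a 95% profile-likelihood confidence interval (1.92 log-unit
#' drop, chi-squared with 1 df).  `NEUTRAL` has no free parameter
#' (`k = 0`).  Multiple cages may be supplied as a list; their
#' log-likelihoods are pooled with a shared fitness parameter.
#'
#' @param obs A [cage_observations()] table or list of them.
#' @param p A [drive_params()] object.
#' @param model Fitness-model name.
#' @param w_range Search range for the fitness parameter.
#' @return An object of class `fit_result` with elements `model`,
#'   `mle_fitness`, `loglik`, `aicc`, `ci95`, `n_transitions`,
#'   `identifiable`.
#' @export
fit_fitness_model <- function(obs, p, model, w_range = c(0.05, 1.5)) {
  obs_list <- .as_obs_list(obs)
  for (o in obs_list) if (nrow(o) < 3)
    stop("each cage needs at least 3 generations (one usable transition)")
  model <- match.arg(model, FITNESS_MODELS)
  .validate_drive_params(p)
  ctx <- .model_context(p)
  n <- .n_transitions(obs_list)
  ll_at <- function(w) {
    fv <- .fitness_vectors(fitness_spec(model, w))
    sum(vapply(obs_list, .traj_ll, numeric(1), ctx = ctx, fv = fv))
  }
  if (model == "NEUTRAL") {
    ll <- ll_at(1)
    return(structure(list(model = model, mle_fitness = 1,
                          mle_relative_r1 = NA_real_, loglik = ll,
                          aicc = .aicc(ll, 0L, n), ci95 = c(NA_real_, NA_real_),
                          n_transitions = n, identifiable = TRUE),
                     class = "fit_result"))
  }
  mx <- .max_ll_w(ll_at, w_range)
  ci <- if (is.finite(mx$loglik))
    .profile_ci(ll_at, mx$mle, mx$loglik, mx$grid_w, mx$grid_ll, w_range)
  else c(NA_real_, NA_real_)
  structure(list(model = model, mle_fitness = mx$mle,
                 mle_relative_r1 = NA_real_, loglik = mx$loglik,
                 aicc = .aicc(mx$loglik, 1L, n), ci95 = ci,
                 n_transitions = n, identifiable = mx$identifiable),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s\n", x$model))
  cat(sprintf("  fitness MLE %.4f  (95%% CI %.4f - %.4f)\n",
              x$mle_fitness, x$ci95[1], x$ci95[2]))
  if (!is.na(x$mle_relative_r1))
    cat(sprintf("  relative r1 MLE %.5f\n", x$mle_relative_r1))
  cat(sprintf("  logLik %.3f | AICc %.3f | transitions %d\n",
              x$loglik, x$aicc, x$n_transitions))
  if (!x$identifiable) cat("  (flat likelihood: parameter not identifiable)\n")
  invisible(x)
}

#' Compare fitness-cost models by AICc
#'
#' Fits each requested model to the (possibly pooled) cage observations and
#' ranks them by ascending AICc.  Ties keep the supplied model order.
#'
#' @inheritParams fit_fitness_model
#' @param models Character vector of at least two model names.
#' @return A list of `fit_result` objects sorted by AICc, of class
#'   `model_comparison`.
#' @export
compare_models <- function(obs, p, models = FITNESS_MODELS) {
  if (length(models) < 2) stop("need at least two models to compare")
  fits <- lapply(models, function(mm) fit_fitness_model(obs, p, mm))
  ord <- order(vapply(fits, function(f) f$aicc, numeric(1)))
  structure(fits[ord], class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  cat("<model_comparison> (ascending AICc)\n")
  print.data.frame(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.model_comparison <- function(x, ...) {
  data.frame(
    model = vapply(x, function(f) f$model, character(1)),
    mle_fitness = vapply(x, function(f) f$mle_fitness, numeric(1)),
    loglik = vapply(x, function(f) f$loglik, numeric(1)),
    aicc = vapply(x, function(f) f$aicc, numeric(1)),
    ci_low = vapply(x, function(f) f$ci95[1], numeric(1)),
    ci_high = vapply(x, function(f) f$ci95[2], numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Bound the relative r1 rate from cage trajectories
#'
#' Profiles the likelihood over the relative r1 rate (the fraction of
#' newly formed resistance alleles that are functional), co-optimizing the
#' fitness parameter of `best_model` at every point, and returns the MLE
#' together with the one-sided 95% upper bound from the 1.92 log-unit
#' profile drop.  The relative rate converts to absolute germline and
#' embryo functional-resistance rates via [r1_absolute_rates()].
#'
#' @param obs A [cage_observations()] table or list of cages pooled with
#'   shared parameters.
#' @param p A [drive_params()] object (its `relative_r1_rate` is the
#'   profiled quantity; the stored value is ignored).
#' @param best_model Fitness model co-fitted alongside the r1 rate,
#'   typically the AICc-best model from [compare_models()].
#' @param rho_max Upper end of the profiled range.
#' @return A list of class `r1_fit`: `mle`, `upper95`, `loglik`, `aicc`,
#'   `germline_rate` and `embryo_rate` (absolute rates at the upper
#'   bound), and `at_boundary` (TRUE if the profile never dropped below
#'   the threshold before `rho_max`).
#' @export
fit_relative_r1 <- function(obs, p, best_model = "DIRECT_VIABILITY",
                            rho_max = 0.05) {
  obs_list <- .as_obs_list(obs)
  best_model <- match.arg(best_model, FITNESS_MODELS)
  .validate_drive_params(p)
  n <- .n_transitions(obs_list)
  profile_at <- function(rho) {
    p_rho <- p
    p_rho$relative_r1_rate <- rho
    ctx <- .model_context(p_rho)
    if (best_model == "NEUTRAL") {
      fv <- .fitness_vectors(fitness_spec())
      sum(vapply(obs_list, .traj_ll, numeric(1), ctx = ctx, fv = fv))
    } else {
      ll_at <- function(w) {
        fv <- .fitness_vectors(fitness_spec(best_model, w))
        sum(vapply(obs_list, .traj_ll, numeric(1), ctx = ctx, fv = fv))
      }
      .max_ll_w(ll_at, c(0.05, 1.5), n_grid = 16)$loglik
    }
  }
  rhos <- seq(0, rho_max, length.out = 11)
  profs <- vapply(rhos, profile_at, numeric(1))
  i <- which.max(profs)
  if (i == 1L) {
    mle <- 0
    llmax <- profs[1]
  } else {
    lo <- rhos[max(i - 1L, 1L)]
    hi <- rhos[min(i + 1L, length(rhos))]
    opt <- stats::optimize(profile_at, c(lo, hi), maximum = TRUE, tol = 1e-5)
    mle <- opt$maximum
    llmax <- opt$objective
    if (profs[i] > llmax) { mle <- rhos[i]; llmax <- profs[i] }
  }
  thr <- llmax - .CHISQ95_1DF_DROP
  at_boundary <- profile_at(rho_max) > thr
  gfun <- function(r) {
    v <- profile_at(r) - thr
    if (is.finite(v)) v else -1e10
  }
  upper <- if (at_boundary) rho_max else
    stats::uniroot(gfun, c(mle, rho_max), tol = 1e-5)$root
  k <- if (best_model == "NEUTRAL") 1L else 2L
  abs_rates <- r1_absolute_rates(upper, p)
  structure(list(mle = mle, upper95 = upper, loglik = llmax,
                 aicc = .aicc(llmax, k, n),
                 germline_rate = abs_rates$germline,
                 embryo_rate = abs_rates$embryo,
                 best_model = best_model, at_boundary = at_boundary),
            class = "r1_fit")
}

#' @export
print.r1_fit <- function(x, ...) {
  cat(sprintf("<r1_fit> co-fitted with %s\n", x$best_model))
  cat(sprintf("  relative r1 MLE %.5f | 95%% upper bound %.5f%s\n",
              x$mle, x$upper95, if (x$at_boundary) " (search boundary)" else ""))
  cat(sprintf("  absolute rates at bound: germline %.5f%%, embryo %.5f%%\n",
              100 * x$germline_rate, 100 * x$embryo_rate))
  invisible(x)
}

#' Convert a relative r1 rate to absolute formation rates
#'
#' The relative r1 rate is the fraction of resistance alleles that are
#' functional; multiplying by the total germline resistance rate and by
#' the embryo cut rate gives the absolute germline and embryo functional
#' resistance allele formation rates.
#'
#' @param relative_r1 Relative r1 rate in `[0, 1]`.
#' @param p A [drive_params()] object.
#' @return List with elements `germline` and `embryo`.
#' @examples
#' r1_absolute_rates(0.003, drive_params())  # 0.067% and 0.16%
#' @export
r1_absolute_rates <- function(relative_r1, p) {
  stopifnot(is.numeric(relative_r1), relative_r1 >= 0, relative_r1 <= 1)
  list(germline = relative_r1 * p$germline_resistance_total,
       embryo = relative_r1 * p$embryo_cut_rate)
}
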