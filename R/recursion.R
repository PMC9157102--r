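# The deterministic (infinite-population) generation update.
#
# One generation: (1) sterile females contribute nothing; (2) female
# genotypes are weighted by fecundity, male genotypes by mating success
# (every female mates, mate choice proportional to frequency x mating
# success); (3) the two parental gamete distributions are crossed; (4)
# embryo cutting is applied according to the mother; (5) offspring are
# weighted by viability; (6) sexes are assigned 1:1 and each sex's
# distribution renormalized.
#
# For speed the mother-specific pieces are precomputed in a "context": for
# each mother genotype g a 30 x 8 map O_g from father gamete to offspring
# genotype (mother gametes marginalized, embryo cutting folded in).  These
# depend on drive parameters only, not on fitness, so a context is shared
# across all likelihood evaluations for fixed parameters.

.model_context <- function(p) {
  Gf <- .gamete_matrix(p, "FEMALE")
  Gm <- .gamete_matrix(p, "MALE")
  E30 <- .embryo_matrix30(p)
  # gamete pair -> offspring genotype index
  CG <- matrix(0L, 8L, 8L)
  for (i in 1:8) for (j in 1:8) {
    dam <- (i - 1L) %/% 2L + 1L; oam <- (i - 1L) %% 2L + 1L
    daf <- (j - 1L) %/% 2L + 1L; oaf <- (j - 1L) %% 2L + 1L
    CG[i, j] <- .gi(.pair4[dam, daf], .pair2[oam, oaf])
  }
  O2 <- matrix(0, .N_GENO, .N_GENO * 8L)  # row g = vec(O_g), column-major
  for (g in seq_len(.N_GENO)) {
    Og <- matrix(0, .N_GENO, 8L)
    gm <- Gf[g, ]
    for (j in 1:8) {
      col <- numeric(.N_GENO)
      for (i in 1:8) col[CG[i, j]] <- col[CG[i, j]] + gm[i]
      Og[, j] <- col
    }
    if (p$cas9_present && .carrier30[g]) Og <- E30 %*% Og
    O2[g, ] <- as.vector(Og)
  }
  list(p = p, Gf = Gf, Gm = Gm, O2 = O2)
}

# extinction as a first-class signaled condition
.signal_extinction <- function(msg) {
  stop(errorCondition(msg, class = c("drive_extinction", "error")))
}

#' Test whether an error is the extinction signal
#'
#' The generation update signals population extinction (no fertile females
#' or zero total offspring weight) as a classed condition rather than
#' returning NaNs; `is_extinction(e)` identifies it in `tryCatch` handlers.
#'
#' @param e A condition object.
#' @return `TRUE` for the extinction condition.
#' @export
is_extinction <- function(e) inherits(e, "drive_extinction")

# core update on a plain 30 x 2 matrix; fv from .fitness_vectors()
.next_gen_mat <- function(m, ctx, fv) {
  wf <- m[, 1] * fv$fec
  wf[.sterile30] <- 0
  wm <- m[, 2] * fv$mat
  if (sum(wf) <= 0) .signal_extinction("no fertile females: population extinct")
  if (sum(wm) <= 0) .signal_extinction("no reproducing males: population extinct")
  pool <- as.vector(crossprod(ctx$Gm, wm / sum(wm)))          # father gametes
  mix <- matrix(as.vector(wf %*% ctx$O2), .N_GENO, 8L)        # sum_g wf_g O_g
  z <- as.vector(mix %*% pool)
  zf <- z * fv$via
  zm <- z * fv$via
  if (sum(zf) <= 0 || sum(zm) <= 0)
    .signal_extinction("zero offspring weight: population extinct")
  cbind(zf / sum(zf), zm / sum(zm))
}

#' Advance the population one generation
#'
#' Expected-value (deterministic) update of the genotype-frequency
#' recursion.  Sterile females do not reproduce; female fecundity and male
#' mating-success multipliers weight the parents; gametes reflect germline
#' conversion, resistance formation, and off-target cutting; embryo cutting
#' applies to offspring of drive-carrying mothers; viability weights the
#' offspring; sexes are born 1:1.
#'
#' If no female can reproduce or the total offspring weight is zero, a
#' classed `drive_extinction` condition is signaled (see
#' [is_extinction()]).
#'
#' @param state A normalized [population_state()].
#' @param p A [drive_params()] object.
#' @param spec A [fitness_spec()]; default neutral.
#' @return The next generation's `population_state`.
#' @examples
#' st <- founder_state(0.088, drive_params())
#' carrier_frequency(next_generation(st, drive_params()))
#' @export
next_generation <- function(state, p, spec = fitness_spec()) {
  m <- .check_state(state)
  .validate_drive_params(p)
  stopifnot(inherits(spec, "fitness_spec"))
  ctx <- .model_context(p)
  fv <- .fitness_vectors(spec)
  .new_state(.next_gen_mat(m, ctx, fv))
}

# load on a plain matrix; returns per-female reproductive output relative
# to an all-wild-type population (which scores exactly 1 in these units)
.load_mat <- function(m, ctx, fv) {
  fertile <- sum(m[!.sterile30, 1])
  wm <- m[, 2] * fv$mat
  if (sum(wm) <= 0) return(list(load = 1, fertile_female_fraction = fertile))
  wf <- m[, 1] * fv$fec
  wf[.sterile30] <- 0
  pool <- as.vector(crossprod(ctx$Gm, wm / sum(wm)))
  mix <- matrix(as.vector(wf %*% ctx$O2), .N_GENO, 8L)
  out <- sum(as.vector(mix %*% pool) * fv$via)
  list(load = 1 - out, fertile_female_fraction = fertile)
}

#' Genetic load of a population state
#'
#' The fractional reduction in per-capita reproductive output relative to
#' an all-wild-type population of the same size: 0 means no loss of
#' reproductive capacity, 1 means the population can no longer reproduce.
#' Accounts for female sterility, fecundity and mating-success costs, and
#' the viability of the offspring the current females would produce
#' (including embryo cutting).  The fraction of fertile females is reported
#' alongside.
#'
#' @inheritParams next_generation
#' @return A list of class `load_report` with elements `genetic_load` and
#'   `fertile_female_fraction`.
#' @export
genetic_load <- function(state, p, spec = fitness_spec()) {
  m <- .check_state(state)
  .validate_drive_params(p)
  ctx <- .model_context(p)
  fv <- .fitness_vectors(spec)
  r <- .load_mat(m, ctx, fv)
  structure(list(genetic_load = min(max(r$load, 0), 1),
                 fertile_female_fraction = r$fertile_female_fraction),
            class = "load_report")
}

#' @export
print.load_report <- function(x, ...) {
  cat(sprintf("<load_report> genetic load %.4f | fertile females %.4f\n",
              x$genetic_load, x$fertile_female_fraction))
  invisible(x)
}
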