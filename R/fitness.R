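# Fitness multipliers.  All models use the square-root rule for
# heterozygotes (multiplicative costs between alleles) except the somatic
# cleavage model, whose parameter is already the net heterozygote fitness.

# per-spec multiplier vectors over the 30 sex-free genotypes
.fitness_vectors <- function(spec) {
  w <- spec$homozygote_fitness
  fec <- rep(1, .N_GENO)   # applies to females
  mat <- rep(1, .N_GENO)   # applies to males
  via <- rep(1, .N_GENO)   # applies to both sexes
  switch(spec$model,
    NEUTRAL = NULL,
    DIRECT_VIABILITY = {
      via <- w^(.ndrive30 / 2)
    },
    DIRECT_FECUNDITY_MATING = {
      fec <- w^(.ndrive30 / 2)
      mat <- w^(.ndrive30 / 2)
    },
    OFFTARGET_VIABILITY = {
      via <- w^(.ndis30 / 2)
    },
    OFFTARGET_FECUNDITY_MATING = {
      fec <- w^(.ndis30 / 2)
      mat <- w^(.ndis30 / 2)
    },
    SOMATIC_HET_FECUNDITY = {
      het <- .gi(2L, 1:3)  # DRIVE/WT, any off-target pair
      fec[het] <- w
    },
    stop("unknown fitness model: ", spec$model)
  )
  list(fec = fec, mat = mat, via = via)
}

#' Fitness multipliers of a genotype
#'
#' Returns the three multiplicative fitness components of a genotype under
#' a fitness-cost model: fecundity (females), mating success (males), and
#' viability (both sexes).  Components not touched by the model are 1.
#' Female sterility from lacking a functional target-gene allele is handled
#' separately by [is_female_sterile()] and is not part of these
#' multipliers.
#'
#' @param g A [genotype()].
#' @param spec A [fitness_spec()].
#' @return Named numeric vector `c(fecundity, mating, viability)`.
#' @examples
#' genotype_fitness(genotype(c("DRIVE", "WT")),
#'                  fitness_spec("DIRECT_VIABILITY", 0.8))
#' @export
genotype_fitness <- function(g, spec) {
  stopifnot(inherits(g, "drive_genotype"), inherits(spec, "fitness_spec"))
  fv <- .fitness_vectors(spec)
  gi <- .geno_index(g)
  fec <- if (g$sex == "FEMALE") fv$fec[gi] else 1
  mat <- if (g$sex == "MALE") fv$mat[gi] else 1
  c(fecundity = fec, mating = mat, viability = fv$via[gi])
}
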