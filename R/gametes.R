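# Gamete formation and embryo cutting.
#
# Germline events in a Cas9-bearing drive carrier: each wild-type allele at
# the drive locus is converted to DRIVE with probability c, to R1 with
# probability rho * g, to R2 with probability (1 - rho) * g, and remains WT
# otherwise (conversion and resistance formation compete at the same
# germline stage).  Each INTACT off-target allele is disrupted with
# probability u.  Each locus then transmits one allele Mendelianly; the two
# loci are unlinked, so transmissions are independent.

# allele-level germline maps -------------------------------------------------

.germline_drive_dist <- function(allele, conv, p, cutting) {
  v <- numeric(4)
  if (cutting && allele == 1L) {
    g <- p$germline_resistance_total
    v[1] <- 1 - conv - g
    v[2] <- conv
    v[3] <- p$relative_r1_rate * g
    v[4] <- (1 - p$relative_r1_rate) * g
  } else v[allele] <- 1
  v
}

.germline_ot_dist <- function(allele, p, cutting) {
  v <- numeric(2)
  if (cutting && allele == 1L) {
    v[1] <- 1 - p$offtarget_germline_cut_rate
    v[2] <- p$offtarget_germline_cut_rate
  } else v[allele] <- 1
  v
}

# 8-vector of gamete probabilities, index (drive_allele - 1) * 2 + ot_allele
.gamete_vec <- function(dpi, opi, p, sex) {
  al <- .drive_pairs[dpi, ]
  ot <- .ot_pairs[opi, ]
  cutting <- p$cas9_present && any(al == 2L)
  conv <- if (sex == "FEMALE") p$conversion_female else p$conversion_male
  dm <- 0.5 * (.germline_drive_dist(al[1], conv, p, cutting) +
               .germline_drive_dist(al[2], conv, p, cutting))
  om <- 0.5 * (.germline_ot_dist(ot[1], p, cutting) +
               .germline_ot_dist(ot[2], p, cutting))
  as.vector(t(outer(dm, om)))  # dm major: (da - 1) * 2 + oa
}

# 30 x 8 gamete matrix for all sex-free genotypes of one parental sex
.gamete_matrix <- function(p, sex) {
  G <- matrix(0, .N_GENO, 8L)
  for (dpi in 1:10) for (opi in 1:3)
    G[.gi(dpi, opi), ] <- .gamete_vec(dpi, opi, p, sex)
  G
}

#' Germline gamete distribution of a parent
#'
#' Probability distribution over (drive-locus allele, off-target allele)
#' gametes produced by a parent, after germline drive conversion,
#' resistance allele formation, and off-target cutting.  Conversion uses
#' the rate matching the parent's sex.
#'
#' @param parent A [genotype()].
#' @param p A [drive_params()] object.
#' @return A data frame with columns `drive_allele`, `offtarget_allele`,
#'   `probability` (8 rows summing to 1).
#' @examples
#' germline_gamete_distribution(genotype(c("DRIVE", "WT")), drive_params())
#' @export
germline_gamete_distribution <- function(parent, p) {
  stopifnot(inherits(parent, "drive_genotype"))
  .validate_drive_params(p)
  v <- .gamete_vec(parent$dpi, parent$opi, p, parent$sex)
  data.frame(
    drive_allele = rep(DRIVE_ALLELES, each = 2L),
    offtarget_allele = rep(OFFTARGET_ALLELES, times = 4L),
    probability = v,
    stringsAsFactors = FALSE
  )
}

# embryo cutting -------------------------------------------------------------

# per-allele embryo map: WT -> {WT: 1-e, R1: e*rho, R2: e*(1-rho)}
.embryo_allele_dist <- function(allele, p) {
  v <- numeric(4)
  if (allele == 1L) {
    e <- p$embryo_cut_rate
    v[1] <- 1 - e
    v[3] <- e * p$relative_r1_rate
    v[4] <- e * (1 - p$relative_r1_rate)
  } else v[allele] <- 1
  v
}

# 10 x 10 transition matrix on drive pairs (column = source pair)
.embryo_matrix10 <- function(p) {
  E <- matrix(0, 10, 10)
  for (k in 1:10) {
    va <- .embryo_allele_dist(.drive_pairs[k, 1], p)
    vb <- .embryo_allele_dist(.drive_pairs[k, 2], p)
    for (i in 1:4) for (j in 1:4) {
      pr <- va[i] * vb[j]
      if (pr > 0) E[.pair4[i, j], k] <- E[.pair4[i, j], k] + pr
    }
  }
  E
}

# 30 x 30 version acting on full sex-free genotype distributions
.embryo_matrix30 <- function(p) kronecker(.embryo_matrix10(p), diag(3))

#' Apply embryo-stage resistance allele formation
#'
#' If the mother carries at least one drive allele (and Cas9 is present),
#' maternally deposited Cas9/gRNA cleaves each wild-type drive-locus allele
#' of each offspring independently with probability `embryo_cut_rate`,
#' forming r1 vs r2 alleles in proportion `relative_r1_rate` to
#' `1 - relative_r1_rate`.  Off-target alleles are not cut at the embryo
#' stage.  With a drive-free mother the distribution is returned unchanged.
#'
#' @param offspring_dist A normalized [population_state()] of offspring
#'   genotype frequencies.
#' @param mother The mother's [genotype()].
#' @param p A [drive_params()] object.
#' @return A `population_state` with the embryo-cut distribution.
#' @export
apply_embryo_cutting <- function(offspring_dist, mother, p) {
  stopifnot(inherits(offspring_dist, "population_state"),
            inherits(mother, "drive_genotype"))
  .validate_drive_params(p)
  m <- unclass(offspring_dist)
  if (any(abs(colSums(m) - 1) > 1e-9))
    stop("offspring distribution is not normalized")
  if (p$cas9_present && .has_drive_dp[mother$dpi]) {
    E <- .embryo_matrix30(p)
    m <- E %*% m
  }
  .new_state(m)
}
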