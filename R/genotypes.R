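# Genotype space for the two-locus split-drive model.
#
# Drive locus alleles: WT, DRIVE, R1 (functional resistance), R2
# (nonfunctional resistance).  Off-target locus alleles: INTACT, DISRUPTED.
# A diploid genotype is an unordered pair at each locus plus a sex, giving
# 10 x 3 x 2 = 60 states.  Internally the 30 sex-free genotypes are indexed
# drive-pair-major: gi = (drive_pair - 1) * 3 + offtarget_pair.

DRIVE_ALLELES <- c("WT", "DRIVE", "R1", "R2")
OFFTARGET_ALLELES <- c("INTACT", "DISRUPTED")
SEXES <- c("FEMALE", "MALE")
FITNESS_MODELS <- c("NEUTRAL", "SOMATIC_HET_FECUNDITY", "DIRECT_VIABILITY",
                    "DIRECT_FECUNDITY_MATING", "OFFTARGET_VIABILITY",
                    "OFFTARGET_FECUNDITY_MATING")

# canonical unordered pairs, alleles sorted WT < DRIVE < R1 < R2
.drive_pairs <- local({
  m <- NULL
  for (a in 1:4) for (b in a:4) m <- rbind(m, c(a, b))
  m
})
.ot_pairs <- rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L))

# allele-pair -> pair-index lookups
.pair4 <- local({
  p <- matrix(0L, 4, 4)
  for (k in seq_len(nrow(.drive_pairs))) {
    p[.drive_pairs[k, 1], .drive_pairs[k, 2]] <- k
    p[.drive_pairs[k, 2], .drive_pairs[k, 1]] <- k
  }
  p
})
.pair2 <- local({
  p <- matrix(0L, 2, 2)
  for (k in seq_len(nrow(.ot_pairs))) {
    p[.ot_pairs[k, 1], .ot_pairs[k, 2]] <- k
    p[.ot_pairs[k, 2], .ot_pairs[k, 1]] <- k
  }
  p
})

.N_GENO <- 30L
.gi <- function(dpi, opi) (dpi - 1L) * 3L + opi

# per-drive-pair flags, expanded to the 30 sex-free genotypes
.has_drive_dp <- apply(.drive_pairs, 1, function(x) any(x == 2L))
.sterile_dp <- apply(.drive_pairs, 1, function(x) !any(x %in% c(1L, 3L)))
.ndrive_dp <- apply(.drive_pairs, 1, function(x) sum(x == 2L))
.ndis_op <- apply(.ot_pairs, 1, function(x) sum(x == 2L))

.carrier30 <- rep(.has_drive_dp, each = 3L)
.sterile30 <- rep(.sterile_dp, each = 3L)
.ndrive30 <- rep(.ndrive_dp, each = 3L)
.ndis30 <- rep(.ndis_op, times = 10L)

.pair_label <- function(pairs, alleles) {
  apply(pairs, 1, function(x) paste(alleles[x], collapse = "/"))
}
.drive_pair_labels <- .pair_label(.drive_pairs, DRIVE_ALLELES)
.ot_pair_labels <- .pair_label(.ot_pairs, OFFTARGET_ALLELES)

# labels for the 30 sex-free genotypes, drive-pair-major order
.geno_drive30 <- rep(.drive_pair_labels, each = 3L)
.geno_ot30 <- rep(.ot_pair_labels, times = 10L)

#' Enumerate the full genotype space
#'
#' Lists all 60 two-locus diploid genotype states in canonical order:
#' females before males; within a sex, drive-locus pairs ordered with
#' alleles sorted `WT < DRIVE < R1 < R2`, and for each drive pair the three
#' off-target pairs ordered `INTACT/INTACT`, `INTACT/DISRUPTED`,
#' `DISRUPTED/DISRUPTED`.  Pairs are unordered (`A/B` is the same state as
#' `B/A`), giving 10 drive pairs, 3 off-target pairs, and 2 sexes.
#'
#' @return A data frame with 60 rows and columns `genotype_drive`,
#'   `genotype_offtarget`, `sex`.
#' @examples
#' g <- enumerate_genotypes()
#' nrow(g)  # 60
#' @export
enumerate_genotypes <- function() {
  data.frame(
    genotype_drive = rep(.geno_drive30, times = 2L),
    genotype_offtarget = rep(.geno_ot30, times = 2L),
    sex = rep(SEXES, each = .N_GENO),
    stringsAsFactors = FALSE
  )
}

#' Construct a single genotype
#'
#' @param drive_pair Character vector of length 2 with values among
#'   `"WT"`, `"DRIVE"`, `"R1"`, `"R2"`.  Order is irrelevant.
#' @param offtarget_pair Character vector of length 2 with values among
#'   `"INTACT"`, `"DISRUPTED"`.
#' @param sex `"FEMALE"` or `"MALE"`.
#' @return An object of class `drive_genotype`.
#' @examples
#' genotype(c("DRIVE", "WT"), sex = "FEMALE")
#' @export
genotype <- function(drive_pair, offtarget_pair = c("INTACT", "INTACT"),
                     sex = "FEMALE") {
  d <- match(drive_pair, DRIVE_ALLELES)
  o <- match(offtarget_pair, OFFTARGET_ALLELES)
  if (length(d) != 2L || anyNA(d))
    stop("drive_pair must be two alleles among ", paste(DRIVE_ALLELES, collapse = ", "))
  if (length(o) != 2L || anyNA(o))
    stop("offtarget_pair must be two alleles among ", paste(OFFTARGET_ALLELES, collapse = ", "))
  sex <- match.arg(sex, SEXES)
  d <- sort(d)
  o <- sort(o)
  structure(
    list(drive = DRIVE_ALLELES[d], offtarget = OFFTARGET_ALLELES[o], sex = sex,
         dpi = .pair4[d[1], d[2]], opi = .pair2[o[1], o[2]]),
    class = "drive_genotype"
  )
}

#' @export
print.drive_genotype <- function(x, ...) {
  cat(sprintf("<genotype> %s | %s | %s\n",
              paste(x$drive, collapse = "/"),
              paste(x$offtarget, collapse = "/"), x$sex))
  invisible(x)
}

.geno_index <- function(g) .gi(g$dpi, g$opi)

#' Is a female genotype sterile?
#'
#' Females are sterile when neither drive-locus allele preserves the target
#' fertility gene, i.e. when both alleles are `DRIVE` or `R2`.  `WT` and
#' `R1` alleles each restore fertility; the rule is female-specific because
#' the target gene only affects female fertility.
#'
#' @param g A [genotype()] with `sex = "FEMALE"`.
#' @return `TRUE` if the female is sterile.
#' @examples
#' is_female_sterile(genotype(c("DRIVE", "DRIVE")))  # TRUE
#' is_female_sterile(genotype(c("DRIVE", "R1")))     # FALSE
#' @export
is_female_sterile <- function(g) {
  stopifnot(inherits(g, "drive_genotype"))
  if (g$sex != "FEMALE")
    stop("sterility rule applies to females only; got a MALE genotype")
  .sterile_dp[g$dpi]
}
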