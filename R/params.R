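#' Drive parameters
#'
#' Bundles the molecular rates of the drive system.  Defaults are the
#' experimentally measured values used throughout the package: drive
#' conversion 76.7% (average of the female rate 72.7% and male rate 80.7%,
#' applied to both sexes), total germline resistance allele formation
#' 22.2%, embryo cut rate 52.2% from maternally deposited Cas9, germline
#' off-target cut rate 1 in drive carriers, and 50% of off-target sites
#' already disrupted in founder drive carriers (which descend from male
#' drive heterozygotes).
#'
#' @param conversion_female,conversion_male Probability that a germline
#'   wild-type allele in a drive/wild-type heterozygote is converted to a
#'   drive allele, per parent sex.
#' @param germline_resistance_total Probability that the same allele instead
#'   becomes a resistance allele (r1 or r2 combined).  Conversion and
#'   resistance formation compete at the same germline stage, so
#'   `conversion + germline_resistance_total <= 1` per sex.
#' @param embryo_cut_rate Probability that each wild-type drive-locus allele
#'   of an offspring of a drive-carrying mother is cleaved in the embryo.
#' @param relative_r1_rate Fraction of newly formed resistance alleles that
#'   are functional (r1) rather than nonfunctional (r2).
#' @param offtarget_germline_cut_rate Probability that each intact
#'   off-target allele is disrupted in the germline of a Cas9-bearing drive
#'   carrier.
#' @param initial_offtarget_cut_fraction Fraction of off-target alleles
#'   already disrupted in founder drive carriers.
#' @param cas9_present If `FALSE` the drive is inert: conversion,
#'   resistance formation, and off-target cutting rates are all effectively
#'   zero (the split-Cas9 design).
#' @return An object of class `drive_params`.
#' @examples
#' drive_params()                       # measured defaults
#' drive_params(cas9_present = FALSE)   # no-Cas9 control
#' @export
drive_params <- function(conversion_female = 0.767,
                         conversion_male = 0.767,
                         germline_resistance_total = 0.222,
                         embryo_cut_rate = 0.522,
                         relative_r1_rate = 0,
                         offtarget_germline_cut_rate = 1,
                         initial_offtarget_cut_fraction = 0.5,
                         cas9_present = TRUE) {
  p <- list(conversion_female = conversion_female,
            conversion_male = conversion_male,
            germline_resistance_total = germline_resistance_total,
            embryo_cut_rate = embryo_cut_rate,
            relative_r1_rate = relative_r1_rate,
            offtarget_germline_cut_rate = offtarget_germline_cut_rate,
            initial_offtarget_cut_fraction = initial_offtarget_cut_fraction,
            cas9_present = isTRUE(cas9_present))
  .validate_drive_params(p)
  structure(p, class = "drive_params")
}

.validate_drive_params <- function(p) {
  rates <- p[setdiff(names(p), "cas9_present")]
  for (nm in names(rates)) {
    v <- rates[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("parameter '", nm, "' must be a single probability in [0, 1]")
  }
  if (p$conversion_female + p$germline_resistance_total > 1 + 1e-12)
    stop("conversion_female + germline_resistance_total exceeds 1")
  if (p$conversion_male + p$germline_resistance_total > 1 + 1e-12)
    stop("conversion_male + germline_resistance_total exceeds 1")
  invisible(p)
}

#' @export
print.drive_params <- function(x, ...) {
  cat("<drive_params>\n")
  for (nm in names(x)) cat(sprintf("  %-31s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Fitness-cost specification
#'
#' Selects one of the fitness-cost models and its homozygote-fitness
#' parameter `w`:
#' \describe{
#'   \item{NEUTRAL}{no cost beyond the sterility of females lacking a
#'     functional target-gene allele (`w` forced to 1).}
#'   \item{DIRECT_VIABILITY}{drive homozygotes have viability `w`,
#'     heterozygotes `sqrt(w)` (multiplicative costs).}
#'   \item{DIRECT_FECUNDITY_MATING}{female fecundity and male mating
#'     success scale with `w` the same way.}
#'   \item{OFFTARGET_VIABILITY, OFFTARGET_FECUNDITY_MATING}{the same two
#'     schemes keyed on disrupted off-target alleles instead of drive
#'     alleles.}
#'   \item{SOMATIC_HET_FECUNDITY}{somatic Cas9 cleavage: `w` is the net
#'     fecundity of female drive/wild-type heterozygotes; all other
#'     genotypes are unaffected.}
#' }
#'
#' @param model One of the model names above.
#' @param homozygote_fitness Positive fitness parameter `w` (net
#'   heterozygote fitness for `SOMATIC_HET_FECUNDITY`).
#' @return An object of class `fitness_spec`.
#' @examples
#' fitness_spec("DIRECT_VIABILITY", 0.8)
#' @export
fitness_spec <- function(model = "NEUTRAL", homozygote_fitness = 1) {
  model <- match.arg(model, FITNESS_MODELS)
  w <- homozygote_fitness
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w <= 0)
    stop("homozygote_fitness must be a single positive number")
  if (model == "NEUTRAL" && w != 1)
    stop("NEUTRAL fitness forces homozygote_fitness = 1")
  structure(list(model = model, homozygote_fitness = w),
            class = "fitness_spec")
}

#' @export
print.fitness_spec <- function(x, ...) {
  cat(sprintf("<fitness_spec> %s (w = %g)\n", x$model, x$homozygote_fitness))
  invisible(x)
}
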