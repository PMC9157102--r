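# Population state: per-sex genotype frequency distributions.
# Internally a 30 x 2 numeric matrix (columns FEMALE, MALE), each column a
# probability distribution over the sex-free genotypes in canonical order.
# Sexes are produced 1:1 at birth, so the state carries no sex ratio.

.new_state <- function(m) {
  dimnames(m) <- list(NULL, SEXES)
  structure(m, class = "population_state")
}

.check_state <- function(state) {
  m <- unclass(state)
  if (!is.matrix(m) || nrow(m) != .N_GENO || ncol(m) != 2L)
    stop("population_state must be a 30 x 2 frequency matrix")
  if (any(m < -1e-12)) stop("negative genotype frequencies")
  if (any(abs(colSums(m) - 1) > 1e-9))
    stop("each sex's genotype distribution must sum to 1")
  m
}

#' Construct a population state
#'
#' A population state holds, for each sex, a normalized frequency
#' distribution over the 30 two-locus genotypes (see
#' [enumerate_genotypes()]).  It can be built from a long-format data frame
#' with columns `genotype_drive`, `genotype_offtarget`, `sex`, `frequency`;
#' genotypes absent from the table get frequency 0 and allele order within
#' a pair is irrelevant.
#'
#' @param x A data frame as described above, or a 30 x 2 numeric matrix in
#'   canonical genotype order (columns FEMALE, MALE).
#' @return An object of class `population_state`.
#' @seealso [founder_state()], [as.data.frame.population_state()]
#' @export
population_state <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else if (is.data.frame(x)) {
    need <- c("genotype_drive", "genotype_offtarget", "sex", "frequency")
    if (!all(need %in% names(x)))
      stop("data frame must have columns ", paste(need, collapse = ", "))
    m <- matrix(0, .N_GENO, 2L)
    key <- function(lbl, alleles, pairs, lookup) {
      parts <- strsplit(lbl, "/", fixed = TRUE)
      vapply(parts, function(pp) {
        idx <- match(pp, alleles)
        if (length(idx) != 2L || anyNA(idx)) stop("bad allele pair: ", paste(pp, collapse = "/"))
        lookup[idx[1], idx[2]]
      }, integer(1))
    }
    dpi <- key(x$genotype_drive, DRIVE_ALLELES, .drive_pairs, .pair4)
    opi <- key(x$genotype_offtarget, OFFTARGET_ALLELES, .ot_pairs, .pair2)
    sx <- match(x$sex, SEXES)
    if (anyNA(sx)) stop("sex must be FEMALE or MALE")
    for (i in seq_len(nrow(x)))
      m[.gi(dpi[i], opi[i]), sx[i]] <- m[.gi(dpi[i], opi[i]), sx[i]] + x$frequency[i]
  } else stop("x must be a matrix or data frame")
  st <- .new_state(m)
  .check_state(st)
  st
}

#' @export
as.data.frame.population_state <- function(x, ...) {
  m <- unclass(x)
  data.frame(
    genotype_drive = rep(.geno_drive30, times = 2L),
    genotype_offtarget = rep(.geno_ot30, times = 2L),
    sex = rep(SEXES, each = .N_GENO),
    frequency = c(m[, 1], m[, 2]),
    stringsAsFactors = FALSE
  )
}

#' @export
print.population_state <- function(x, ...) {
  df <- as.data.frame(x)
  df <- df[df$frequency > 1e-12, ]
  cat(sprintf("<population_state> carrier frequency %.4f\n", carrier_frequency(x)))
  print.data.frame(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Founder population state
#'
#' The release composition used in the cage experiments: all drive carriers
#' are drive/wild-type heterozygotes whose off-target alleles are disrupted
#' independently with probability `initial_offtarget_cut_fraction`;
#' non-carriers are fully wild-type with intact off-target sites.  Both
#' sexes share the same composition.
#'
#' @param carrier_freq Initial drive-carrier frequency in `[0, 1]`.
#' @param p A [drive_params()] object.
#' @return A [population_state()].
#' @examples
#' founder_state(0.088, drive_params())
#' @export
founder_state <- function(carrier_freq, p = drive_params()) {
  .validate_drive_params(p)
  if (!is.numeric(carrier_freq) || carrier_freq < 0 || carrier_freq > 1)
    stop("carrier_freq must be in [0, 1]")
  q <- p$initial_offtarget_cut_fraction
  f <- numeric(.N_GENO)
  f[.gi(2L, 1:3)] <- carrier_freq * c((1 - q)^2, 2 * q * (1 - q), q^2)
  f[.gi(1L, 1L)] <- 1 - carrier_freq
  .new_state(cbind(f, f))
}

#' Drive-carrier frequency of a state
#'
#' Total frequency, pooled over both sexes (weighted 1:1), of genotypes
#' carrying at least one drive allele -- the DsRed-positive phenotype
#' scored in the cage experiments.
#'
#' @param state A [population_state()].
#' @return A number in `[0, 1]`.
#' @export
carrier_frequency <- function(state) {
  m <- .check_state(state)
  0.5 * sum(m[.carrier30, 1]) + 0.5 * sum(m[.carrier30, 2])
}

#' Write / read a population state as a delimited table
#'
#' Serializes the long-format view (columns `genotype_drive`,
#' `genotype_offtarget`, `sex`, `frequency`) as CSV.
#'
#' @param state A [population_state()].
#' @param path File path.
#' @return `read_population_state` returns a `population_state`;
#'   `write_population_state` returns `path` invisibly.
#' @export
write_population_state <- function(state, path) {
  utils::write.csv(as.data.frame(state), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population_state
#' @export
read_population_state <- function(path) {
  population_state(utils::read.csv(path, stringsAsFactors = FALSE))
}
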