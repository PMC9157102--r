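# Estimators turning raw cross counts into the headline molecular rates.
# All estimators are pure functions of the counts.

#' Offspring phenotype counts from drive-heterozygote crosses
#'
#' @param parent_sex `"FEMALE"` or `"MALE"` (sex of the drive-heterozygous
#'   parent crossed to wild-type).
#' @param with_drive,without_drive Pooled offspring counts with and without
#'   the DsRed drive phenotype.
#' @param batches Optional data frame of per-vial subcounts with columns
#'   `vial`, `with_drive`, `without_drive`; must sum to the totals.
#' @return An object of class `cross_counts`.
#' @export
cross_counts <- function(parent_sex, with_drive, without_drive,
                         batches = NULL) {
  parent_sex <- match.arg(parent_sex, SEXES)
  stopifnot(with_drive >= 0, without_drive >= 0)
  if (!is.null(batches)) {
    stopifnot(is.data.frame(batches),
              all(c("with_drive", "without_drive") %in% names(batches)))
    if (sum(batches$with_drive) != with_drive ||
        sum(batches$without_drive) != without_drive)
      stop("batch subcounts do not sum to the totals")
  }
  structure(list(parent_sex = parent_sex, with_drive = with_drive,
                 without_drive = without_drive, batches = batches),
            class = "cross_counts")
}

#' Sterility assay counts
#'
#' @param sterile,assessed Sterile count among assessed drive-carrier
#'   daughters of drive mothers.
#' @param baseline_sterile,baseline_assessed The same for the baseline
#'   group (drive-carrier daughters of drive fathers, no embryo exposure).
#' @return An object of class `sterility_counts`.
#' @export
sterility_counts <- function(sterile, assessed,
                             baseline_sterile, baseline_assessed) {
  stopifnot(sterile >= 0, assessed > 0, sterile <= assessed,
            baseline_sterile >= 0, baseline_assessed > 0,
            baseline_sterile <= baseline_assessed)
  structure(list(sterile = sterile, assessed = assessed,
                 baseline_sterile = baseline_sterile,
                 baseline_assessed = baseline_assessed),
            class = "sterility_counts")
}

#' Pooled drive inheritance rate
#'
#' Fraction of offspring showing the drive phenotype, with the binomial
#' standard error of the mean of the pooled proportion.
#'
#' @param x A [cross_counts()] object.
#' @return Named numeric vector `c(rate, sem)`.
#' @examples
#' inheritance_rate(cross_counts("FEMALE", 864, 136))
#' @export
inheritance_rate <- function(x) {
  stopifnot(inherits(x, "cross_counts"))
  n <- x$with_drive + x$without_drive
  if (n == 0) stop("no offspring counted")
  r <- x$with_drive / n
  c(rate = r, sem = sqrt(r * (1 - r) / n))
}

#' Drive conversion rate from an inheritance rate
#'
#' For a drive/wild-type heterozygote crossed to wild-type with no
#' viability differences among offspring, an inheritance rate `i` implies
#' that a fraction `2i - 1` of the germline wild-type alleles were
#' converted to drive alleles.
#'
#' @param i Inheritance rate in `[0, 1]`; values below 0.5 produce a
#'   warning (they imply negative conversion).
#' @return The conversion rate `2i - 1`.
#' @examples
#' conversion_from_inheritance(0.864)  # 0.728
#' @export
conversion_from_inheritance <- function(i) {
  if (!is.numeric(i) || i < 0 || i > 1)
    stop("inheritance rate must be in [0, 1]")
  if (i < 0.5)
    warning("inheritance below 0.5 implies a negative conversion rate")
  2 * i - 1
}

#' Average drive conversion rate over sexes
#'
#' Arithmetic mean of the female and male conversion rates, the summary
#' used to parameterize the recursion.
#'
#' @param c_female,c_male Conversion rates in `[0, 1]`.
#' @return The mean rate.
#' @examples
#' average_conversion(0.727, 0.807)  # 0.767
#' @export
average_conversion <- function(c_female, c_male) {
  stopifnot(c_female >= 0, c_female <= 1, c_male >= 0, c_male <= 1)
  (c_female + c_male) / 2
}

#' Embryo resistance allele formation rate from a sterility assay
#'
#' Solves `baseline + (1 - baseline) * r = observed` for `r`, where
#' `observed` is the sterility rate of drive-carrier daughters of drive
#' mothers and `baseline` the background sterility of the laboratory
#' stock: the excess sterility attributable to embryo cutting of the
#' paternal wild-type allele.
#'
#' @param s A [sterility_counts()] object.
#' @return The embryo resistance allele formation rate.
#' @examples
#' embryo_rate_from_sterility(sterility_counts(12, 22, 1, 20))  # 0.522
#' @export
embryo_rate_from_sterility <- function(s) {
  stopifnot(inherits(s, "sterility_counts"))
  s_obs <- s$sterile / s$assessed
  s_base <- s$baseline_sterile / s$baseline_assessed
  if (s_obs < s_base)
    stop("observed sterility below baseline: negative rate is not a rate")
  (s_obs - s_base) / (1 - s_base)
}

#' Read cross and sterility count tables
#'
#' `read_cross_counts` expects a CSV with header
#' `parent_sex,with_drive,without_drive` and optionally `vial`; rows
#' sharing a `parent_sex` are pooled, with vial rows retained as batches.
#' `read_sterility_counts` expects one row with header
#' `sterile,assessed,baseline_sterile,baseline_assessed`.
#'
#' @param path CSV file path.
#' @return A list of [cross_counts()] (one per parent sex present), or a
#'   [sterility_counts()].
#' @export
read_cross_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("parent_sex", "with_drive", "without_drive")
  if (!all(need %in% names(df)))
    stop("cross counts file needs columns ", paste(need, collapse = ", "))
  lapply(split(df, df$parent_sex), function(d) {
    batches <- if ("vial" %in% names(d) && nrow(d) > 1)
      d[c("vial", "with_drive", "without_drive")] else NULL
    cross_counts(d$parent_sex[1], sum(d$with_drive), sum(d$without_drive),
                 batches = batches)
  })
}

#' @rdname read_cross_counts
#' @export
read_sterility_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sterile", "assessed", "baseline_sterile", "baseline_assessed")
  if (!all(need %in% names(df)))
    stop("sterility counts file needs columns ", paste(need, collapse = ", "))
  sterility_counts(df$sterile[1], df$assessed[1],
                   df$baseline_sterile[1], df$baseline_assessed[1])
}
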