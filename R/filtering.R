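#' Remove rare OTUs
#'
#' Applies the two sequential rarity rules used upstream of network
#' construction. Rule 1 removes an OTU only if its count is below
#' `min_count_everywhere` in *every* sample of both conditions (an OTU
#' reaching the threshold anywhere survives). Rule 2 then removes an
#' OTU whose count is below `min_count_prevalence` in at least
#' `prevalence_frac` of the samples. Counts of surviving OTUs are never
#' modified, and the filter is idempotent.
#'
#' @param x an [OtuExperiment-class].
#' @param min_count_everywhere rule-1 count threshold (default 10).
#' @param min_count_prevalence rule-2 count threshold (default 5).
#' @param prevalence_frac rule-2 sample fraction (default 0.5).
#' @return the filtered `OtuExperiment`; the attached
#'   [FilterReport-class] is available via [filterReport()].
#' @export
filterRareOtus <- function(x, min_count_everywhere = 10,
                           min_count_prevalence = 5,
                           prevalence_frac = 0.5) {
  cnt <- otuCounts(x)
  rule1 <- apply(cnt < min_count_everywhere, 1, all)
  kept1 <- cnt[!rule1, , drop = FALSE]
  rule2 <- rowMeans(kept1 < min_count_prevalence) >= prevalence_frac
  surviving <- rownames(kept1)[!rule2]
  if (!length(surviving)) stop("all OTUs filtered")
  rep <- new("FilterReport",
             nInput = nrow(cnt),
             nRemovedRule1 = sum(rule1),
             nRemovedRule2 = sum(rule2),
             nRemovedSamples =
               as.integer(metadata(x)$n_removed_samples %||% 0L),
             survivingIds = surviving)
  out <- x[surviving, ]
  out@filterReport <- rep
  validObject(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Column-normalised relative abundances
#'
#' @param x an [OtuExperiment-class] or a non-negative count matrix
#'   (OTUs x samples).
#' @return numeric OTU x sample matrix of fractions; every column sums
#'   to 1. An all-zero sample is an error naming the sample.
#' @export
relativeAbundance <- function(x) {
  cnt <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
  cs <- colSums(cnt)
  if (any(cs == 0))
    stop("all-zero sample(s): ",
         paste(colnames(cnt)[cs == 0], collapse = ", "))
  sweep(cnt, 2, cs, "/")
}

#' Log-transform relative abundances for network construction
#'
#' Returns `log10(fraction + pseudocount)` with samples as rows
#' (observations) and OTUs as columns (variables), the orientation
#' expected by the correlation-network functions. The default
#' pseudocount is half the smallest non-zero fraction in the table, a
#' standard choice for compositional data entering correlation
#' analysis.
#'
#' @param relab OTU x sample fraction matrix from
#'   [relativeAbundance()].
#' @param pseudocount positive offset added before the log; default
#'   half the smallest non-zero fraction.
#' @return sample x OTU numeric matrix; zero-variance OTU columns are
#'   flagged in the `"zero_variance"` attribute.
#' @export
transformForNetwork <- function(relab, pseudocount = NULL) {
  relab <- as.matrix(relab)
  if (is.null(pseudocount)) {
    nz <- relab[relab > 0]
    if (!length(nz)) stop("table has no non-zero fractions")
    pseudocount <- min(nz) / 2
  }
  if (pseudocount <= 0) stop("pseudocount must be positive")
  out <- t(log10(relab + pseudocount))
  zv <- apply(out, 2, function(v) var(v) == 0)
  attr(out, "pseudocount") <- pseudocount
  attr(out, "zero_variance") <- colnames(out)[zv]
  out
}

#' Relative daily nitrate dose
#'
#' Converts a daily nitrate dose in mg to mmol per kg body mass per
#' day using the molar mass of nitrate, 62.004 g/mol.
#'
#' @param dose_mg_per_day daily dose in mg.
#' @param body_mass_kg body mass in kg (> 0).
#' @param digits if non-NULL, round the result half-away-from-zero to
#'   this many decimals (report display convention).
#' @return dose in mmol.kg^-1.d^-1.
#' @examples
#' computeRelativeDose(750, 70.5, digits = 2)
#' @export
computeRelativeDose <- function(dose_mg_per_day, body_mass_kg,
                                digits = NULL) {
  if (any(body_mass_kg <= 0)) stop("body mass must be positive")
  out <- (dose_mg_per_day / 62.004) / body_mass_kg
  if (!is.null(digits)) out <- roundHalfAway(out, digits)
  out
}

#' Round half away from zero
#'
#' Commercial rounding used for report display (R's `round()` rounds
#' half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
roundHalfAway <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
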