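#' Prevalence threshold for differential-abundance testing
#'
#' Marks taxa whose overall mean relative abundance across all samples
#' strictly exceeds `min_frac_of_total` (default 1e-4, i.e. >0.01% of
#' total bacteria) as eligible for testing.
#'
#' @param relab OTU x sample fraction matrix.
#' @param min_frac_of_total strict lower bound on the overall mean
#'   fraction.
#' @return logical vector, one entry per taxon.
#' @export
prevalenceThreshold <- function(relab, min_frac_of_total = 1e-4) {
  rowMeans(relab) > min_frac_of_total
}

#' Paired t-test on subject-matched abundances
#'
#' Two-sided paired t-test, t = mean(d) / (sd(d)/sqrt(n)) on the
#' within-subject differences d, with n-1 degrees of freedom.
#' Degenerate inputs are resolved explicitly: all-zero differences give
#' t = 0, p = 1; zero-variance differences with non-zero mean give
#' p = 0 with `degenerate = TRUE`.
#'
#' @param x_pl,x_br numeric vectors of equal length >= 3, matched by
#'   subject.
#' @return list with `t`, `p`, `degenerate`.
#' @export
pairedTTest <- function(x_pl, x_br) {
  if (length(x_pl) != length(x_br)) stop("vectors must be paired")
  if (length(x_pl) < 3) stop("need at least 3 pairs")
  d <- x_br - x_pl
  if (all(d == 0)) return(list(t = 0, p = 1, degenerate = FALSE))
  if (sd(d) == 0)
    return(list(t = sign(mean(d)) * Inf, p = 0, degenerate = TRUE))
  ht <- t.test(x_br, x_pl, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted q-values capped at 1 with monotonicity enforced;
#' `q[i] = min over j with p_(j) >= p_(i) of p_(j) * m / rank(j)`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Percent change between condition means
#'
#' 100 * (mean_br - mean_pl) / mean_pl; undefined (NA) when the
#' placebo mean is zero. Report tables display it rounded half away
#' from zero to the nearest integer percent.
#'
#' @param mean_pl,mean_br per-condition mean relative abundances.
#' @return percent change (not rounded).
#' @examples
#' percentChange(0.010, 0.0359)  # +259
#' @export
percentChange <- function(mean_pl, mean_br) {
  ifelse(mean_pl > 0, 100 * (mean_br - mean_pl) / mean_pl, NA_real_)
}

.rank_index <- c(phylum = 1L, class = 2L, order = 3L, family = 4L,
                 genus = 5L, species = 6L)

#' Roll relative abundances up to a taxonomic rank
#'
#' Sums fractions over taxa sharing the lineage prefix down to `rank`.
#' Lineages are semicolon-delimited `phylum;class;order;family;genus;
#' species`; taxa with missing lineage at that rank are grouped under
#' `"unclassified"`.
#'
#' @param relab OTU x sample fraction matrix.
#' @param taxonomy lineage strings, one per row of `relab`.
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, `"species"`, or `"otu"` (no rollup).
#' @return taxon x sample fraction matrix.
#' @export
rollupRank <- function(relab, taxonomy, rank = "species") {
  if (rank == "otu") return(relab)
  idx <- .rank_index[[rank]]
  parts <- strsplit(ifelse(is.na(taxonomy), "", taxonomy), ";", fixed = TRUE)
  key <- vapply(parts, function(pp) {
    if (length(pp) >= idx && nzchar(trimws(pp[idx])))
      paste(trimws(pp[seq_len(idx)]), collapse = ";")
    else "unclassified"
  }, "")
  rs <- rowsum(relab, key)
  rs[order(rownames(rs)), , drop = FALSE]
}

#' Paired differential abundance with BH correction
#'
#' The full differential-abundance stage: relative abundances (rolled
#' up to `rank` if requested), the >0.01%-style prevalence screen,
#' subject-paired t-tests between conditions, Benjamini-Hochberg
#' correction over the tested taxa, and percent-change reporting.
#'
#' @param x an [OtuExperiment-class].
#' @param rank taxonomic rank for rollup (see [rollupRank()]).
#' @param alpha significance level on BH q-values (default 0.05).
#' @param min_frac_of_total prevalence screen threshold (default 1e-4).
#' @param log_transform run the t-tests on log10(fraction +
#'   pseudocount) rather than raw fractions (default TRUE; abundance
#'   fractions are strongly right-skewed, and a multiplicative model
#'   is the standard testing scale for them). Means and percent
#'   changes are always reported on the raw fraction scale.
#' @return data.frame with one row per taxon: `taxon`, `mean_PL`,
#'   `mean_BR`, `percent_change`, `t_statistic`, `p_raw`, `q_bh`,
#'   `tested`, `significant`; ordered by `p_raw` among tested taxa.
#' @export
differentialAbundance <- function(x, rank = "otu", alpha = 0.05,
                                  min_frac_of_total = 1e-4,
                                  log_transform = TRUE) {
  relab <- relativeAbundance(x)
  relab <- rollupRank(relab, otuTaxonomy(x), rank)
  cond <- sampleCondition(x)
  subj <- sampleSubject(x)
  pl_cols <- which(cond == "PL")[order(subj[cond == "PL"])]
  br_cols <- which(cond == "BR")[order(subj[cond == "BR"])]
  tested <- prevalenceThreshold(relab, min_frac_of_total)
  mean_pl <- rowMeans(relab[, pl_cols, drop = FALSE])
  mean_br <- rowMeans(relab[, br_cols, drop = FALSE])
  test_mat <- relab
  if (log_transform) {
    nz <- relab[relab > 0]
    pc <- if (length(nz)) min(nz) / 2 else 1e-8
    test_mat <- log10(relab + pc)
  }
  tt <- lapply(rownames(relab), function(tx) {
    if (!tested[tx]) return(list(t = NA_real_, p = NA_real_))
    pairedTTest(test_mat[tx, pl_cols], test_mat[tx, br_cols])
  })
  p_raw <- vapply(tt, `[[`, 0, "p")
  q <- rep(NA_real_, length(p_raw))
  q[tested] <- bhAdjust(p_raw[tested])
  out <- data.frame(
    taxon = rownames(relab),
    mean_PL = mean_pl, mean_BR = mean_br,
    percent_change = percentChange(mean_pl, mean_br),
    t_statistic = vapply(tt, `[[`, 0, "t"),
    p_raw = p_raw, q_bh = q, tested = tested,
    significant = !is.na(q) & q <= alpha,
    row.names = NULL
  )
  out[order(!out$tested, out$p_raw), ]
}
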