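#' @import methods
#' @importFrom stats cor sd var prcomp pt p.adjust t.test kruskal.test
#'   hclust cutree as.dist quantile rnorm runif rgamma rmultinom qt
#'   setNames complete.cases aggregate lm coef pchisq median
#' @importFrom utils read.delim write.table packageVersion modifyList
NULL

#' Paired OTU count experiment
#'
#' `OtuExperiment` is a thin extension of
#' [SummarizedExperiment::SummarizedExperiment] holding an OTU-by-sample
#' count matrix for a paired two-condition (crossover) design. The
#' `counts` assay stores non-negative integer counts; `colData` carries
#' `subject` and `condition` (a factor with levels `PL`, the placebo
#' condition, and `BR`, the nitrate condition); `rowData` carries the
#' semicolon-delimited taxonomic lineage of each OTU.
#'
#' Validity requires non-negative integer counts, unique OTU identifiers,
#' at least two samples, and every subject present exactly once per
#' condition (the constructor drops incomplete subjects with a warning
#' before validity is checked).
#'
#' @slot filterReport `NULL` or a [FilterReport-class] recording the rare-OTU
#'   filtering applied to produce this object.
#' @export
setClass("OtuExperiment",
  contains = "SummarizedExperiment",
  slots = c(filterReport = "ANY"),
  prototype = prototype(filterReport = NULL)
)

#' Report of rare-OTU filtering
#'
#' Records how many OTUs each sequential filtering rule removed. Rule 1
#' removes OTUs whose count is below `min_count_everywhere` in every
#' sample of both conditions; rule 2 then removes OTUs with fewer than
#' `min_count_prevalence` counts in at least `prevalence_frac` of the
#' remaining samples.
#'
#' @slot nInput number of OTUs before filtering.
#' @slot nRemovedRule1,nRemovedRule2 OTUs removed by each rule (each OTU
#'   counted once; rules are applied sequentially).
#' @slot nRemovedSamples samples dropped because the subject lacked one
#'   condition.
#' @slot survivingIds character vector of OTU ids retained.
#' @export
setClass("FilterReport", slots = c(
  nInput = "integer",
  nRemovedRule1 = "integer",
  nRemovedRule2 = "integer",
  nRemovedSamples = "integer",
  survivingIds = "character"
))

setValidity("FilterReport", function(object) {
  if (object@nInput != length(object@survivingIds) +
      object@nRemovedRule1 + object@nRemovedRule2)
    return("input count must equal surviving + removed (rule1 + rule2)")
  TRUE
})

#' Host trait table for a paired design
#'
#' Subject-by-trait matrices of physiological and cognitive traits, one
#' matrix per dietary condition plus an optional baseline-only matrix
#' (e.g. ACE-III cognitive subscores measured once, before the
#' intervention). Missing values are `NA`.
#'
#' @slot pl,br numeric subject x trait matrices for the placebo and
#'   nitrate conditions (identical rownames and colnames).
#' @slot base numeric subject x trait matrix of baseline-only traits
#'   (possibly 0 columns).
#' @slot units named character vector of units per trait (may be empty).
#' @export
setClass("TraitTable", slots = c(
  pl = "matrix", br = "matrix", base = "matrix", units = "character"
))

setValidity("TraitTable", function(object) {
  if (!identical(rownames(object@pl), rownames(object@br)))
    return("PL and BR trait matrices must share subjects (rownames)")
  if (!identical(colnames(object@pl), colnames(object@br)))
    return("PL and BR trait matrices must share traits (colnames)")
  if (ncol(object@base) > 0 &&
      !identical(rownames(object@base), rownames(object@pl)))
    return("baseline trait matrix must share subjects with PL/BR")
  TRUE
})

#' Signed weighted co-occurrence network
#'
#' Holds the signed adjacency and topological overlap matrices of one
#' condition (or of the consensus across conditions), together with the
#' soft-threshold power used.
#'
#' @slot adjacency symmetric OTU x OTU matrix in \[0, 1\] (unit diagonal
#'   by convention; the diagonal is excluded from connectivity sums).
#' @slot tom symmetric topological overlap matrix in \[0, 1\].
#' @slot beta positive integer soft-threshold power.
#' @slot condition label: `"PL"`, `"BR"` or `"consensus"`.
#' @export
setClass("CooccurrenceNetwork", slots = c(
  adjacency = "matrix", tom = "matrix", beta = "integer",
  condition = "character"
))

setValidity("CooccurrenceNetwork", function(object) {
  if (nrow(object@tom) != ncol(object@tom)) return("TOM must be square")
  if (max(abs(object@tom - t(object@tom))) > 1e-8)
    return("TOM must be symmetric")
  if (min(object@tom) < -1e-12 || max(object@tom) > 1 + 1e-8)
    return("TOM entries must lie in [0, 1]")
  TRUE
})

#' Module assignment and eigengenes
#'
#' The result of hierarchical module detection on a topological overlap
#' matrix: per-OTU module labels (0 = unassigned, the conventional
#' "grey" module), the clustering dendrogram, per-condition module
#' eigengene matrices, and per-OTU module membership (kME).
#'
#' @slot labels named integer vector, one entry per OTU; 0 means
#'   unassigned.
#' @slot dendro the average-linkage `hclust` object on `1 - TOM`.
#' @slot eigengenes named list of sample x module eigengene matrices,
#'   one per condition.
#' @slot kme named list of OTU x module matrices of correlations with
#'   each eigengene, one per condition.
#' @slot minModuleSize integer, the minimum size used at detection.
#' @export
setClass("ModuleSet", slots = c(
  labels = "integer", dendro = "ANY", eigengenes = "list",
  kme = "list", minModuleSize = "integer"
))

setValidity("ModuleSet", function(object) {
  sz <- table(object@labels[object@labels > 0])
  if (length(sz) && any(sz < object@minModuleSize))
    return("non-grey module smaller than minModuleSize")
  TRUE
})

#' Module eigengene by trait correlation network
#'
#' Pearson correlations (and two-sided Student p-values) between module
#' eigengenes and host traits for one condition, or their consensus
#' across conditions. `n` records the number of complete pairs behind
#' each cell; cells with fewer than 4 complete pairs are `NA`.
#'
#' @slot r,p,n module x trait matrices of correlations, p-values and
#'   pair counts.
#' @slot condition `"PL"`, `"BR"` or `"consensus"`.
#' @export
setClass("ModuleTraitNetwork", slots = c(
  r = "matrix", p = "matrix", n = "matrix", condition = "character"
))

setValidity("ModuleTraitNetwork", function(object) {
  if (!identical(dim(object@r), dim(object@p)))
    return("r and p must have identical dimensions")
  r <- object@r[!is.na(object@r)]
  if (length(r) && max(abs(r)) > 1 + 1e-12) return("|r| must be <= 1")
  p <- object@p[!is.na(object@p)]
  if (length(p) && (min(p) < 0 || max(p) > 1)) return("p must lie in [0,1]")
  TRUE
})

#' LDA effect-size screening result
#'
#' Per (module, OTU) output of the two-stage biomarker screen:
#' Kruskal-Wallis p-value, signed log10 LDA effect size, the enriched
#' class, and whether the OTU passes both the significance and effect
#' thresholds.
#'
#' @slot table data.frame with columns `module`, `otu_id`, `kw_p`,
#'   `lda_effect`, `enriched_class`, `passes`.
#' @slot threshold log10 LDA effect threshold used for `passes`.
#' @slot alpha Kruskal-Wallis significance level used for `passes`.
#' @export
setClass("LefseResult", slots = c(
  table = "data.frame", threshold = "numeric", alpha = "numeric"
))

setValidity("LefseResult", function(object) {
  tb <- object@table
  need <- c("module", "otu_id", "kw_p", "lda_effect", "enriched_class",
            "passes")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  bad <- tb$passes & !is.na(tb$kw_p) & tb$kw_p > object@alpha
  if (any(bad, na.rm = TRUE))
    return("passing OTUs must satisfy the Kruskal-Wallis alpha")
  TRUE
})

#' Planted ground truth of a synthetic dataset
#'
#' @slot moduleOf named integer vector: planted module of each OTU
#'   (0 = background).
#' @slot conditionLogFc named numeric vector: planted log fold change
#'   (BR vs PL, natural log) per OTU.
#' @slot traitLoadings data.frame with columns `trait`, `module`,
#'   `target_r`, `scope` (`both` for stable couplings, `PL`/`BR` for
#'   condition-specific ones, `BASE` for baseline-only traits).
#' @slot seed integer seed the dataset was generated from.
#' @slot params list of generator parameters.
#' @export
setClass("SyntheticTruth", slots = c(
  moduleOf = "integer", conditionLogFc = "numeric",
  traitLoadings = "data.frame", seed = "integer", params = "list"
))

#' A paired synthetic microbiome dataset with ground truth
#'
#' @slot otus an [OtuExperiment-class] with paired PL/BR samples.
#' @slot traits a [TraitTable-class].
#' @slot truth a [SyntheticTruth-class].
#' @export
setClass("SyntheticDataset", slots = c(
  otus = "OtuExperiment", traits = "TraitTable", truth = "SyntheticTruth"
))
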