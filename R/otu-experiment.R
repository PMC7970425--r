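#' Construct a paired OTU experiment
#'
#' Builds an [OtuExperiment-class] from a count matrix and per-sample
#' subject/condition labels. Subjects present in only one of the two
#' conditions are dropped (with a warning), mirroring the exclusion of
#' incomplete crossover participants.
#'
#' @param counts non-negative integer matrix, OTUs in rows (unique
#'   rownames), samples in columns.
#' @param subject character vector of subject identifiers, one per
#'   sample column.
#' @param condition vector of condition labels, `"PL"` (placebo) or
#'   `"BR"` (nitrate), one per sample column.
#' @param taxonomy optional character vector of semicolon-delimited
#'   lineages, one per OTU.
#' @return a validated `OtuExperiment`.
#' @examples
#' cnt <- matrix(rpois(12, 20), 3, 4,
#'               dimnames = list(paste0("OTU", 1:3), NULL))
#' oe <- OtuExperiment(cnt, subject = c("S1", "S1", "S2", "S2"),
#'                     condition = c("PL", "BR", "PL", "BR"))
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   rowData assayNames
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @export
OtuExperiment <- function(counts, subject, condition, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("counts must have OTU identifiers as rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  subject <- as.character(subject)
  condition <- as.character(condition)
  if (length(subject) != ncol(counts) || length(condition) != ncol(counts))
    stop("subject and condition must have one entry per sample column")
  if (!all(condition %in% c("PL", "BR")))
    stop("condition labels must be 'PL' or 'BR'")
  if (is.null(taxonomy)) taxonomy <- rep(NA_character_, nrow(counts))

  # drop subjects lacking one of the two conditions
  tab <- table(subject, condition)
  ok <- rownames(tab)[rowSums(tab > 0) == 2 & rowSums(tab) == 2]
  bad <- setdiff(unique(subject), ok)
  n_removed <- sum(!subject %in% ok)
  if (length(bad)) {
    warning("dropping ", length(bad),
            " subject(s) without both conditions (or with replicates): ",
            paste(bad, collapse = ", "))
    keep <- subject %in% ok
    counts <- counts[, keep, drop = FALSE]
    condition <- condition[keep]
    subject <- subject[keep]
  }
  if (ncol(counts) < 2) stop("need at least 2 samples after pairing")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0(subject, "_", condition)
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(subject = subject,
                        condition = factor(condition, c("PL", "BR")),
                        row.names = colnames(counts)),
    rowData = DataFrame(taxonomy = taxonomy, row.names = rownames(counts))
  )
  obj <- new("OtuExperiment", se)
  metadata(obj)$n_removed_samples <- n_removed
  validObject(obj)
  obj
}

setValidity("OtuExperiment", function(object) {
  if (!"counts" %in% assayNames(object)) return("missing 'counts' assay")
  cnt <- assay(object, "counts")
  if (any(cnt < 0)) return("counts must be non-negative")
  if (anyDuplicated(rownames(object))) return("OTU ids must be unique")
  if (ncol(object) < 2) return("need at least 2 sample columns")
  if (!all(c("subject", "condition") %in% colnames(colData(object))))
    return("colData must contain 'subject' and 'condition'")
  tab <- table(object$subject, object$condition)
  if (!all(tab == 1))
    return("every subject must appear exactly once per condition")
  TRUE
})

#' @describeIn OtuExperiment the integer count matrix.
#' @param x,object an `OtuExperiment`.
#' @export
otuCounts <- function(x) assay(x, "counts")

#' @describeIn OtuExperiment per-sample subject identifiers.
#' @export
sampleSubject <- function(x) x$subject

#' @describeIn OtuExperiment per-sample condition factor (PL/BR).
#' @export
sampleCondition <- function(x) x$condition

#' @describeIn OtuExperiment per-OTU taxonomy strings.
#' @export
otuTaxonomy <- function(x) rowData(x)$taxonomy

#' @describeIn OtuExperiment the filter report, or NULL if unfiltered.
#' @export
filterReport <- function(x) x@filterReport

#' @describeIn OtuExperiment compact display.
#' @export
setMethod("show", "OtuExperiment", function(object) {
  cat(sprintf("OtuExperiment: %d OTUs x %d samples (%d paired subjects)\n",
              nrow(object), ncol(object),
              length(unique(object$subject))))
  callNextMethod()
  if (!is.null(object@filterReport)) show(object@filterReport)
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf(paste0(
    "FilterReport: %d input OTUs; %d removed by rule 1 (<min everywhere),",
    " %d by rule 2 (low prevalence); %d retained; %d sample(s) dropped\n"),
    object@nInput, object@nRemovedRule1, object@nRemovedRule2,
    length(object@survivingIds), object@nRemovedSamples))
})

setMethod("show", "TraitTable", function(object) {
  cat(sprintf(
    "TraitTable: %d subjects x %d per-condition traits, %d baseline-only\n",
    nrow(object@pl), ncol(object@pl), ncol(object@base)))
})

setMethod("show", "CooccurrenceNetwork", function(object) {
  cat(sprintf(
    "CooccurrenceNetwork [%s]: %d OTUs, soft power beta = %d\n",
    object@condition, nrow(object@tom), object@beta))
})

setMethod("show", "ModuleSet", function(object) {
  sz <- moduleSizes(object)
  cat(sprintf("ModuleSet: %d modules over %d OTUs (%d unassigned)\n",
              sum(names(sz) != "0"), length(object@labels),
              sum(object@labels == 0L)))
  print(sz)
})

setMethod("show", "ModuleTraitNetwork", function(object) {
  cat(sprintf("ModuleTraitNetwork [%s]: %d modules x %d traits\n",
              object@condition, nrow(object@r), ncol(object@r)))
})

setMethod("show", "LefseResult", function(object) {
  cat(sprintf(
    "LefseResult: %d OTUs screened, %d pass |LDA| >= %.3g at alpha = %.3g\n",
    nrow(object@table), sum(object@table$passes, na.rm = TRUE),
    object@threshold, object@alpha))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset (seed ", object@truth@seed, ")\n", sep = "")
  show(object@otus)
  show(object@traits)
})

#' Module labels and sizes
#'
#' `moduleLabels()` returns the named per-OTU integer label vector
#' (0 = unassigned); `moduleSizes()` tabulates it; `moduleEigengenes()`
#' returns the sample x module eigengene matrix for one condition;
#' `moduleMembership()` the corresponding kME matrix.
#'
#' @param x a [ModuleSet-class].
#' @param condition condition whose eigengenes/kME to return.
#' @return see description.
#' @export
moduleLabels <- function(x) x@labels

#' @rdname moduleLabels
#' @export
moduleSizes <- function(x) table(factor(x@labels))

#' @rdname moduleLabels
#' @export
moduleEigengenes <- function(x, condition = "PL") {
  if (!condition %in% names(x@eigengenes))
    stop("no eigengenes for condition '", condition, "'")
  x@eigengenes[[condition]]
}

#' @rdname moduleLabels
#' @export
moduleMembership <- function(x, condition = "PL") {
  if (!condition %in% names(x@kme))
    stop("no kME for condition '", condition, "'")
  x@kme[[condition]]
}

#' Trait table accessors
#'
#' @param x a [TraitTable-class].
#' @param condition `"PL"`, `"BR"` or `"BASE"` (baseline-only traits).
#' @return numeric subject x trait matrix.
#' @export
traitValues <- function(x, condition = c("PL", "BR", "BASE")) {
  condition <- match.arg(condition)
  switch(condition, PL = x@pl, BR = x@br, BASE = x@base)
}

#' @rdname traitValues
#' @export
traitSubjects <- function(x) rownames(x@pl)

#' Construct a TraitTable
#'
#' @param pl,br numeric subject x trait matrices (shared dimnames) of
#'   per-condition trait measurements.
#' @param base optional subject x trait matrix of baseline-only traits.
#' @param units optional named character vector of units.
#' @return a [TraitTable-class].
#' @export
TraitTable <- function(pl, br, base = NULL, units = character()) {
  pl <- as.matrix(pl); br <- as.matrix(br)
  if (is.null(base))
    base <- matrix(numeric(0), nrow(pl), 0, dimnames = list(rownames(pl)))
  new("TraitTable", pl = pl, br = br, base = as.matrix(base), units = units)
}
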