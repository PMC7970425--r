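#' Read and write OTU count tables
#'
#' The TSV layout has `otu_id` as first column, one column per sample
#' named `<subject>_<condition>` (e.g. `S07_PL`), and a final
#' `taxonomy` column of semicolon-delimited ranks. BIOM (JSON flavour)
#' tables are accepted read-only; sample ids must follow the same
#' `<subject>_<condition>` convention.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"` (JSON BIOM, requires the
#'   `biomformat` package).
#' @return `readOtuTable()` returns an [OtuExperiment-class];
#'   `writeOtuTable()` returns `path` invisibly.
#' @export
readOtuTable <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    counts <- as.matrix(biomformat::biom_data(b))
    tax <- tryCatch({
      om <- biomformat::observation_metadata(b)
      if (is.data.frame(om)) apply(om, 1, paste, collapse = ";")
      else vapply(om, paste, "", collapse = ";")
    }, error = function(e) rep(NA_character_, nrow(counts)))
    meta <- .parse_sample_ids(colnames(counts))
    return(OtuExperiment(counts, meta$subject, meta$condition, tax))
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "otu_id")
    stop("format error: first column must be 'otu_id'")
  has_tax <- names(df)[ncol(df)] == "taxonomy"
  tax <- if (has_tax) df$taxonomy else rep(NA_character_, nrow(df))
  smp_cols <- setdiff(names(df), c("otu_id", "taxonomy"))
  counts <- as.matrix(df[, smp_cols, drop = FALSE])
  if (any(is.na(counts)) || any(counts != round(counts)) || any(counts < 0))
    stop("format error: counts must be non-negative integers")
  rownames(counts) <- df$otu_id
  if (anyDuplicated(df$otu_id))
    stop("format error: duplicate OTU id in ", path)
  meta <- .parse_sample_ids(smp_cols)
  OtuExperiment(counts, meta$subject, meta$condition, tax)
}

.parse_sample_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)_(PL|BR)$", ids))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad))
    stop("sample id(s) not of the form <subject>_<PL|BR>: ",
         paste(ids[bad], collapse = ", "))
  list(subject = vapply(m, `[`, "", 2L),
       condition = vapply(m, `[`, "", 3L))
}

#' @rdname readOtuTable
#' @param x an [OtuExperiment-class].
#' @export
writeOtuTable <- function(x, path) {
  df <- data.frame(otu_id = rownames(x), otuCounts(x),
                   taxonomy = otuTaxonomy(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write trait tables
#'
#' TSV with first column `subject_id` and one column per trait named
#' `trait@PL`, `trait@BR` or `trait@BASE` (baseline-only traits such as
#' ACE-III subscores). Missing values are `NA`.
#'
#' @param path file path.
#' @return `readTraitTable()` returns a [TraitTable-class].
#' @export
readTraitTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "subject_id")
    stop("format error: first column must be 'subject_id'")
  subj <- as.character(df$subject_id)
  cols <- names(df)[-1]
  m <- regmatches(cols, regexec("^(.*)@(PL|BR|BASE)$", cols))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad))
    stop("trait column(s) not of the form trait@{PL,BR,BASE}: ",
         paste(cols[bad], collapse = ", "))
  trait <- vapply(m, `[`, "", 2L)
  scope <- vapply(m, `[`, "", 3L)
  pick <- function(sc) {
    sel <- which(scope == sc)
    out <- as.matrix(df[, 1 + sel, drop = FALSE])
    dimnames(out) <- list(subj, trait[sel])
    storage.mode(out) <- "double"
    out
  }
  pl <- pick("PL"); br <- pick("BR")
  if (!identical(colnames(pl), colnames(br)))
    stop("each per-condition trait needs both a @PL and a @BR column")
  TraitTable(pl, br, base = pick("BASE"))
}

#' @rdname readTraitTable
#' @param x a [TraitTable-class].
#' @export
writeTraitTable <- function(x, path) {
  pl <- traitValues(x, "PL"); br <- traitValues(x, "BR")
  base <- traitValues(x, "BASE")
  df <- data.frame(subject_id = rownames(pl), check.names = FALSE)
  for (tr in colnames(pl)) {
    df[[paste0(tr, "@PL")]] <- pl[, tr]
    df[[paste0(tr, "@BR")]] <- br[, tr]
  }
  for (tr in colnames(base)) df[[paste0(tr, "@BASE")]] <- base[, tr]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
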