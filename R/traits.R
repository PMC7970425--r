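#' Correlate module eigengenes with host traits
#'
#' Pearson correlation (and two-sided Student p-value) between each
#' module eigengene and each trait, using pairwise-complete subjects.
#' When `condition = "PL"` the baseline-only traits (e.g. ACE-III
#' subscores measured once, before the intervention) are appended to
#' the per-condition traits, so baseline cognition is analysed within
#' the placebo network.
#'
#' @param eg sample x module eigengene matrix for one condition.
#' @param traits a [TraitTable-class].
#' @param condition `"PL"` or `"BR"`; selects the trait columns and
#'   controls inclusion of baseline-only traits.
#' @param subjects subject id per eigengene row (default: rownames of
#'   `eg`); must match `traitSubjects(traits)`.
#' @param include_baseline whether baseline traits join the PL network
#'   (default TRUE).
#' @return a [ModuleTraitNetwork-class]. Cells with fewer than 4
#'   complete pairs are `NA` with a warning.
#' @export
eigengeneTraitCorrelation <- function(eg, traits,
                                      condition = c("PL", "BR"),
                                      subjects = rownames(eg),
                                      include_baseline = TRUE) {
  condition <- match.arg(condition)
  tv <- traitValues(traits, condition)
  if (condition == "PL" && include_baseline &&
      ncol(traitValues(traits, "BASE")) > 0)
    tv <- cbind(tv, traitValues(traits, "BASE"))
  if (is.null(subjects)) stop("need subject ids for eigengene rows")
  miss <- setdiff(subjects, rownames(tv))
  if (length(miss))
    stop("subjects absent from trait table: ", paste(miss, collapse = ", "))
  tv <- tv[subjects, , drop = FALSE]
  nm <- colnames(eg); nt <- colnames(tv)
  r <- p <- n <- matrix(NA_real_, length(nm), length(nt),
                        dimnames = list(nm, nt))
  low <- character(0)
  for (i in seq_along(nm)) for (j in seq_along(nt)) {
    ok <- complete.cases(eg[, i], tv[, j])
    n[i, j] <- sum(ok)
    if (sum(ok) < 4) { low <- c(low, nt[j]); next }
    ct <- corTest(eg[ok, i], tv[ok, j])
    r[i, j] <- ct$r; p[i, j] <- ct$p
  }
  if (length(low))
    warning("cells with <4 complete pairs set to NA (traits: ",
            paste(unique(low), collapse = ", "), ")")
  new("ModuleTraitNetwork", r = r, p = p, n = n, condition = condition)
}

#' Pearson correlation with Student p-value
#'
#' @param x,y numeric vectors (no NA).
#' @return list with `r` and two-sided `p` on n-2 df.
#' @keywords internal
corTest <- function(x, y) {
  n <- length(x)
  r <- cor(x, y)
  if (is.na(r)) return(list(r = NA_real_, p = NA_real_))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(list(r = r, p = 0))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

#' Consensus module-trait correlation network
#'
#' Reduces two per-condition networks to the relationships stable
#' across both dietary conditions: where the signs agree, the
#' consensus correlation is the sign times the smaller magnitude and
#' the consensus p-value the larger (less significant) of the two;
#' where the signs disagree the cell is non-concordant (r = 0, p = 1).
#' Only modules and traits present in both networks are retained, so
#' baseline-only traits drop out of the consensus.
#'
#' @param net_pl,net_br [ModuleTraitNetwork-class] objects for the two
#'   conditions.
#' @return a consensus [ModuleTraitNetwork-class]; its `n` matrix is
#'   the per-cell minimum of the two pair counts.
#' @export
consensusCorrelation <- function(net_pl, net_br) {
  mods <- intersect(rownames(net_pl@r), rownames(net_br@r))
  trs <- intersect(colnames(net_pl@r), colnames(net_br@r))
  if (!length(mods) || !length(trs))
    stop("networks share no modules/traits")
  r1 <- net_pl@r[mods, trs, drop = FALSE]
  r2 <- net_br@r[mods, trs, drop = FALSE]
  p1 <- net_pl@p[mods, trs, drop = FALSE]
  p2 <- net_br@p[mods, trs, drop = FALSE]
  concord <- sign(r1) == sign(r2)
  r <- ifelse(concord, sign(r1) * pmin(abs(r1), abs(r2)), 0)
  p <- ifelse(concord, pmax(p1, p2), 1)
  r[is.na(r1) | is.na(r2)] <- NA
  p[is.na(p1) | is.na(p2)] <- NA
  n <- pmin(net_pl@n[mods, trs, drop = FALSE],
            net_br@n[mods, trs, drop = FALSE])
  new("ModuleTraitNetwork", r = r, p = p, n = n, condition = "consensus")
}

#' Significant module-trait cells
#'
#' Cells of a module-trait network with p <= alpha, ordered by
#' decreasing correlation magnitude. Raw (unadjusted) p-values are
#' screened by default, matching the reporting convention of the
#' analysis this package implements; set `adjust = "BH"` for a false
#' discovery rate screen instead.
#'
#' @param net a [ModuleTraitNetwork-class].
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with columns `module`, `trait`, `r`, `p`, `n`.
#' @export
significantCells <- function(net, alpha = 0.05,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p <- net@p
  if (adjust == "BH") {
    ok <- !is.na(p)
    p[ok] <- bhAdjust(p[ok])
  }
  hit <- which(!is.na(p) & p <= alpha, arr.ind = TRUE)
  out <- data.frame(
    module = rownames(net@r)[hit[, 1]],
    trait = colnames(net@r)[hit[, 2]],
    r = net@r[hit], p = p[hit], n = net@n[hit])
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Long-format export of a module-trait network
#'
#' @param net a [ModuleTraitNetwork-class].
#' @return data.frame `module`, `trait`, `r`, `p`, `n` for all cells
#'   (heatmap-ready).
#' @export
moduleTraitLong <- function(net) {
  data.frame(
    module = rep(rownames(net@r), times = ncol(net@r)),
    trait = rep(colnames(net@r), each = nrow(net@r)),
    r = as.vector(net@r), p = as.vector(net@p), n = as.vector(net@n))
}
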