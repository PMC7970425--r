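#' Kruskal-Wallis screening p-value
#'
#' Rank-based H test (with tie correction, chi-square p) comparing a
#' feature across classes; the first stage of the effect-size screen.
#' A constant feature has no rank signal and returns p = 1.
#'
#' @param values numeric vector.
#' @param classes class labels (>= 2 classes, each >= 2 observations).
#' @return the p-value.
#' @export
kruskalWallisP <- function(values, classes) {
  classes <- factor(classes)
  if (nlevels(classes) < 2) stop("need at least 2 classes")
  if (any(table(classes) < 2)) stop("each class needs >= 2 observations")
  if (length(unique(values)) == 1) return(1)
  kruskal.test(values, classes)$p.value
}

#' Bootstrapped LDA effect size
#'
#' For each of `n_boot` subsamples (fraction `subsample_frac`, both
#' classes required, bounded retries), a linear discriminant between
#' the two classes is fitted on the feature block with a
#' diagonally-loaded within-class covariance. Each feature's per-run
#' effect is the average of (i) its share of the class-mean separation
#' along the unit discriminant axis and (ii) its raw class-mean
#' difference; the final effect is the mean over runs, reported as
#' `log10` of the effect magnitude (floored at 0) and signed by the
#' enriched class: positive when the second class level has the larger
#' mean (character input is levelled in order of first appearance, so
#' PL-then-BR data give positive scores to nitrate-enriched
#' features). Features
#' are expected on the per-million relative abundance scale, which
#' puts meaningful effects on the familiar 2-6 log10 range.
#' Deterministic for a fixed seed.
#'
#' @param x numeric sample x feature matrix (per-million scale).
#' @param classes two-class factor (`PL`/`BR`), one label per row.
#' @param n_boot number of bootstrap subsamples (default 30).
#' @param subsample_frac fraction of samples per subsample (default
#'   2/3).
#' @param seed integer RNG seed.
#' @return data.frame with `feature`, `lda_effect` (signed log10),
#'   `enriched_class`.
#' @export
ldaEffectSize <- function(x, classes, n_boot = 30, subsample_frac = 2/3,
                          seed = 1) {
  x <- as.matrix(x)
  classes <- if (is.factor(classes)) droplevels(classes)
             else factor(classes, levels = unique(classes))
  if (nlevels(classes) != 2) stop("exactly 2 classes required")
  lev <- levels(classes)
  n <- nrow(x)
  m <- max(2L, floor(subsample_frac * n))
  eff <- matrix(0, n_boot, ncol(x))
  withSeed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- NULL
      for (try in 1:100) {
        cand <- sample.int(n, m)
        if (nlevels(droplevels(classes[cand])) == 2 &&
            min(table(classes[cand])) >= 2) { idx <- cand; break }
      }
      if (is.null(idx))
        stop("could not draw a subsample containing both classes")
      eff[b, ] <- .lda_run(x[idx, , drop = FALSE], classes[idx], lev)
    }
  })
  effect <- colMeans(eff)
  mu1 <- colMeans(x[classes == lev[1], , drop = FALSE])
  mu2 <- colMeans(x[classes == lev[2], , drop = FALSE])
  enriched <- ifelse(mu2 >= mu1, lev[2], lev[1])
  signed <- ifelse(enriched == lev[2], 1, -1) * log10(pmax(effect, 1))
  data.frame(feature = colnames(x) %||% seq_len(ncol(x)),
             lda_effect = signed, enriched_class = enriched,
             row.names = NULL)
}

# one discriminant fit; returns per-feature absolute effect
.lda_run <- function(x, cl, lev) {
  m1 <- colMeans(x[cl == lev[1], , drop = FALSE])
  m2 <- colMeans(x[cl == lev[2], , drop = FALSE])
  xc <- x
  xc[cl == lev[1], ] <- sweep(x[cl == lev[1], , drop = FALSE], 2, m1)
  xc[cl == lev[2], ] <- sweep(x[cl == lev[2], , drop = FALSE], 2, m2)
  sw <- crossprod(xc) / max(1, nrow(x) - 2)
  load <- 0.01 * mean(diag(sw)) + 1e-10
  w <- solve(sw + diag(load, ncol(x)), m2 - m1)
  wn <- sqrt(sum(w^2))
  if (wn == 0) return(rep(0, ncol(x)))
  w <- w / wn
  proj_sep <- abs(sum(w * (m2 - m1)))
  (abs(w) * proj_sep + abs(m2 - m1)) / 2
}

#' Per-module biomarker screen (Kruskal-Wallis + LDA effect size)
#'
#' Runs, within each co-occurrence module, the two-stage biomarker
#' screen comparing the placebo and nitrate conditions: features
#' failing the Kruskal-Wallis test at `alpha` are dropped; survivors
#' receive a bootstrapped LDA effect size. Abundances are rescaled to
#' per-million before the discriminant fit.
#'
#' @param x an [OtuExperiment-class] (relative abundances are computed
#'   internally).
#' @param labels named per-OTU module labels (0 = unassigned,
#'   screened as its own "M0" group).
#' @param alpha Kruskal-Wallis significance level (default 0.05).
#' @param threshold absolute log10 LDA effect required to pass
#'   (default 2).
#' @param n_boot,subsample_frac,seed see [ldaEffectSize()].
#' @return a [LefseResult-class].
#' @export
lefseModules <- function(x, labels, alpha = 0.05, threshold = 2,
                         n_boot = 30, subsample_frac = 2/3, seed = 1) {
  relab <- relativeAbundance(x) * 1e6
  classes <- sampleCondition(x)
  labels <- labels[rownames(relab)]
  rows <- list()
  for (mod in sort(unique(labels))) {
    members <- names(labels)[labels == mod]
    sub <- t(relab[members, , drop = FALSE])
    kw <- vapply(members, function(f) kruskalWallisP(sub[, f], classes), 0)
    keep <- members[kw <= alpha]
    res <- data.frame(module = paste0("MM", mod), otu_id = members,
                      kw_p = unname(kw), lda_effect = NA_real_,
                      enriched_class = NA_character_, passes = FALSE)
    if (length(keep)) {
      le <- ldaEffectSize(sub[, keep, drop = FALSE], classes,
                          n_boot = n_boot,
                          subsample_frac = subsample_frac,
                          seed = seed + mod)
      i <- match(keep, res$otu_id)
      res$lda_effect[i] <- le$lda_effect
      res$enriched_class[i] <- le$enriched_class
      res$passes[i] <- abs(le$lda_effect) >= threshold
    }
    rows[[as.character(mod)]] <- res
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("LefseResult", table = tab, threshold = threshold, alpha = alpha)
}

#' Module-driver OTUs
#'
#' Per module, the OTUs whose absolute log10 LDA effect meets the
#' threshold, ranked by decreasing effect magnitude; modules with no
#' qualifying OTU return an empty entry.
#'
#' @param lefse a [LefseResult-class].
#' @param threshold log10 effect threshold (default: the one stored in
#'   `lefse`).
#' @return named list (one element per module) of data.frames with
#'   `otu_id`, `lda_effect`, `enriched_class`, `kw_p`.
#' @export
moduleDrivers <- function(lefse, threshold = NULL) {
  if (is.null(threshold)) threshold <- lefse@threshold
  tb <- lefse@table
  out <- lapply(split(tb, tb$module), function(df) {
    hit <- df[!is.na(df$lda_effect) & abs(df$lda_effect) >= threshold &
                df$kw_p <= lefse@alpha, ]
    hit <- hit[order(-abs(hit$lda_effect)), ]
    hit[, c("otu_id", "lda_effect", "enriched_class", "kw_p")]
  })
  out[order(names(out))]
}
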