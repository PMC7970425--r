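#' Signed weighted adjacency
#'
#' Maps pairwise correlation to edge weights as
#' `a_ij = ((1 + cor_ij) / 2) ^ beta`, so perfectly anti-correlated
#' OTUs get weight 0 and only positive co-occurrence builds modules.
#' The diagonal is set to 1 by convention and excluded from
#' connectivity sums.
#'
#' @param x numeric sample x OTU matrix (observations in rows), e.g.
#'   from [transformForNetwork()].
#' @param beta integer soft-threshold power >= 1.
#' @param method correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @return symmetric OTU x OTU adjacency matrix in \[0, 1\];
#'   zero-variance OTUs have their correlations set to 0 and are
#'   listed in the `"zero_variance"` attribute.
#' @export
signedAdjacency <- function(x, beta, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(x) < 3) stop("need at least 3 samples")
  if (beta < 1) stop("beta must be >= 1")
  zv <- apply(x, 2, function(v) var(v) == 0)
  cc <- suppressWarnings(cor(x, method = method))
  cc[is.na(cc)] <- 0
  a <- ((1 + cc) / 2)^beta
  diag(a) <- 1
  attr(a, "zero_variance") <- colnames(x)[zv]
  a
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins `log10 k` into `n_bins` equal-width bins, regresses
#' `log10 p(k)` on the bin mean `log10 k`, and returns the signed fit
#' index `-sign(slope) * R^2` (near 1 for an approximately scale-free
#' degree distribution, near 0 or negative otherwise).
#'
#' @param k non-negative connectivity vector.
#' @param n_bins number of bins (default 10).
#' @return list with `r2_signed`, `slope`, `n_bins_used`;
#'   `r2_signed = NA` when fewer than 3 non-empty bins exist.
#' @export
scaleFreeFitIndex <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 3)
    return(list(r2_signed = NA_real_, slope = NA_real_, n_bins_used = 0L))
  lk <- log10(k)
  breaks <- seq(min(lk), max(lk), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9
  bin <- cut(lk, breaks)
  freq <- tapply(lk, bin, length)
  mids <- tapply(lk, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3)
    return(list(r2_signed = NA_real_, slope = NA_real_,
                n_bins_used = sum(keep)))
  y <- log10(freq[keep] / sum(freq[keep]))
  fit <- lm(y ~ mids[keep])
  slope <- coef(fit)[2]
  r2 <- summary(fit)$r.squared
  list(r2_signed = unname(-sign(slope) * r2), slope = unname(slope),
       n_bins_used = sum(keep))
}

#' Pick the soft-threshold power for a consensus network
#'
#' For each candidate power, builds the signed adjacency in each
#' condition, computes whole-network connectivity
#' `k_i = sum_{j != i} a_ij`, and evaluates the scale-free fit index.
#' Returns the smallest power whose signed R^2 reaches `r2_target` in
#' *both* conditions. When no candidate power qualifies - common for
#' strongly block-structured data whose degree distribution is not
#' scale-free - the selection falls back, with a warning, to the
#' established sample-size-based default for signed networks (18 for
#' fewer than 21 samples, 16 up to 30, 14 up to 40, 12 otherwise),
#' clamped to the nearest candidate power.
#'
#' @param x_pl,x_br sample x OTU matrices, one per condition.
#' @param powers candidate integer powers (default 1:20).
#' @param r2_target minimum signed scale-free R^2 (default 0.8).
#' @param method correlation method (see [signedAdjacency()]).
#' @param n_bins connectivity histogram bins for the fit.
#' @return list with `beta` (chosen power) and `fits` (data.frame:
#'   `power`, `r2_PL`, `r2_BR`, `mean_k_PL`, `mean_k_BR`).
#' @export
pickSoftThreshold <- function(x_pl, x_br, powers = 1:20, r2_target = 0.8,
                              method = "pearson", n_bins = 10) {
  if (!length(powers)) stop("powers must be non-empty")
  powers <- sort(unique(as.integer(powers)))
  base <- lapply(list(PL = x_pl, BR = x_br), function(x) {
    a1 <- signedAdjacency(x, beta = 1, method = method)
    diag(a1) <- 0
    a1
  })
  fits <- do.call(rbind, lapply(powers, function(b) {
    row <- list(power = b)
    for (cd in c("PL", "BR")) {
      k <- rowSums(base[[cd]]^b)
      sf <- scaleFreeFitIndex(k, n_bins)
      row[[paste0("r2_", cd)]] <- sf$r2_signed
      row[[paste0("mean_k_", cd)]] <- mean(k)
    }
    as.data.frame(row)
  }))
  min_r2 <- pmin(fits$r2_PL, fits$r2_BR)
  pass <- which(!is.na(min_r2) & min_r2 >= r2_target)
  if (length(pass)) beta <- fits$power[pass[1]]
  else {
    n <- min(nrow(x_pl), nrow(x_br))
    want <- if (n <= 20) 18L else if (n <= 30) 16L else if (n <= 40) 14L
            else 12L
    beta <- powers[which.min(abs(powers - want))]
    warning("no power reached scale-free R^2 >= ", r2_target,
            " in both conditions; falling back to the signed-network",
            " default for ", n, " samples: beta = ", beta)
  }
  list(beta = as.integer(beta), fits = fits)
}

#' Topological overlap matrix
#'
#' Smooths an adjacency by shared-neighbour structure:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' `TOM_ii = 1`. Two OTUs score high when they are strongly connected
#' *and* share neighbours, which suppresses spurious isolated
#' associations.
#'
#' @param a symmetric adjacency matrix with entries in \[0, 1\].
#' @return symmetric TOM in \[0, 1\] with unit diagonal.
#' @export
tomSimilarity <- function(a) {
  a <- as.matrix(a)
  if (max(abs(a - t(a))) > 1e-10) stop("adjacency must be symmetric")
  if (min(a) < 0 || max(a) > 1 + 1e-12)
    stop("adjacency entries must lie in [0, 1]")
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  l <- a0 %*% a0                       # l_ij = sum_u a_iu a_uj, u != i,j
  kmin <- outer(k, k, pmin)
  tom <- (l + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Reference triple-loop TOM (oracle)
#'
#' Literal O(n^3) evaluation of the topological overlap definition,
#' kept as an independent cross-check for [tomSimilarity()].
#'
#' @param a symmetric adjacency matrix.
#' @keywords internal
#' @export
tomSimilarityNaive <- function(a) {
  n <- nrow(a)
  a0 <- a; diag(a0) <- 0
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a0[i, u] * a0[u, j]
    ki <- sum(a0[i, -i]); kj <- sum(a0[j, -j])
    tom[i, j] <- (l + a0[i, j]) / (min(ki, kj) + 1 - a0[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

#' Consensus topological overlap across conditions
#'
#' Rescales the BR TOM so that its `scale_quantile` off-diagonal
#' quantile matches the PL one (a power transform, preserving \[0,1\]),
#' then takes the element-wise minimum. A relationship therefore only
#' survives in the consensus as strongly as it is present in the
#' *weaker* condition.
#'
#' @param tom_pl,tom_br TOM matrices of identical shape.
#' @param scale_quantile quantile used for cross-condition calibration
#'   (default 0.95).
#' @return consensus TOM matrix.
#' @export
consensusTom <- function(tom_pl, tom_br, scale_quantile = 0.95) {
  if (!identical(dim(tom_pl), dim(tom_br)))
    stop("TOM matrices must have identical shape")
  off <- upper.tri(tom_pl)
  q_pl <- quantile(tom_pl[off], scale_quantile, names = FALSE)
  q_br <- quantile(tom_br[off], scale_quantile, names = FALSE)
  br <- tom_br
  if (q_pl > 0 && q_br > 0 && q_pl < 1 && q_br < 1) {
    br <- tom_br^(log(q_pl) / log(q_br))
    diag(br) <- 1
  }
  cons <- pmin(tom_pl, br)
  dimnames(cons) <- dimnames(tom_pl)
  cons
}

.deep_split_qlo <- c(`0` = 0.90, `1` = 0.80, `2` = 0.60, `3` = 0.40,
                     `4` = 0.20)

# score a candidate cut: primarily the number of clusters surviving the
# size + cohesion validation, then the number of OTUs they cover
.cut_score <- function(raw, tom, min_size, cohesion_min) {
  lab <- .validate_clusters(raw, tom, min_size, cohesion_min)
  max(lab) + sum(lab > 0) / (length(lab) + 1)
}

#' Detect co-occurrence modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - TOM`, followed by an adaptive tree cut: candidate cut heights
#' spanning the merge-height distribution (the depth of the grid
#' controlled by `deep_split`, 0-4; deeper splits consider lower cuts
#' and hence finer clusters) are scored by the mean silhouette width
#' of the resulting clusters, and the best cut is kept. Clusters below
#' `min_module_size` are unassigned, and a cohesion validation
#' dissolves candidate clusters whose mean within-cluster topological
#' overlap does not exceed `cohesion_min` times the network background
#' - this is what sends clusters of a structureless (noise) network to
#' the unassigned module. When expression data are supplied, a kME
#' rescue pass then reassigns each OTU to the module whose eigengene
#' it correlates with at `kme_rescue` or better (minimum across
#' conditions), and modules whose eigengenes correlate above
#' `1 - merge_height` in every condition are merged iteratively.
#' Modules are relabelled 1, 2, ... by decreasing size; label 0 is the
#' unassigned ("grey") module.
#'
#' @param tom topological overlap matrix.
#' @param x named list of sample x OTU matrices (one per condition,
#'   e.g. `list(PL = ..., BR = ...)`) used for eigengenes, kME rescue
#'   and merging. With `NULL`, no rescue or merging is performed and
#'   no eigengenes are attached.
#' @param min_module_size smallest allowed module (default 20,
#'   must be >= 3).
#' @param deep_split split sensitivity 0-4 (default 2).
#' @param merge_height eigengene dissimilarity below which modules are
#'   merged (default 0.25, i.e. correlation > 0.75); `NULL` or `0`
#'   disables merging.
#' @param cohesion_min minimum ratio of within-module to background
#'   mean TOM (default 1.5).
#' @param kme_rescue minimum (across conditions) eigengene correlation
#'   at which an OTU is (re)assigned to its best-matching module
#'   (default 0.45); `NULL` disables the rescue pass.
#' @param cut_height optional explicit cut height overriding the
#'   adaptive selection.
#' @return a [ModuleSet-class].
#' @export
detectModules <- function(tom, x = NULL, min_module_size = 20,
                          deep_split = 2, merge_height = 0.25,
                          cohesion_min = 1.5, kme_rescue = 0.45,
                          cut_height = NULL) {
  if (min_module_size < 3) stop("min_module_size must be >= 3")
  n <- nrow(tom)
  dis <- 1 - tom
  hc <- hclust(as.dist(dis), method = "average")
  if (is.null(cut_height)) {
    qlo <- .deep_split_qlo[as.character(deep_split)]
    if (is.na(qlo)) stop("deep_split must be one of 0:4")
    grid <- unique(quantile(hc$height, seq(qlo, 1, length.out = 30),
                            names = FALSE) - 1e-10)
    scores <- vapply(grid, function(h)
      .cut_score(cutree(hc, h = h), tom, min_module_size, cohesion_min),
      0)
    cut_height <- grid[which.max(scores)]
  }
  raw <- cutree(hc, h = cut_height)
  labels <- .validate_clusters(raw, tom, min_module_size, cohesion_min)
  names(labels) <- rownames(tom)

  if (!is.null(x) && !is.null(kme_rescue) && any(labels > 0)) {
    labels <- .kme_rescue(labels, x, kme_rescue)
    labels <- .validate_clusters(labels, tom, min_module_size,
                                 cohesion_min)
    names(labels) <- rownames(tom)
  }
  if (!is.null(x) && !is.null(merge_height) && merge_height > 0)
    labels <- .merge_modules(labels, x, merge_height)
  labels <- .relabel_by_size(labels)

  eg <- list(); kme <- list()
  if (!is.null(x) && any(labels > 0)) {
    eg <- lapply(x, function(xx) moduleEigengene(xx, labels))
    kme <- lapply(x, function(xx) kmeMatrix(xx, moduleEigengene(xx, labels)))
  }
  new("ModuleSet", labels = labels, dendro = hc, eigengenes = eg,
      kme = kme, minModuleSize = as.integer(min_module_size))
}

# keep clusters of raw that meet the size and cohesion requirements
.validate_clusters <- function(raw, tom, min_size, cohesion_min) {
  out <- integer(length(raw))
  off_mean <- mean(tom[upper.tri(tom)])
  nxt <- 0L
  for (cl in sort(unique(raw[raw > 0]))) {
    idx <- which(raw == cl)
    if (length(idx) < min_size) next
    sub <- tom[idx, idx]
    within <- mean(sub[upper.tri(sub)])
    if (off_mean > 0 && within / off_mean < cohesion_min) next
    nxt <- nxt + 1L
    out[idx] <- nxt
  }
  out
}

# pull unassigned OTUs into the module whose eigengene they match at
# the threshold (minimum across conditions), and drop assigned OTUs
# whose membership in their own module has fallen below threshold / 2
.kme_rescue <- function(labels, x, threshold) {
  min_kme <- NULL
  for (xx in x) {
    km <- kmeMatrix(xx, moduleEigengene(xx, labels))
    min_kme <- if (is.null(min_kme)) km else pmin(min_kme, km)
  }
  mods <- as.integer(sub("^ME", "", colnames(min_kme)))
  best <- max.col(min_kme, ties.method = "first")
  best_val <- min_kme[cbind(seq_len(nrow(min_kme)), best)]
  out <- labels
  grey <- labels == 0L
  out[grey & best_val >= threshold] <- mods[best[grey & best_val >= threshold]]
  own <- match(paste0("ME", labels), colnames(min_kme))
  own_val <- ifelse(is.na(own), NA_real_,
                    min_kme[cbind(seq_along(labels), own)])
  out[!grey & !is.na(own_val) & own_val < threshold / 2] <- 0L
  names(out) <- names(labels)
  out
}

# iteratively merge the closest module pair whose eigengene correlation
# exceeds 1 - merge_height in every condition
.merge_modules <- function(labels, x, merge_height) {
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) return(labels)
    egs <- lapply(x, function(xx) moduleEigengene(xx, labels))
    min_cor <- NULL
    for (eg in egs) {
      cc <- cor(eg)
      min_cor <- if (is.null(min_cor)) cc else pmin(min_cor, cc)
    }
    diag(min_cor) <- -Inf
    best <- which(min_cor == max(min_cor), arr.ind = TRUE)[1, ]
    if (max(min_cor) < 1 - merge_height) return(labels)
    keep <- mods[min(best)]; drop <- mods[max(best)]
    labels[labels == drop] <- keep
  }
}

.relabel_by_size <- function(labels) {
  mods <- labels[labels > 0]
  if (!length(mods)) return(labels)
  sz <- sort(table(mods), decreasing = TRUE)
  map <- setNames(seq_along(sz), names(sz))
  out <- labels
  out[labels > 0] <- map[as.character(mods)]
  storage.mode(out) <- "integer"
  names(out) <- names(labels)
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' column-standardised profiles of its member OTUs, scaled to unit
#' variance and sign-oriented to correlate positively with the
#' module's mean member profile. A single-member module returns that
#' member's standardised profile, with a warning.
#'
#' @param x sample x OTU matrix.
#' @param labels per-OTU module labels (0 = unassigned, excluded).
#' @return sample x module matrix, columns `ME1`, `ME2`, ...; the
#'   `"var_explained"` attribute gives the share of member variance
#'   captured by each eigengene.
#' @export
moduleEigengene <- function(x, labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no assigned modules")
  out <- matrix(NA_real_, nrow(x), length(mods),
                dimnames = list(rownames(x), paste0("ME", mods)))
  ve <- setNames(numeric(length(mods)), colnames(out))
  for (i in seq_along(mods)) {
    idx <- which(labels == mods[i])
    sub <- scale(x[, idx, drop = FALSE])
    sub[, colSums(is.na(sub)) > 0 | apply(sub, 2, function(v) any(!is.finite(v)))] <- 0
    if (length(idx) == 1) {
      warning("module ", mods[i], " has a single member")
      e <- sub[, 1]
      ve[i] <- 1
    } else {
      sv <- svd(sub, nu = 1, nv = 1)
      e <- sv$u[, 1] * sv$d[1]
      ve[i] <- sv$d[1]^2 / sum(sv$d^2)
    }
    if (sd(e) > 0) e <- e / sd(e)
    m <- rowMeans(sub)
    if (sd(m) > 0 && cor(e, m) < 0) e <- -e
    out[, i] <- e
  }
  attr(out, "var_explained") <- ve
  out
}

#' Module membership (kME)
#'
#' Correlation of each OTU profile with each module eigengene; an
#' OTU's kME for its own module measures its intramodular
#' connectivity (hub-ness).
#'
#' @param x sample x OTU matrix.
#' @param eigengenes sample x module matrix from [moduleEigengene()].
#' @return OTU x module correlation matrix in \[-1, 1\].
#' @export
kmeMatrix <- function(x, eigengenes) {
  cc <- suppressWarnings(cor(x, eigengenes))
  cc[is.na(cc)] <- 0
  cc
}

#' Build per-condition and consensus co-occurrence networks
#'
#' Convenience wrapper running soft-threshold selection, per-condition
#' signed adjacency and TOM, and the consensus TOM.
#'
#' @param x_pl,x_br sample x OTU matrices per condition.
#' @inheritParams pickSoftThreshold
#' @inheritParams consensusTom
#' @param beta optional fixed power; when `NULL` it is chosen by
#'   [pickSoftThreshold()].
#' @return list with `networks` (named list of
#'   [CooccurrenceNetwork-class] for PL, BR and consensus), `beta`,
#'   and `fits` (scale-free fit table, `NULL` when `beta` was fixed).
#' @export
buildConsensusNetwork <- function(x_pl, x_br, powers = 1:20,
                                  r2_target = 0.8, beta = NULL,
                                  method = "pearson",
                                  scale_quantile = 0.95) {
  fits <- NULL
  if (is.null(beta)) {
    sel <- pickSoftThreshold(x_pl, x_br, powers, r2_target, method)
    beta <- sel$beta; fits <- sel$fits
  }
  beta <- as.integer(beta)
  a_pl <- signedAdjacency(x_pl, beta, method)
  a_br <- signedAdjacency(x_br, beta, method)
  t_pl <- tomSimilarity(a_pl)
  t_br <- tomSimilarity(a_br)
  t_cons <- consensusTom(t_pl, t_br, scale_quantile)
  nets <- list(
    PL = new("CooccurrenceNetwork", adjacency = a_pl, tom = t_pl,
             beta = beta, condition = "PL"),
    BR = new("CooccurrenceNetwork", adjacency = a_br, tom = t_br,
             beta = beta, condition = "BR"),
    consensus = new("CooccurrenceNetwork",
                    adjacency = pmin(a_pl, a_br), tom = t_cons,
                    beta = beta, condition = "consensus"))
  list(networks = nets, beta = beta, fits = fits)
}
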