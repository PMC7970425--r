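#' Alpha diversity indices
#'
#' `shannonIndex()` computes the Shannon-Wiener index
#' H' = -sum p_i log p_i over the positive fractions (natural log by
#' default). `chao1()` computes the Chao1 richness estimate
#' S_obs + F1^2 / (2 F2) when doubletons are present, and the
#' bias-corrected S_obs + F1 (F1 - 1) / 2 when F2 = 0 (F1 = number of
#' singletons, F2 = number of doubletons). `otuRichness()` counts
#' strictly positive entries.
#'
#' @param counts non-negative numeric vector of abundances (integer
#'   counts for `chao1`).
#' @param base logarithm base for Shannon (default `exp(1)`).
#' @return a single number.
#' @examples
#' shannonIndex(c(5, 5, 5, 5))  # log(4)
#' chao1(c(rep(1, 4), rep(2, 2), rep(5, 10)))
#' @export
shannonIndex <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all-zero abundance vector")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' @rdname shannonIndex
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / 2
}

#' @rdname shannonIndex
#' @export
otuRichness <- function(counts) sum(counts > 0)

#' Bray-Curtis dissimilarity
#'
#' `brayCurtis()` computes sum |x - y| / sum (x + y) for one pair;
#' `brayCurtisMatrix()` the full sample x sample dissimilarity matrix
#' of an abundance table (samples in columns).
#'
#' @param x,y non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return a number in \[0, 1\], 0 iff `x == y`, 1 for disjoint
#'   supports.
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x + y)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / tot
}

#' @rdname brayCurtis
#' @param mat OTU x sample abundance matrix.
#' @export
brayCurtisMatrix <- function(mat) {
  as.matrix(vegan::vegdist(t(mat), method = "bray"))
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS on a dissimilarity matrix (monotone regression
#' over ranked dissimilarities), taking the best of `n_starts` random
#' starts. Deterministic for a fixed seed. The engine is
#' `vegan::metaMDS` with `monoMDS`.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @param k target dimensionality (default 2).
#' @param n_starts number of random starts.
#' @param max_iter iteration cap per start.
#' @param seed integer RNG seed.
#' @return list with `coordinates` (sample x k, centred), `stress`
#'   (stress-1, in \[0,1\]), `n_iterations`, `converged`.
#' @export
runNMDS <- function(d, k = 2, n_starts = 20, max_iter = 200, seed = 1) {
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  fit <- withSeed(seed, {
    vegan::metaMDS(as.dist(d), k = k, try = n_starts, trymax = n_starts,
                   maxit = max_iter, trace = 0, autotransform = FALSE,
                   wascores = FALSE, engine = "monoMDS")
  })
  coords <- scale(fit$points, center = TRUE, scale = FALSE)
  list(coordinates = coords[, , drop = FALSE], stress = fit$stress,
       n_iterations = fit$iters %||% NA_integer_,
       converged = isTRUE(fit$converged) || (fit$stress < 1e-4))
}

#' PERMANOVA (ADONIS) on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance partitioning the
#' squared dissimilarities among groups (pseudo-F), with the
#' permutation p-value computed under optional restriction of
#' permutations within subject strata - appropriate for the paired
#' crossover design where each subject contributes one sample per
#' condition.
#'
#' @param d symmetric dissimilarity matrix.
#' @param groups group labels (>= 2 groups, each with >= 2 samples).
#' @param n_perm number of permutations (>= 10).
#' @param seed integer RNG seed.
#' @param strata optional subject labels restricting permutations.
#' @return list with `pseudo_F`, `R2`, `p_value`, `n_permutations`.
#' @export
runPermanova <- function(d, groups, n_perm = 999, seed = 1, strata = NULL) {
  if (n_perm < 10) stop("n_perm must be at least 10")
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  d <- as.dist(as.matrix(d))
  ctrl <- permute::how(nperm = n_perm)
  if (!is.null(strata)) permute::setBlocks(ctrl) <- factor(strata)
  df <- data.frame(groups = groups)
  fit <- withSeed(seed, {
    vegan::adonis2(d ~ groups, data = df, permutations = ctrl)
  })
  list(pseudo_F = fit$F[1], R2 = fit$R2[1], p_value = fit$`Pr(>F)`[1],
       n_permutations = n_perm)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb an enclosing simulation stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
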