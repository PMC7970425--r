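#' Default parameters of the paired-microbiome generator
#'
#' The defaults emulate the scale and structure of the crossover study
#' this pipeline targets: 26 subjects measured under both a placebo
#' (PL) and a nitrate (BR) condition; eight planted co-occurrence
#' modules of sizes 243, 48, 24, 71, 57, 71, 46 and 24 plus 26
#' background OTUs; condition fold changes on selected OTUs matching
#' the reported percent changes (e.g. +259%, +305%, -79%); and three
#' stable module-trait couplings at population correlations -0.39,
#' -0.44 and +0.48, alongside condition-specific (unstable) couplings
#' and baseline-only cognitive traits.
#'
#' @param n_subjects paired subjects (default 26).
#' @param module_sizes planted module sizes (default the eight sizes
#'   above).
#' @param n_background OTUs outside every module (default 26).
#' @param depth sequencing depth per sample; every sample's counts sum
#'   to exactly this (default 50000).
#' @param dispersion Dirichlet concentration; smaller values give more
#'   overdispersed compositional counts (default 5000, a count
#'   variance inflation of roughly 11 at the default depth).
#' @param lambda_range per-OTU loading range on the module factor
#'   (default c(1.0, 1.6)); together with `sigma` this yields
#'   within-module log-abundance correlations around 0.5-0.7 and,
#'   after count noise, observed correlations near 0.6 on retained
#'   OTUs - strong, hub-bearing co-occurrence modules.
#' @param sigma per-OTU log-abundance noise SD (default 0.5).
#' @param baseline_sd SD of per-OTU baseline log abundances (default
#'   1); calibrated so the rare-OTU filter retains about 90% of OTUs,
#'   matching a post-filter table of several hundred OTUs.
#' @param percent_changes named list (module label as character, "0"
#'   for background) of percent changes applied to the leading OTUs of
#'   each module; defaults mirror the reported per-module effects.
#' @param stable_couplings data.frame `trait`, `module`, `target_r` of
#'   couplings shared across conditions.
#' @param unstable_couplings data.frame `trait`, `module`, `target_r`,
#'   `scope` (`PL` or `BR`) of single-condition couplings.
#' @param baseline_couplings data.frame `trait`, `module`, `target_r`
#'   of baseline-only (ACE-III-style) trait couplings.
#' @param n_traits total per-condition traits (default 32; the
#'   remainder beyond the planted couplings are pure noise).
#' @param n_baseline_traits baseline-only traits (default 5).
#' @return named parameter list for [simulatePairedMicrobiome()].
#' @export
syntheticParams <- function(
    n_subjects = 26,
    module_sizes = c(243L, 48L, 24L, 71L, 57L, 71L, 46L, 24L),
    n_background = 26,
    depth = 50000,
    dispersion = 5000,
    lambda_range = c(1.0, 1.6),
    sigma = 0.5,
    baseline_sd = 1,
    percent_changes = list(
      `1` = c(-37, 118, -56, -66),
      `2` = c(-60, -79, -80, -46, -56, -78, -63),
      `3` = c(-30),
      `4` = c(-41, -47, -52),
      `5` = c(96, 183, 175, 305, 115, 109),
      `6` = c(259),
      `0` = c(628, 544)),
    stable_couplings = data.frame(
      trait = c("reaction_time", "MAP", "VO2_rest"),
      module = c(5L, 6L, 7L),
      target_r = c(-0.39, -0.44, 0.48)),
    unstable_couplings = data.frame(
      trait = c("plasma_nitrite", "muscle_PCr", "brain_Cho"),
      module = c(2L, 4L, 8L),
      target_r = c(0.5, -0.5, 0.5),
      scope = c("BR", "BR", "PL")),
    baseline_couplings = data.frame(
      trait = c("ACE_total", "ACE_language", "ACE_memory"),
      module = c(6L, 4L, 1L),
      target_r = c(0.45, 0.51, -0.40)),
    n_traits = 32,
    n_baseline_traits = 5) {
  as.list(environment())
}

#' Generate a paired synthetic microbiome dataset with ground truth
#'
#' Simulates a two-condition crossover dataset with planted
#' co-occurrence modules, condition effects and trait couplings.
#' Per-subject latent module factors `f_m ~ N(0, 1)` are shared across
#' conditions (inducing the paired-subject correlation of a crossover
#' design); the log abundance of OTU i in sample (s, c) is
#' `baseline_i + lambda_i * f_{module(i), s} + logFC_i * [c == BR] +
#' noise`; sample compositions are closed through a softmax and counts
#' drawn Dirichlet-multinomial at the stated depth, so every sample
#' sums to exactly `depth`. Planted traits are linear in the realized
#' per-condition module eigengene (computed exactly as the analysis
#' pipeline computes it, from the planted labels) with unit-variance
#' Gaussian noise weighted so the population eigengene-trait
#' correlation equals the planted `target_r`; stable couplings share
#' the target across conditions, unstable ones load in a single
#' condition, and baseline-only traits couple to the placebo
#' eigengene. Byte-identical reproducible from `(params, seed)`.
#'
#' @param params parameter list from [syntheticParams()].
#' @param seed integer RNG seed.
#' @return a [SyntheticDataset-class].
#' @export
simulatePairedMicrobiome <- function(params = syntheticParams(), seed = 1) {
  p <- params
  n_mod <- length(p$module_sizes)
  n_otu <- sum(p$module_sizes) + p$n_background
  module_of <- rep(c(seq_len(n_mod), 0L),
                   c(p$module_sizes, p$n_background))
  otu_ids <- sprintf("OTU%04d", seq_len(n_otu))
  names(module_of) <- otu_ids

  log_fc <- setNames(numeric(n_otu), otu_ids)
  for (mod in names(p$percent_changes)) {
    idx <- which(module_of == as.integer(mod))
    eff <- p$percent_changes[[mod]]
    if (length(eff) > length(idx))
      stop("module ", mod, " too small for its planted effects")
    log_fc[idx[seq_along(eff)]] <- log1p(eff / 100)
  }

  ns <- p$n_subjects
  subjects <- sprintf("S%02d", seq_len(ns))

  withSeed(seed, {
    lambda <- runif(n_otu, p$lambda_range[1], p$lambda_range[2])
    lambda[module_of == 0L] <- 0
    baseline <- rnorm(n_otu, 0, p$baseline_sd)
    f <- matrix(rnorm(ns * n_mod), ns, n_mod,
                dimnames = list(subjects, NULL))

    counts <- matrix(0L, n_otu, 2 * ns,
                     dimnames = list(otu_ids, NULL))
    cond <- rep(c("PL", "BR"), each = ns)
    subj <- rep(subjects, 2)
    colnames(counts) <- paste0(subj, "_", cond)
    for (j in seq_len(2 * ns)) {
      fm <- ifelse(module_of > 0, f[subj[j], pmax(module_of, 1L)], 0)
      lx <- baseline + lambda * fm +
        if (cond[j] == "BR") log_fc else 0
      lx <- lx + rnorm(n_otu, 0, p$sigma)
      q <- exp(lx - max(lx)); q <- q / sum(q)
      g <- rgamma(n_otu, shape = q * p$dispersion, rate = 1)
      if (sum(g) == 0) g[which.max(q)] <- 1
      counts[, j] <- as.integer(rmultinom(1, p$depth, g / sum(g)))
    }

    # realized per-condition module eigengenes, computed exactly as the
    # analysis pipeline computes them (log10 transform of relative
    # abundances, standardized PC1 over the planted members), so trait
    # couplings are calibrated against the quantity the pipeline will
    # actually correlate - no analytic attenuation correction needed
    xs <- transformForNetwork(sweep(counts, 2, colSums(counts), "/"))
    eg <- lapply(c(PL = "PL", BR = "BR"), function(cd) {
      m <- xs[cond == cd, , drop = FALSE]
      rownames(m) <- subj[cond == cd]
      moduleEigengene(m[subjects, , drop = FALSE], module_of)
    })
    loads <- .assemble_trait_loadings(p)
    mk_traits <- function(scope_set, traits, eg_cond) {
      out <- matrix(rnorm(ns * length(traits)), ns, length(traits),
                    dimnames = list(subjects, traits))
      for (k in seq_len(nrow(loads))) {
        if (!loads$scope[k] %in% scope_set) next
        tr <- loads$trait[k]
        if (!tr %in% traits) next
        r <- loads$target_r[k]
        if (abs(r) >= 1)
          stop("infeasible target_r for trait '", tr, "'")
        e <- eg[[eg_cond]][, paste0("ME", loads$module[k])]
        out[, tr] <- r * e + sqrt(1 - r^2) * rnorm(ns)
      }
      out
    }
    per_cond <- .trait_names(p)
    pl <- mk_traits(c("both", "PL"), per_cond, "PL")
    br <- mk_traits(c("both", "BR"), per_cond, "BR")
    base_names <- .baseline_trait_names(p)
    base <- mk_traits("BASE", base_names, "PL")
  })

  taxonomy <- sprintf(
    "Bacteria;Class%02d;Order%02d;Family%02d;Genus%04d;Species%04d",
    module_of + 1L, module_of + 1L, module_of + 1L,
    seq_len(n_otu), seq_len(n_otu))

  otus <- OtuExperiment(counts, subject = subj, condition = cond,
                        taxonomy = taxonomy)
  traits <- TraitTable(pl, br, base = base)
  truth <- new("SyntheticTruth", moduleOf = module_of,
               conditionLogFc = log_fc,
               traitLoadings = .assemble_trait_loadings(p),
               seed = as.integer(seed), params = p)
  new("SyntheticDataset", otus = otus, traits = traits, truth = truth)
}

.trait_names <- function(p) {
  planted <- c(p$stable_couplings$trait, p$unstable_couplings$trait)
  extra <- p$n_traits - length(planted)
  if (extra < 0) stop("n_traits smaller than the planted couplings")
  c(planted, sprintf("trait_%02d", seq_len(extra)))
}

.baseline_trait_names <- function(p) {
  planted <- p$baseline_couplings$trait
  extra <- p$n_baseline_traits - length(planted)
  if (extra < 0) stop("n_baseline_traits smaller than planted couplings")
  c(planted, sprintf("ACE_extra_%02d", seq_len(extra)))
}

.assemble_trait_loadings <- function(p) {
  tag <- function(df, scope = NULL) {
    out <- data.frame(trait = df$trait, module = df$module,
                      target_r = df$target_r)
    out$scope <- if (is.null(scope)) df$scope
                 else rep(scope, nrow(out))
    out
  }
  rbind(tag(p$stable_couplings, "both"),
        tag(p$unstable_couplings),
        tag(p$baseline_couplings, "BASE"))
}

#' Export and re-import planted ground truth
#'
#' Writes one row per OTU (`otu_id`, `module`, `condition_log_fc`) as
#' TSV; trait couplings go to a sidecar `<path>.loadings.tsv`.
#'
#' @param d a [SyntheticDataset-class].
#' @param path output TSV path.
#' @return `exportTruth()` returns `path` invisibly; `readTruth()` a
#'   list with `otus` and `loadings` data.frames.
#' @export
exportTruth <- function(d, path) {
  tr <- d@truth
  df <- data.frame(otu_id = names(tr@moduleOf),
                   module = unname(tr@moduleOf),
                   condition_log_fc = unname(tr@conditionLogFc))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tr@traitLoadings, paste0(path, ".loadings.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname exportTruth
#' @export
readTruth <- function(path) {
  list(otus = read.delim(path, stringsAsFactors = FALSE),
       loadings = read.delim(paste0(path, ".loadings.tsv"),
                             stringsAsFactors = FALSE))
}

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement between a detected module assignment and
#' the planted truth (1 = identical partitions up to relabeling,
#' ~0 = chance).
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(length(a))
  expected <- sum_a * sum_b / n
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
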