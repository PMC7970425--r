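test_that("generation is byte-identical for a fixed seed", {
  p <- small_params()
  d1 <- simulatePairedMicrobiome(p, seed = 11)
  d2 <- simulatePairedMicrobiome(p, seed = 11)
  expect_identical(otuCounts(d1@otus), otuCounts(d2@otus))
  expect_identical(traitValues(d1@traits, "PL"), traitValues(d2@traits, "PL"))
  expect_identical(traitValues(d1@traits, "BASE"),
                   traitValues(d2@traits, "BASE"))
  d3 <- simulatePairedMicrobiome(p, seed = 12)
  expect_false(identical(otuCounts(d1@otus), otuCounts(d3@otus)))
})

test_that("counts close to the stated sequencing depth per sample", {
  p <- small_params()
  d <- simulatePairedMicrobiome(p, seed = 13)
  expect_true(all(colSums(otuCounts(d@otus)) == p$depth))
  expect_equal(nrow(d@otus), sum(p$module_sizes) + p$n_background)
  expect_equal(ncol(d@otus), 2 * p$n_subjects)
})

test_that("default preset mirrors the study scale", {
  p <- syntheticParams()
  expect_identical(p$n_subjects, 26)
  expect_identical(p$module_sizes, c(243L, 48L, 24L, 71L, 57L, 71L, 46L, 24L))
  expect_identical(p$n_background, 26)
  expect_identical(p$n_traits, 32)
  expect_equal(sort(p$stable_couplings$target_r), c(-0.44, -0.39, 0.48))
})

test_that("strong loadings and vanishing noise drive correlations to 1", {
  p <- small_params(lambda_range = c(3, 3), sigma = 0.05,
                    dispersion = 1e6, depth = 2e5, baseline_sd = 0.3)
  d <- simulatePairedMicrobiome(p, seed = 14)
  xs <- split_conditions(d@otus)
  truth <- d@truth@moduleOf
  m1 <- names(truth)[truth == 1L]
  cc <- cor(xs$PL[, m1])
  expect_gt(min(cc), 0.9)
})

test_that("a null generator produces ~alpha false positives", {
  p <- small_params(percent_changes = list(),
                    stable_couplings = data.frame(trait = character(),
                      module = integer(), target_r = numeric()),
                    unstable_couplings = data.frame(trait = character(),
                      module = integer(), target_r = numeric(),
                      scope = character()),
                    baseline_couplings = data.frame(trait = character(),
                      module = integer(), target_r = numeric()))
  hits <- 0; cells <- 0
  for (s in 1:10) {
    d <- simulatePairedMicrobiome(p, seed = 600 + s)
    xs <- split_conditions(d@otus)
    truth <- d@truth@moduleOf
    net <- eigengeneTraitCorrelation(moduleEigengene(xs$PL, truth),
                                     d@traits, "PL")
    hits <- hits + sum(net@p <= 0.05, na.rm = TRUE)
    cells <- cells + sum(!is.na(net@p))
  }
  expect_gt(hits / cells, 0.01)
  expect_lt(hits / cells, 0.10)
})

test_that("planted eigengene-trait correlation hits its target at large n", {
  p <- small_params(n_subjects = 1500)
  d <- simulatePairedMicrobiome(p, seed = 15)
  xs <- split_conditions(d@otus)
  truth <- d@truth@moduleOf
  eg_pl <- moduleEigengene(xs$PL, truth)
  eg_br <- moduleEigengene(xs$BR, truth)
  tl <- d@truth@traitLoadings
  dev <- c()
  for (k in which(tl$scope == "both")) {
    me <- paste0("ME", tl$module[k])
    r_pl <- cor(eg_pl[, me], traitValues(d@traits, "PL")[rownames(eg_pl),
                                                         tl$trait[k]])
    r_br <- cor(eg_br[, me], traitValues(d@traits, "BR")[rownames(eg_br),
                                                         tl$trait[k]])
    dev <- c(dev, r_pl - tl$target_r[k], r_br - tl$target_r[k])
  }
  # aggregated over couplings and conditions so the Monte-Carlo error
  # of a single sample correlation (~0.02 at n = 1500) averages out
  expect_lt(mean(abs(dev)), 0.03)
  expect_lt(max(abs(dev)), 0.06)
  # single-condition coupling: present in BR, absent in PL
  un <- tl[tl$scope == "BR", ][1, ]
  me <- paste0("ME", un$module)
  expect_equal(cor(eg_br[, me],
                   traitValues(d@traits, "BR")[rownames(eg_br), un$trait]),
               un$target_r, tolerance = 0.08)
  expect_lt(abs(cor(eg_pl[, me],
                    traitValues(d@traits, "PL")[rownames(eg_pl), un$trait])),
            0.08)
})

test_that("planted condition effects shift observed relative abundances", {
  hit <- 0; tot <- 0
  for (s in 1:5) {
    d <- simulatePairedMicrobiome(seed = 700 + s)
    relab <- relativeAbundance(d@otus)
    cond <- sampleCondition(d@otus)
    fc <- d@truth@conditionLogFc
    big <- names(fc)[abs(fc) > 0]
    obs <- log(rowMeans(relab[big, cond == "BR"]) /
               rowMeans(relab[big, cond == "PL"]))
    # planted log fold changes are tracked within +-15 percentage points
    # of the percent scale for moderately sized effects
    pct_err <- abs(100 * (exp(obs) - 1) - 100 * (exp(fc[big]) - 1))
    hit <- hit + sum(pct_err <= 15 + 0.15 * abs(100 * (exp(fc[big]) - 1)))
    tot <- tot + length(big)
  }
  expect_gt(hit / tot, 0.6)
})

test_that("truth export round-trips and is stable across identical runs", {
  p <- small_params()
  d <- simulatePairedMicrobiome(p, seed = 16)
  path <- withr::local_tempfile(fileext = ".tsv")
  exportTruth(d, path)
  back <- readTruth(path)
  expect_identical(nrow(back$otus), nrow(d@otus))
  expect_identical(back$otus$module, unname(d@truth@moduleOf))
  expect_equal(back$otus$condition_log_fc, unname(d@truth@conditionLogFc))
  expect_identical(back$loadings$trait, d@truth@traitLoadings$trait)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  exportTruth(simulatePairedMicrobiome(p, seed = 16), path2)
  expect_identical(unname(tools::md5sum(path)), unname(tools::md5sum(path2)))
})

test_that("infeasible trait targets are rejected by name", {
  p <- small_params(stable_couplings = data.frame(
    trait = "impossible", module = 1L, target_r = 1.2))
  expect_error(simulatePairedMicrobiome(p, seed = 1), "impossible")
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(91)
  for (i in 1:10) {
    a <- sample(0:3, 60, replace = TRUE)
    b <- sample(0:3, 60, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjustedRandIndex(rep(1, 5), rep(2, 5)), 1)
})
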