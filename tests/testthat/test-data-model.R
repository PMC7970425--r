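test_that("OTU table TSV round-trip preserves counts and taxonomy", {
  cnt <- rand_counts(3, 2, seed = 4)
  tax <- c("P1;C1;O1;F1;G1;S1", "P1;C1;O1;F1;G1;S2", "P2;C2;O2;F2;G2;S3")
  oe <- toy_otu(cnt, taxonomy = tax)
  expect_identical(dim(oe), c(3L, 4L))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeOtuTable(oe, path)
  back <- readOtuTable(path)
  expect_identical(otuCounts(back), otuCounts(oe))
  expect_identical(otuTaxonomy(back), tax)
  expect_identical(as.character(sampleCondition(back)),
                   as.character(sampleCondition(oe)))
})

test_that("subjects missing one condition are dropped with a warning", {
  cnt <- rand_counts(3, 2, seed = 5)
  cnt <- cbind(cnt, S3_PL = c(5L, 5L, 5L))
  expect_warning(
    oe <- OtuExperiment(cnt, subject = c("S1", "S1", "S2", "S2", "S3"),
                        condition = c("PL", "BR", "PL", "BR", "PL")),
    "S3")
  expect_identical(ncol(oe), 4L)
  expect_false("S3" %in% sampleSubject(oe))
})

test_that("malformed tables are rejected", {
  cnt <- rand_counts(2, 2)
  rownames(cnt) <- c("A", "A")
  expect_error(toy_otu(cnt), "duplicate OTU id")
  cnt2 <- rand_counts(2, 2)
  cnt2[1, 1] <- -1L
  expect_error(toy_otu(cnt2), "non-negative")
})

test_that("rare-OTU filtering applies the two rules sequentially", {
  # 4 samples; hand-enumerated rule outcomes
  cnt <- rbind(
    allzero  = c(0L, 0L, 0L, 0L),    # rule 1 (< 10 everywhere)
    justlow  = c(9L, 9L, 9L, 9L),    # rule 1 despite good prevalence
    peak     = c(10L, 6L, 7L, 6L),   # kept: >= 10 once, >= 5 in all
    sparse   = c(12L, 0L, 0L, 0L),   # rule 2: < 5 in 75% of samples
    boundary = c(10L, 5L, 4L, 5L))   # kept: < 5 in only 25%
  oe <- toy_otu(cnt)
  flt <- filterRareOtus(oe)
  rep <- filterReport(flt)
  expect_setequal(rownames(flt), c("peak", "boundary"))
  expect_identical(rep@nInput, 5L)
  expect_identical(rep@nRemovedRule1, 2L)
  expect_identical(rep@nRemovedRule2, 1L)
  # surviving counts untouched
  expect_identical(otuCounts(flt), otuCounts(oe)[c("peak", "boundary"), ])
  # an OTU sitting exactly at 50% low-prevalence is removed (>= frac)
  cnt2 <- rbind(half = c(10L, 4L, 6L, 4L), keep = c(10L, 10L, 10L, 10L))
  expect_setequal(rownames(filterRareOtus(toy_otu(cnt2))), "keep")
})

test_that("filtering is idempotent", {
  oe <- toy_otu(rand_counts(40, 4, seed = 9, lambda = 12))
  once <- filterRareOtus(oe)
  twice <- filterRareOtus(once)
  expect_identical(otuCounts(twice), otuCounts(once))
  expect_identical(filterReport(twice)@nRemovedRule1, 0L)
  expect_identical(filterReport(twice)@nRemovedRule2, 0L)
})

test_that("filtering everything is an error", {
  expect_error(filterRareOtus(toy_otu(rbind(a = c(1L, 1L, 1L, 1L)))),
               "all OTUs filtered")
})

test_that("relative abundances are column-normalised fractions", {
  cnt <- rbind(a = c(2L, 1L, 3L, 1L), b = c(2L, 3L, 1L, 3L))
  relab <- relativeAbundance(toy_otu(cnt))
  expect_equal(unname(relab[, 1]), c(0.5, 0.5))
  expect_equal(unname(relab[, 2]), c(0.25, 0.75))
  relab2 <- relativeAbundance(toy_otu(rand_counts(30, 5, seed = 2)))
  expect_equal(unname(colSums(relab2)), rep(1, 10), tolerance = 1e-12)
  cnt0 <- rbind(a = c(5L, 0L, 2L, 2L), b = c(5L, 0L, 2L, 2L))
  expect_error(relativeAbundance(toy_otu(cnt0)), "S1_BR")
})

test_that("network transform is log10 with pseudocount, invertible", {
  relab <- relativeAbundance(toy_otu(rand_counts(20, 4, seed = 3)))
  out <- transformForNetwork(relab, pseudocount = 1e-6)
  expect_identical(dim(out), rev(dim(relab)))
  expect_equal(max(abs(10^out - 1e-6 - t(relab))), 0, tolerance = 1e-12)
  # zero maps to log10(pseudocount); monotone in the fraction
  zr <- matrix(c(0, 0.1, 0.9, 1), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  tr <- transformForNetwork(zr, pseudocount = 1e-6)
  expect_equal(tr["s1", "a"], -6)
  expect_true(all(diff(sort(tr[order(t(zr))])) >= 0))
  expect_error(transformForNetwork(relab, pseudocount = 0), "positive")
})

test_that("relative nitrate dose conversion matches the worked range", {
  expect_equal(computeRelativeDose(750, 51.4, digits = 2), 0.24)
  expect_equal(computeRelativeDose(750, 103.0, digits = 2), 0.12)
  expect_equal(computeRelativeDose(0, 70), 0)
  expect_error(computeRelativeDose(750, 0), "positive")
})

test_that("report rounding is half away from zero", {
  expect_equal(roundHalfAway(0.125, 2), 0.13)
  expect_equal(roundHalfAway(-0.125, 2), -0.13)
  expect_equal(roundHalfAway(2.5), 3)
})

test_that("trait table TSV round-trip keeps per-condition and baseline", {
  pl <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("S", 1:3),
                                               c("MAP", "VO2")))
  br <- pl + 1
  base <- matrix(c(90, 85, NA), 3, 1,
                 dimnames = list(paste0("S", 1:3), "ACE_total"))
  tt <- TraitTable(pl, br, base = base)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTraitTable(tt, path)
  back <- readTraitTable(path)
  expect_equal(traitValues(back, "PL"), pl)
  expect_equal(traitValues(back, "BR"), br)
  expect_equal(traitValues(back, "BASE"), base)
})

test_that("taxonomic rollup sums fractions within lineage", {
  relab <- rbind(a = c(0.2, 0.5), b = c(0.3, 0.25), c = c(0.5, 0.25))
  colnames(relab) <- c("s1", "s2")
  tax <- c("P1;C;O;F;G1;Sp1", "P1;C;O;F;G1;Sp2", "P2;C;O;F;G2;Sp3")
  phy <- rollupRank(relab, tax, "phylum")
  expect_equal(unname(phy["P1", ]), c(0.5, 0.75))
  gen <- rollupRank(relab, tax, "genus")
  expect_identical(nrow(gen), 2L)
  expect_equal(unname(colSums(gen)), c(1, 1))
})
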