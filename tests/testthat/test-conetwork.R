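test_that("signed adjacency maps correlation through ((1+r)/2)^beta", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),      # cor +1
             c = c(4, 3, 2, 1),                         # cor -1 with a
             d = c(1, -1, 1, -1), e = c(1, 1, -1, -1))  # cor 0 pair
  a6 <- signedAdjacency(x, beta = 6)
  expect_equal(a6["a", "b"], 1)
  expect_equal(a6["a", "c"], 0)
  expect_equal(a6["d", "e"], 0.5^6)
  expect_equal(diag(a6), setNames(rep(1, 5), colnames(x)))
  # zero-variance OTU flagged, correlations zeroed
  xz <- cbind(x, z = rep(3, 4))
  az <- suppressWarnings(signedAdjacency(xz, beta = 2))
  expect_identical(attr(az, "zero_variance"), "z")
  expect_equal(az["z", "a"], 0.25)   # ((1+0)/2)^2
  expect_error(signedAdjacency(x[1:2, ], 2), "3 samples")
})

test_that("scale-free fit index is ~1 on an exact power law, low on flat", {
  # degree sequence with p(k) proportional to k^-1 over octaves
  k <- rep(2^(0:7), times = round(2048 / 2^(0:7)))
  fit <- suppressWarnings(scaleFreeFitIndex(k, n_bins = 8))
  expect_gte(fit$r2_signed, 0.99)
  expect_lt(fit$slope, 0)
  # near-uniform degrees carry no scale-free signal
  set.seed(2)
  flat <- runif(400, 9, 11)
  expect_lt(scaleFreeFitIndex(flat)$r2_signed, 0.8)
})

test_that("soft threshold selection is minimal among passing powers", {
  d <- simulatePairedMicrobiome(small_params(), seed = 2)
  xs <- split_conditions(d@otus)
  sel <- suppressWarnings(
    pickSoftThreshold(xs$PL, xs$BR, powers = 1:20, r2_target = 0.8))
  fits <- sel$fits
  expect_identical(nrow(fits), 20L)   # full candidate grid covered
  min_r2 <- pmin(fits$r2_PL, fits$r2_BR)
  pass <- fits$power[!is.na(min_r2) & min_r2 >= 0.8]
  if (length(pass)) {
    expect_identical(sel$beta, as.integer(min(pass)))
  } else {
    # sample-size fallback for a 26-subject signed network
    expect_identical(sel$beta, 16L)
  }
  expect_true(all(diff(fits$mean_k_PL) < 0))  # connectivity shrinks
})

test_that("TOM matches closed forms and the triple-loop oracle", {
  # complete unit-weight graph: overlap is exactly 1
  ones <- matrix(1, 5, 5)
  expect_equal(tomSimilarity(ones), ones)
  # 3 nodes at a = 0.5: (0.25 + 0.5) / (1 + 1 - 0.5)
  half <- matrix(0.5, 3, 3); diag(half) <- 1
  expect_equal(tomSimilarity(half)[1, 2], 0.5)
  # empty graph
  expect_equal(tomSimilarity(diag(4)), diag(4))
  set.seed(31)
  for (i in 1:5) {
    a <- matrix(runif(100), 10, 10)
    a <- (a + t(a)) / 2; diag(a) <- 1
    expect_equal(tomSimilarity(a), tomSimilarityNaive(a),
                 tolerance = 1e-12)
  }
  expect_error(tomSimilarity(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("consensus TOM is idempotent and bounded by both conditions", {
  set.seed(5)
  a <- matrix(runif(64, 0, 0.9), 8, 8); a <- (a + t(a)) / 2; diag(a) <- 1
  tm <- tomSimilarity(a)
  expect_equal(consensusTom(tm, tm), tm)
  b <- matrix(runif(64, 0, 0.9), 8, 8); b <- (b + t(b)) / 2; diag(b) <- 1
  tb <- tomSimilarity(b)
  cons <- consensusTom(tm, tb)
  expect_true(all(cons <= tm + 1e-12))
  expect_error(consensusTom(tm, tb[1:4, 1:4]), "shape")
})

test_that("a module present in only one condition collapses in consensus", {
  set.seed(17)
  n <- 26
  f <- rnorm(n)
  # module pairs kept well under the 95% scaling quantile's mass
  block <- sapply(1:20, function(i) 1.2 * f + rnorm(n, sd = 0.4))
  noise_pl <- cbind(block, matrix(rnorm(n * 130), n))
  noise_br <- matrix(rnorm(n * 150), n)  # same OTUs, no structure in BR
  colnames(noise_pl) <- colnames(noise_br) <- paste0("O", 1:150)
  t_pl <- tomSimilarity(signedAdjacency(noise_pl, 6))
  t_br <- tomSimilarity(signedAdjacency(noise_br, 6))
  cons <- consensusTom(t_pl, t_br)
  blk <- upper.tri(diag(20)); bgi <- 21:150; bgt <- upper.tri(diag(130))
  within_pl <- mean(t_pl[1:20, 1:20][blk])
  bg_pl <- mean(t_pl[bgi, bgi][bgt])
  within_cons <- mean(cons[1:20, 1:20][blk])
  bg_cons <- mean(cons[bgi, bgi][bgt])
  expect_gt(within_pl / bg_pl, 5)          # module visible in PL alone
  # collapsed toward background (residual elevation reflects the min
  # of skewed noise in the unstructured pairs, not retained structure)
  expect_lt(within_cons / bg_cons, (within_pl / bg_pl) / 4)
  expect_lt(within_cons / bg_cons, 4)
})

test_that("perfectly separable TOM yields exactly its blocks as modules", {
  sizes <- c(30, 25, 22)
  tm <- matrix(0, sum(sizes), sum(sizes))
  start <- cumsum(c(1, sizes))
  for (i in seq_along(sizes)) {
    idx <- start[i]:(start[i + 1] - 1)
    tm[idx, idx] <- 1
  }
  diag(tm) <- 1
  rownames(tm) <- colnames(tm) <- paste0("O", seq_len(sum(sizes)))
  mods <- detectModules(tm, min_module_size = 20)
  expect_identical(sum(moduleLabels(mods) == 0), 0L)
  expect_identical(length(unique(moduleLabels(mods))), 3L)
  expect_equal(adjustedRandIndex(moduleLabels(mods),
                                 rep(1:3, sizes)), 1)
})

test_that("structureless data leaves most OTUs unassigned", {
  set.seed(23)
  x <- matrix(rnorm(26 * 150), 26, 150,
              dimnames = list(NULL, paste0("O", 1:150)))
  tm <- tomSimilarity(signedAdjacency(x, 6))
  mods <- detectModules(tm, x = list(PL = x), min_module_size = 20)
  expect_lt(mean(moduleLabels(mods) > 0), 0.2)
  expect_error(detectModules(tm, min_module_size = 2), ">= 3")
})

test_that("eigengenes are unit-variance, sign-oriented, SVD-consistent", {
  set.seed(41)
  f <- rnorm(30)
  x <- cbind(sapply(1:8, function(i) f + rnorm(30, sd = 0.3)),
             sapply(1:6, function(i) rnorm(30)))
  colnames(x) <- paste0("O", 1:14)
  labels <- setNames(c(rep(1L, 8), rep(2L, 6)), colnames(x))
  eg <- moduleEigengene(x, labels)
  expect_equal(apply(eg, 2, sd), c(ME1 = 1, ME2 = 1))
  expect_gt(cor(eg[, "ME1"], f), 0.9)
  # sign convention: positive mean correlation with members
  expect_gt(mean(cor(x[, 1:8], eg[, "ME1"])), 0)
  # variance explained equals the top singular-value share (oracle)
  sub <- scale(x[, 1:8])
  sv <- svd(sub)
  expect_equal(attr(eg, "var_explained")[["ME1"]],
               sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
  # invariance to member ordering
  perm <- c(sample(1:8), 9:14)
  eg2 <- moduleEigengene(x[, perm], labels[perm])
  expect_equal(eg2[, "ME1"], eg[, "ME1"], tolerance = 1e-10)
  # identical profiles: eigengene correlates 1 with each member
  xid <- cbind(a = f, b = f, c = f)
  egid <- moduleEigengene(xid, setNames(rep(1L, 3), colnames(xid)))
  expect_equal(unname(cor(xid[, 1], egid[, 1])), 1, tolerance = 1e-12)
})

test_that("kME is bounded, 1 for perfect members, small for noise", {
  set.seed(43)
  f <- rnorm(26)
  x <- cbind(m1 = f, m2 = f, noise = rnorm(26))
  labels <- setNames(c(1L, 1L, 0L), colnames(x))
  km <- kmeMatrix(x, moduleEigengene(x, labels))
  expect_true(all(abs(km) <= 1 + 1e-12))
  expect_equal(unname(km["m1", "ME1"]), 1, tolerance = 1e-10)
  # orthogonal noise stays well below membership strength at n = 26
  null_kme <- replicate(50, {
    xn <- cbind(sapply(1:5, function(i) f + rnorm(26, sd = 0.2)),
                rnorm(26))
    colnames(xn) <- c(paste0("O", 1:5), "probe")
    lab <- setNames(c(rep(1L, 5), 0L), colnames(xn))
    abs(kmeMatrix(xn, moduleEigengene(xn, lab))["probe", "ME1"])
  })
  expect_lt(quantile(null_kme, 0.9), 0.5)
})

test_that("module detection is deterministic for identical input", {
  d <- simulatePairedMicrobiome(small_params(), seed = 6)
  xs <- split_conditions(d@otus)
  net1 <- buildConsensusNetwork(xs$PL, xs$BR, beta = 6)
  net2 <- buildConsensusNetwork(xs$PL, xs$BR, beta = 6)
  m1 <- detectModules(net1$networks$consensus@tom, x = xs)
  m2 <- detectModules(net2$networks$consensus@tom, x = xs)
  expect_identical(moduleLabels(m1), moduleLabels(m2))
})
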