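# small in-code fixtures shared across test files

# paired OtuExperiment with explicit counts (otu x sample); samples are
# S1_PL, S1_BR, S2_PL, S2_BR, ... for n_subj subjects
toy_otu <- function(counts, taxonomy = NULL) {
  n_subj <- ncol(counts) / 2
  subj <- rep(sprintf("S%d", seq_len(n_subj)), each = 2)
  cond <- rep(c("PL", "BR"), n_subj)
  colnames(counts) <- paste0(subj, "_", cond)
  OtuExperiment(counts, subject = subj, condition = cond,
                taxonomy = taxonomy)
}

# deterministic random count matrix
rand_counts <- function(n_otu, n_subj, seed = 1, lambda = 50) {
  set.seed(seed)
  matrix(rpois(n_otu * 2 * n_subj, lambda), n_otu, 2 * n_subj,
         dimnames = list(sprintf("OTU%03d", seq_len(n_otu)), NULL))
}

# small-scale synthetic preset used where full study scale is not needed
small_params <- function(...) {
  base <- list(
    module_sizes = c(40L, 30L, 25L),
    n_background = 15,
    depth = 20000,
    percent_changes = list(`1` = c(300, -79), `2` = c(150)),
    stable_couplings = data.frame(
      trait = c("trait_a", "trait_b"), module = c(1L, 2L),
      target_r = c(0.48, -0.44)),
    unstable_couplings = data.frame(
      trait = "trait_c", module = 3L, target_r = 0.5, scope = "BR"),
    baseline_couplings = data.frame(
      trait = "ACE_total", module = 1L, target_r = 0.45),
    n_traits = 8, n_baseline_traits = 2)
  ov <- list(...)
  base[names(ov)] <- ov
  do.call(syntheticParams, base)
}

# transformed per-condition matrices (subjects as rownames, sorted)
split_conditions <- function(oe) {
  xs <- transformForNetwork(relativeAbundance(oe))
  cond <- sampleCondition(oe)
  subj <- sampleSubject(oe)
  out <- lapply(c(PL = "PL", BR = "BR"), function(cd) {
    m <- xs[cond == cd, , drop = FALSE]
    rownames(m) <- subj[cond == cd]
    m[order(rownames(m)), , drop = FALSE]
  })
  out
}
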