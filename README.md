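# micronet

Weighted co-occurrence network analysis for paired (crossover-design)
microbiome data.

`micronet` is built for studies in which the same subjects provide a
microbial community profile under two conditions — here a placebo
(`PL`) and a nitrate-rich (`BR`) dietary condition — together with
physiological and cognitive traits measured under each condition. The
question it answers is: *which groups of co-occurring taxa move
together, which of them respond to the intervention, and which of their
relationships with host traits are stable across both conditions* (and
hence candidate biomarkers rather than condition-specific noise)?

## The method

Starting from an OTU count table (paired samples, taxonomy per OTU) and
a per-subject trait table, the pipeline:

1. **Filters rare OTUs** — an OTU is removed if its count is below 10
   in every sample of both conditions, then if it has fewer than 5
   counts in at least 50% of the remaining samples.
2. **Builds a signed weighted network per condition** on
   log10-transformed relative abundances: adjacency
   `a_ij = ((1 + cor(x_i, x_j))/2)^beta`, so only positive
   co-occurrence forms modules. The soft power `beta` is the smallest
   value whose scale-free fit `R^2 >= 0.8` holds in both conditions,
   with a sample-size-based fallback.
3. **Smooths each adjacency into a topological overlap matrix (TOM)**,
   `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, and reduces
   the two conditions to a **consensus TOM** (quantile-calibrated
   element-wise minimum): an edge is only as strong as it is in the
   weaker condition.
4. **Detects modules** by average-linkage clustering on `1 - TOM` with
   an adaptive cut, cohesion validation (noise clusters dissolve to
   the unassigned "grey" module) and eigengene-based merging, then
   summarises each module by its **eigengene** (first principal
   component of the member profiles).
5. **Correlates eigengenes with traits** per condition and reduces the
   two matrices to a **consensus correlation network**: cells keep the
   sign-concordant minimum magnitude with the maximum p-value, and
   sign-discordant cells are zeroed — the screen for relationships
   stable across diets. Baseline-only traits (ACE-III subscores) are
   analysed within the placebo network.
6. **Identifies module drivers** with a Kruskal–Wallis screen followed
   by a bootstrapped LDA effect size; drivers are OTUs with
   `|log10 LDA effect| >= 2` between conditions.

Alpha diversity (Shannon H', Chao1, richness), Bray–Curtis NMDS,
PERMANOVA (stratified by subject), and paired differential abundance
with Benjamini–Hochberg correction and percent-change reporting round
out the standard community-level comparisons.

A first-class **synthetic data generator**
(`simulatePairedMicrobiome()`) emulates the study design — 26 paired
subjects, eight planted modules of 24–243 OTUs plus background,
Dirichlet-multinomial counts at fixed depth, planted condition effects
and trait couplings with exported ground truth — so every inferential
step can be benchmarked against known truth.

## Worked example

```r
library(micronet)

d  <- simulatePairedMicrobiome(seed = 7)   # paired 26-subject dataset
oe <- filterRareOtus(d@otus)
oe
#> OtuExperiment: 550 OTUs x 52 samples (26 paired subjects)
#> ...
#> FilterReport: 610 input OTUs; 0 removed by rule 1 (<min everywhere),
#>  60 by rule 2 (low prevalence); 550 retained; 0 sample(s) dropped

xs  <- transformForNetwork(relativeAbundance(oe))
cond <- sampleCondition(oe)
x_pl <- xs[cond == "PL", ]; rownames(x_pl) <- sampleSubject(oe)[cond == "PL"]
x_br <- xs[cond == "BR", ]; rownames(x_br) <- sampleSubject(oe)[cond == "BR"]

net  <- buildConsensusNetwork(x_pl, x_br)
mods <- detectModules(net$networks$consensus@tom,
                      x = list(PL = x_pl, BR = x_br))
mods
#> ModuleSet: 8 modules over 550 OTUs (3 unassigned)
#>   0   1   2   3   4   5   6   7   8
#>   3 229  63  62  55  45  39  34  20

adjustedRandIndex(moduleLabels(mods), d@truth@moduleOf[rownames(oe)])
#> [1] 0.989
```

The detected partition recovers the planted modules at an adjusted Rand
index of 0.99; the module sizes mirror the planted 243/71/71/57/48/46/24/24
structure after filtering. Correlating eigengenes with traits and
reducing to the consensus (`eigengeneTraitCorrelation()`,
`consensusCorrelation()`, `significantCells()`) then yields the short
list of diet-stable module–trait relationships, and
`lefseModules()`/`moduleDrivers()` lists the per-module driver OTUs.

`runPipeline(defaultConfig(seed = 1))` executes all stages end to end,
writing per-stage TSVs, a markdown report and a manifest with
checksums; `inst/scripts/micronet.R` wraps it for shell use. One dose
bookkeeping helper is included: `computeRelativeDose(750, 51.4,
digits = 2)` returns `0.24` mmol·kg⁻¹·d⁻¹ (a 750 mg/d nitrate dose for
a 51.4 kg subject).

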