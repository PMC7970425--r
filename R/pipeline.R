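#' Default run configuration
#'
#' All thresholds of the analysis surfaced as named keys with their
#' standard defaults: rare-OTU rules (10; 5 in 50% of samples),
#' scale-free fit target 0.8, minimum module size 20, log10 LDA
#' threshold 2, significance level 0.05.
#'
#' @param otus,traits input TSV paths; when `NULL` a synthetic
#'   dataset at the default preset is generated from `seed`.
#' @param outdir output directory.
#' @param seed integer master seed for every stochastic stage.
#' @param overrides named list merged over the defaults (nested lists
#'   merge shallowly per stage).
#' @return nested configuration list.
#' @export
defaultConfig <- function(otus = NULL, traits = NULL, outdir = "micronet_out",
                          seed = 1, overrides = list()) {
  cfg <- list(
    input = list(otus = otus, traits = traits),
    outdir = outdir, seed = seed,
    filter = list(min_count_everywhere = 10, min_count_prevalence = 5,
                  prevalence_frac = 0.5),
    transform = list(pseudocount = NULL),
    diversity = list(n_perm = 999, nmds_k = 2, nmds_starts = 20),
    diffabund = list(rank = "otu", alpha = 0.05, min_frac_of_total = 1e-4),
    network = list(powers = 1:20, r2_target = 0.8, min_module_size = 20,
                   deep_split = 2, merge_height = 0.25,
                   scale_quantile = 0.95, method = "pearson",
                   cohesion_min = 1.5),
    traits = list(alpha = 0.05),
    lefse = list(threshold = 2, alpha = 0.05, n_boot = 30,
                 subsample_frac = 2/3))
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], overrides[[nm]])
    else cfg[[nm]] <- overrides[[nm]]
  }
  cfg
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys override [defaultConfig()].
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  defaultConfig(otus = y$input$otus, traits = y$input$traits,
                outdir = y$outdir %||% "micronet_out",
                seed = y$seed %||% 1, overrides = y)
}

.write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         " (partial outputs preserved)", call. = FALSE))
}

#' Run the full co-occurrence network pipeline
#'
#' Executes filter, diversity, differential abundance, consensus
#' network construction, module detection, module-trait consensus
#' screening and the per-module LDA effect-size screen, writing every
#' stage's table plus a run manifest (config, package version, output
#' checksums) and a markdown report. Outputs are a pure function of
#' (inputs, config, seed); re-running with the same manifest
#' reproduces byte-identical files.
#'
#' @param config configuration list from [defaultConfig()] or
#'   [readRunConfig()].
#' @return invisibly, a list with the main in-memory results
#'   (`otus`, `modules`, `networks`, `trait_networks`, `lefse`,
#'   `diffabund`, `diversity`, `manifest_path`).
#' @export
runPipeline <- function(config = defaultConfig()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- config$outdir
  seed <- config$seed
  files <- character(0)

  synth <- NULL
  oe <- .stage("input", {
    if (is.null(config$input$otus)) {
      synth <- simulatePairedMicrobiome(seed = seed)
      synth@otus
    } else readOtuTable(config$input$otus)
  })
  traits <- .stage("input", {
    if (is.null(config$input$traits)) {
      if (is.null(synth)) NULL else synth@traits
    } else readTraitTable(config$input$traits)
  })

  oe <- .stage("filter", do.call(filterRareOtus, c(list(oe), config$filter)))
  rep <- filterReport(oe)
  files <- c(files, .write_tsv(data.frame(
    n_input = rep@nInput, n_removed_rule1 = rep@nRemovedRule1,
    n_removed_rule2 = rep@nRemovedRule2,
    n_removed_samples = rep@nRemovedSamples,
    n_surviving = length(rep@survivingIds)), out, "filter_report.tsv"))

  div <- .stage("diversity", {
    cnt <- otuCounts(oe)
    alpha <- data.frame(
      sample = colnames(cnt),
      subject = sampleSubject(oe), condition = sampleCondition(oe),
      shannon = apply(cnt, 2, shannonIndex),
      chao1 = apply(cnt, 2, chao1),
      richness = apply(cnt, 2, otuRichness))
    bc <- brayCurtisMatrix(relativeAbundance(oe))
    nmds <- runNMDS(bc, k = config$diversity$nmds_k,
                    n_starts = config$diversity$nmds_starts,
                    seed = seed + 11)
    perm <- runPermanova(bc, sampleCondition(oe),
                         n_perm = config$diversity$n_perm,
                         seed = seed + 12, strata = sampleSubject(oe))
    files <- c(files, .write_tsv(alpha, out, "alpha_diversity.tsv"),
      .write_tsv(data.frame(sample = rownames(nmds$coordinates),
                            nmds$coordinates), out, "nmds_coords.tsv"),
      .write_tsv(data.frame(pseudo_F = perm$pseudo_F, R2 = perm$R2,
                            p = perm$p_value,
                            stress = nmds$stress), out, "permanova.tsv"))
    list(alpha = alpha, nmds = nmds, permanova = perm)
  })

  da <- .stage("diffabund", {
    da <- do.call(differentialAbundance, c(list(oe), config$diffabund))
    da$percent_change_display <- roundHalfAway(da$percent_change)
    files <- c(files, .write_tsv(da, out, "diffabund.tsv"))
    da
  })

  netres <- .stage("network", {
    relab <- relativeAbundance(oe)
    xs <- transformForNetwork(relab, config$transform$pseudocount)
    cond <- sampleCondition(oe)
    split_x <- function(cd) {
      m <- xs[cond == cd, , drop = FALSE]
      rownames(m) <- sampleSubject(oe)[cond == cd]
      m[order(rownames(m)), , drop = FALSE]
    }
    x_pl <- split_x("PL"); x_br <- split_x("BR")
    nc <- config$network
    net <- buildConsensusNetwork(x_pl, x_br, powers = nc$powers,
                                 r2_target = nc$r2_target,
                                 method = nc$method,
                                 scale_quantile = nc$scale_quantile)
    mods <- detectModules(net$networks$consensus@tom,
                          x = list(PL = x_pl, BR = x_br),
                          min_module_size = nc$min_module_size,
                          deep_split = nc$deep_split,
                          merge_height = nc$merge_height,
                          cohesion_min = nc$cohesion_min)
    if (!is.null(net$fits))
      files <- c(files, .write_tsv(net$fits, out, "scale_free_fits.tsv"))
    lab <- moduleLabels(mods)
    kme_own <- rep(NA_real_, length(lab))
    if (length(mods@kme)) {
      km <- mods@kme$PL
      own <- match(paste0("ME", lab), colnames(km))
      kme_own <- ifelse(is.na(own), NA_real_,
                        km[cbind(seq_along(lab), own)])
    }
    files <- c(files, .write_tsv(data.frame(
      otu_id = names(lab), module = unname(lab),
      kme_PL = kme_own), out, "modules.tsv"))
    for (cd in names(mods@eigengenes))
      files <- c(files, .write_tsv(data.frame(
        subject = rownames(mods@eigengenes[[cd]]),
        mods@eigengenes[[cd]]), out,
        paste0("eigengenes_", cd, ".tsv")))
    for (cd in names(net$networks)) {
      tm <- net$networks[[cd]]@tom
      files <- c(files, .write_tsv(
        data.frame(otu_id = rownames(tm), round(tm, 8),
                   check.names = FALSE),
        out, paste0("tom_", cd, ".tsv")))
    }
    list(net = net, modules = mods, x = list(PL = x_pl, BR = x_br))
  })

  tn <- .stage("module_traits", {
    if (is.null(traits)) stop("no trait table provided")
    mods <- netres$modules
    net_pl <- eigengeneTraitCorrelation(moduleEigengenes(mods, "PL"),
                                        traits, "PL")
    net_br <- eigengeneTraitCorrelation(moduleEigengenes(mods, "BR"),
                                        traits, "BR")
    cons <- consensusCorrelation(net_pl, net_br)
    for (nm in c("PL", "BR", "consensus")) {
      net <- switch(nm, PL = net_pl, BR = net_br, consensus = cons)
      files <- c(files, .write_tsv(moduleTraitLong(net), out,
                                    paste0("module_traits_", nm, ".tsv")))
    }
    sig <- significantCells(cons, alpha = config$traits$alpha)
    files <- c(files, .write_tsv(sig, out, "consensus_significant.tsv"))
    list(PL = net_pl, BR = net_br, consensus = cons, significant = sig)
  })

  lef <- .stage("lefse", {
    lc <- config$lefse
    lef <- lefseModules(oe, moduleLabels(netres$modules),
                        alpha = lc$alpha, threshold = lc$threshold,
                        n_boot = lc$n_boot,
                        subsample_frac = lc$subsample_frac,
                        seed = seed + 31)
    files <- c(files, .write_tsv(lef@table, out, "lefse.tsv"))
    lef
  })

  .stage("report", {
    sz <- moduleSizes(netres$modules)
    drv <- moduleDrivers(lef)
    lines <- c(
      "# Co-occurrence network pipeline report", "",
      sprintf("Soft-threshold power beta = %d", netres$net$beta), "",
      "## Module sizes", "",
      sprintf("- module %s: %d OTUs", names(sz), as.integer(sz)), "",
      "## Module drivers (|log10 LDA| >= threshold)", "",
      unlist(lapply(names(drv), function(m) {
        if (!nrow(drv[[m]])) sprintf("- %s: none", m)
        else sprintf("- %s: %s", m,
                     paste(sprintf("%s (%.2f)", drv[[m]]$otu_id,
                                   drv[[m]]$lda_effect), collapse = ", "))
      })), "",
      "## Significant consensus module-trait correlations", "",
      if (nrow(tn$significant))
        sprintf("- %s ~ %s: r = %.3f, p = %.4f", tn$significant$module,
                tn$significant$trait, tn$significant$r, tn$significant$p)
      else "- none")
    writeLines(lines, file.path(out, "report.md"))
    files <- c(files, file.path(out, "report.md"))
  })

  manifest <- list(
    config = rapply(config, function(z) z, how = "replace"),
    package_version = as.character(packageVersion("micronet")),
    checksums = as.list(tools::md5sum(sort(unique(files)))))
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(otus = oe, traits = traits, synthetic = synth,
                 diversity = div, diffabund = da,
                 networks = netres$net$networks, beta = netres$net$beta,
                 modules = netres$modules, trait_networks = tn,
                 lefse = lef, manifest_path = manifest_path,
                 files = sort(unique(files))))
}
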