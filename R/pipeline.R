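# End-to-end orchestration on synthetic (or user-supplied) data: simulate,
# correlate, architecture, DBP enrichment, bridging, DMC, DE and
# projection, with per-stage TSV outputs and a manifest.

#' Default pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Named list understood by [runPipeline()].
#' @export
defaultPipelineConfig <- function(outdir = tempfile("methylTAD_"),
                                  seed = 1L) {
  list(outdir = outdir, seed = as.integer(seed),
       rhoThreshold = 0.5, fdrThreshold = 0.05,
       proximalBp = 2000L, longBp = 500000L,
       zThreshold = 10, mcIterations = 1000L,
       samPermutations = 1000L,
       genome = defaultGenomeConfig(),
       cohort = defaultCohortDesign(),
       series = defaultSeriesConfig(),
       overwrite = FALSE)
}

.stageSeed <- function(seed, k) (as.integer(seed) * 131L + k) %% 2147483647L

.writeTsv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t")
  path
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate, correlate, architecture, DBP enrichment, bridging,
#' DMC, DE and projection in order, writing per-stage TSV outputs, and a
#' `manifest.tsv` recording thresholds, seeds, package version and file
#' checksums.  Stages whose output files already exist are skipped unless
#' `config$overwrite` is set.
#'
#' @param config List from [defaultPipelineConfig()], possibly modified.
#'   YAML configuration files can be loaded with [yaml::read_yaml] and
#'   merged over the defaults.
#' @return Invisibly, a list with the in-memory stage results and the
#'   output paths.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  res <- list()
  stage <- function(name, files, fun) {
    files <- file.path(cfg$outdir, files)
    if (!cfg$overwrite && all(file.exists(files))) {
      message("stage ", name, ": cached, skipping")
      return(files)
    }
    tryCatch(fun(files),
             error = function(e) stop("stage ", name, " failed: ",
                                      conditionMessage(e), call. = FALSE))
    files
  }

  ## simulate
  genome <- generateGenome(cfg$genome, seed = .stageSeed(cfg$seed, 1L))
  cohort <- generateCohort(genome, cfg$cohort,
                           seed = .stageSeed(cfg$seed, 2L))
  series <- generateDifferentiationSeries(genome, cfg$series,
                                          seed = .stageSeed(cfg$seed, 3L))
  res$genome <- genome; res$cohort <- cohort; res$series <- series
  paths$simulate <- stage("simulate",
    c("tads.bed", "repeats.bed", "enhancers.bed", "sites.tsv",
      "expression.tsv", "samples.tsv", "truth_pairs.tsv"),
    function(f) {
      writeBed(tadRanges(genome@tads), f[1],
               extraCols = c("tad_id", "origin"))
      writeBed(genome@repeats, f[2],
               extraCols = c("family", "subfamily", "divergence"))
      writeBed(genome@enhancers, f[3])
      writeMethylationTable(cohortMethylation(cohort), f[4], f[6])
      writeExpressionMatrix(cohortExpression(cohort), f[5], f[6])
      .writeTsv(groundTruth(cohort)$pairs, f[7])
    })

  ## correlate
  filt <- filterFeatures(cohortExpression(cohort),
                         cohortMethylation(cohort))
  corr <- correlateWithinTads(filt$expr, filt$meth, genome@tads,
                              genome@genes,
                              rhoThreshold = cfg$rhoThreshold,
                              fdrThreshold = cfg$fdrThreshold,
                              proximalBp = cfg$proximalBp,
                              longBp = cfg$longBp)
  res$correlations <- corr
  paths$correlate <- stage("correlate", "correlations.tsv",
                           function(f) .writeTsv(corr, f))

  ## architecture
  arch <- computeArchitecture(genome@genes, genome@repeats,
                              conservation = genome@conservation,
                              gc = genome@gcTrack)
  res$architecture <- arch
  sigGenes <- unique(corr$gene_id[corr$significant])
  bg <- unique(corr$gene_id)
  if (length(sigGenes) >= 5) {
    dens <- setNames(arch$density_MIR_intron, arch$gene_id)
    res$mirShift <- ecdfShiftTest(dens[sigGenes], dens[bg])
  }
  sites <- SummarizedExperiment::rowRanges(filt$meth)
  sigSites <- sites[sites$site_id %in%
                      unique(corr$site_id[corr$significant])]
  res$siteTests <- siteArchitectureTests(
    sigSites, sites, genome@repeats,
    conservation = genome@conservation, enhancers = genome@enhancers)
  paths$architecture <- stage("architecture", "architecture.tsv",
                              function(f) .writeTsv(arch, f))

  ## DBP Monte-Carlo enrichment over the gene space
  bodies <- geneBodies(genome@genes)
  space <- bodies[bodies$gene_id %in% bg]
  sigBodies <- bodies[bodies$gene_id %in% sigGenes]
  mc <- lapply(names(genome@peaks), function(d)
    mcEnrichmentZ(genome@peaks[[d]], sigBodies, space,
                  nIter = cfg$mcIterations,
                  seed = .stageSeed(cfg$seed, 4L), dbp = d))
  mcDf <- do.call(rbind, lapply(mc, function(r)
    data.frame(dbp = r@dbp, observed = r@observed, null_mean = r@nullMean,
               null_sd = r@nullSd, z = r@z, degenerate = r@degenerate)))
  res$dbpEnrichment <- mcDf
  paths$enrich <- stage("enrich-dbp", "dbp_enrichment.tsv",
                        function(f) .writeTsv(mcDf, f))

  ## PPI bridging
  map <- bindingMap(genome@peaks, sites, genome@genes, genome@repeats)
  sigPairs <- corr[corr$significant, c("gene_id", "site_id")]
  res$bridgeGene <- bridgeEnrichment(sigPairs, map, genome@ppi, "gene")
  res$bridgeMir <- bridgeEnrichment(sigPairs, map, genome@ppi, "mir")
  paths$bridge <- stage("bridge", c("bridge_gene.tsv", "bridge_mir.tsv"),
                        function(f) {
                          .writeTsv(res$bridgeGene, f[1])
                          .writeTsv(res$bridgeMir, f[2])
                        })

  ## DMC per repeat family
  res$dmc <- lapply(setNames(nm = c("MIR", "Alu", "L1")), function(fam)
    tryCatch(dmcByRepeatFamily(filt$meth, c("DNMT3A", "IDH"),
                               genome@repeats, fam,
                               nPerm = cfg$samPermutations,
                               seed = .stageSeed(cfg$seed, 5L)),
             error = function(e) NULL))
  dmcDf <- do.call(rbind, lapply(names(res$dmc), function(fam) {
    r <- res$dmc[[fam]]
    if (is.null(r)) return(NULL)
    data.frame(family = fam, n_tested = r$nTested, n_dmc = r$nDmc,
               pct_dmc = r$pctDmc, n_hyper = r$nHyper, n_hypo = r$nHypo)
  }))
  paths$dmc <- stage("dmc", "dmc_summary.tsv",
                     function(f) .writeTsv(dmcDf, f))

  ## DE between the extreme genotype groups
  res$de <- deTwoClass(cohortExpression(cohort), c("DNMT3A", "IDH"),
                       nPerm = cfg$samPermutations, minMedian = 0,
                       seed = .stageSeed(cfg$seed, 6L))
  paths$de <- stage("de", "de_genes.tsv", function(f)
    .writeTsv(res$de$sam@significant, f))

  ## projection onto the differentiation series
  refRank <- rankNormalize(series)
  qryRank <- rankNormalize(cohortExpression(cohort))
  proj <- fitAndProject(refRank, qryRank)
  prof <- distanceProfile(refRank, qryRank)
  res$projection <- proj
  grpQ <- SummarizedExperiment::colData(cohortExpression(cohort))$group
  if (sum(grpQ == "DOUBLE") >= 2 && sum(grpQ == "DNMT3A") >= 2) {
    keep <- grpQ %in% c("DNMT3A", "DOUBLE")
    res$distanceSam <- distanceSamAndEnrichment(
      list(centered = prof$centered[, keep]),
      grpQ[keep],
      SummarizedExperiment::colData(series)$group,
      contrast = c("DNMT3A", "DOUBLE"),
      nPerm = cfg$samPermutations, seed = .stageSeed(cfg$seed, 7L))
  }
  paths$project <- stage("project",
                         c("ref_scores.tsv", "query_scores.tsv",
                           "distances.tsv"),
                         function(f) {
                           .writeTsv(proj@refScores, f[1])
                           .writeTsv(proj@queryScores, f[2])
                           .writeTsv(prof$centered, f[3])
                         })

  ## manifest with checksums of every emitted file
  allFiles <- unlist(paths)
  allFiles <- allFiles[file.exists(allFiles)]
  manifest <- data.frame(
    file = basename(allFiles),
    md5 = unname(tools::md5sum(allFiles)),
    stringsAsFactors = FALSE)
  settings <- data.frame(
    file = c("setting:seed", "setting:rhoThreshold",
             "setting:fdrThreshold", "setting:proximalBp",
             "setting:longBp", "setting:zThreshold",
             "setting:samPermutations", "setting:version"),
    md5 = c(cfg$seed, cfg$rhoThreshold, cfg$fdrThreshold, cfg$proximalBp,
            cfg$longBp, cfg$zThreshold, cfg$samPermutations,
            as.character(utils::packageVersion("methylTAD"))),
    stringsAsFactors = FALSE)
  .writeTsv(rbind(settings, manifest),
            file.path(cfg$outdir, "manifest.tsv"))
  invisible(list(results = res, paths = paths, outdir = cfg$outdir))
}
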