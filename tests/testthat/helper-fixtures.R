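# Shared fixtures, built once per test run and cached in this environment.
# The "small" genome keeps unit tests fast; acceptance checks build the
# full-size study design themselves.

.fixtures <- new.env(parent = emptyenv())

smallGenomeConfig <- function() {
  cfg <- defaultGenomeConfig()
  cfg$chromSizes <- c(chrA = 6000000L, chrB = 6000000L)
  cfg$nGenes <- 80L
  cfg$nSites <- 800L
  cfg$nEnhancers <- 120L
  cfg$nIslands <- 15L
  cfg$intergenicRepeatsPerMb <- 20
  cfg$peaksPerDbp <- 150L
  cfg
}

smallGenome <- function() {
  if (is.null(.fixtures$genome))
    .fixtures$genome <- generateGenome(smallGenomeConfig(), seed = 11L)
  .fixtures$genome
}

smallCohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generateCohort(smallGenome(), seed = 11L)
  .fixtures$cohort
}

# Filtered matrices + discovery table on the small fixture.
smallDiscovery <- function() {
  if (is.null(.fixtures$discovery)) {
    g <- smallGenome()
    co <- smallCohort()
    filt <- filterFeatures(cohortExpression(co), cohortMethylation(co))
    corr <- correlateWithinTads(filt$expr, filt$meth, g@tads, g@genes)
    .fixtures$discovery <- list(filt = filt, corr = corr)
  }
  .fixtures$discovery
}

smallSeries <- function() {
  if (is.null(.fixtures$series))
    .fixtures$series <- generateDifferentiationSeries(smallGenome(),
                                                      seed = 11L)
  .fixtures$series
}

# Study-scale fixtures (default generator settings: 200 genes, 2,000 CpGs,
# 36 samples), cached across acceptance checks.

studyGenome <- function() {
  if (is.null(.fixtures$studyGenome))
    .fixtures$studyGenome <- generateGenome(seed = 1L)
  .fixtures$studyGenome
}

# Discovery run for one cohort seed: filtered matrices, correlation table
# and ground truth.  Results cached per seed.
studyDiscovery <- function(seed) {
  key <- paste0("study_", seed)
  if (is.null(.fixtures[[key]])) {
    g <- studyGenome()
    co <- generateCohort(g, seed = seed)
    filt <- filterFeatures(cohortExpression(co), cohortMethylation(co))
    corr <- correlateWithinTads(filt$expr, filt$meth, g@tads, g@genes)
    .fixtures[[key]] <- list(filt = filt, corr = corr,
                             truth = groundTruth(co))
  }
  .fixtures[[key]]
}

studySeries <- function() {
  if (is.null(.fixtures$studySeries))
    .fixtures$studySeries <- generateDifferentiationSeries(studyGenome(),
                                                           seed = 1L)
  .fixtures$studySeries
}

# Fraction of reported (significant) pairs that are planted nulls.
falseDiscoveryProportion <- function(corr, truth) {
  rep_ <- paste(corr$gene_id, corr$site_id)[corr$significant]
  if (!length(rep_)) return(0)
  planted <- paste(truth$pairs$gene_id, truth$pairs$site_id)
  mean(!rep_ %in% planted)
}

# A hand-sized partition: chr1 of 10 kb with called TADs [1,3000] and
# [3501,7000] plus complement gaps (boundaries at 3000/3001 etc.).
toyPartition <- function() {
  buildTadPartition(
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(c(1, 3501), c(3000, 7000))),
    c(chr1 = 10000L))
}

# Expression/methylation pair with perfectly monotone relationships.
toyMonotone <- function() {
  n <- 8
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(500, 900),
                                                           width = 1),
                                  site_id = c("sA", "sB"))
  m <- rbind(sA = seq(0.1, 0.8, length.out = n),
             sB = seq(0.8, 0.1, length.out = n))
  meth <- MethylationSet(sites, m,
                         cov = matrix(50L, 2, n),
                         group = rep(c("DNMT3A", "IDH"), each = n / 2))
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 2001),
                                                        c(200, 2200)),
                               gene_id = c("gU", "gD"))
  gm <- GeneModels(ex)
  e <- rbind(gU = 2^seq(1, 4, length.out = n),
             gD = 2^seq(4, 1, length.out = n))
  colnames(e) <- colnames(m) <- sprintf("S%02d", seq_len(n))
  expr <- ExpressionMatrix(e, group = rep(c("DNMT3A", "IDH"), each = n / 2))
  part <- buildTadPartition(GenomicRanges::GRanges(), c(chr1 = 10000L))
  list(expr = expr, meth = meth, genes = gm, partition = part)
}
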