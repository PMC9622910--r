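# Generator contracts: determinism, bounds, planted architecture and the
# planted-pair ground truth.

test_that("generators are deterministic for a fixed (config, seed)", {
  cfg <- smallGenomeConfig()
  cfg$chromSizes <- c(c1 = 3000000L)
  cfg$nGenes <- 25L
  cfg$nSites <- 150L
  cfg$nIslands <- 4L
  cfg$nEnhancers <- 30L
  g1 <- generateGenome(cfg, seed = 5L)
  g2 <- generateGenome(cfg, seed = 5L)
  expect_identical(as.character(g1@repeatSeqs), as.character(g2@repeatSeqs))
  expect_equal(IRanges::ranges(g1@repeats), IRanges::ranges(g2@repeats))
  expect_equal(IRanges::ranges(g1@sites), IRanges::ranges(g2@sites))
  c1 <- generateCohort(g1, seed = 9L)
  c2 <- generateCohort(g1, seed = 9L)
  expect_identical(
    SummarizedExperiment::assay(cohortMethylation(c1), "meth"),
    SummarizedExperiment::assay(cohortMethylation(c2), "meth"))
  expect_identical(
    SummarizedExperiment::assay(cohortExpression(c1), "expr"),
    SummarizedExperiment::assay(cohortExpression(c2), "expr"))
  expect_identical(groundTruth(c1)$pairs, groundTruth(c2)$pairs)
  # a different seed changes the data
  c3 <- generateCohort(g1, seed = 10L)
  expect_false(identical(
    SummarizedExperiment::assay(cohortMethylation(c1), "meth"),
    SummarizedExperiment::assay(cohortMethylation(c3), "meth")))
})

test_that("infeasible gene counts raise a capacity error", {
  cfg <- defaultGenomeConfig()
  cfg$chromSizes <- c(c1 = 1000000L)
  cfg$nGenes <- 10000L
  expect_error(generateGenome(cfg, seed = 1L), "capacity error")
})

test_that("all synthetic annotations are in bounds and architecture classes differ", {
  g <- smallGenome()
  sizes <- g@chromSizes
  for (gr in list(geneBodies(g@genes), g@repeats, g@sites, g@enhancers,
                  g@islands, unlist(g@peaks))) {
    chr <- as.character(GenomeInfoDb::seqnames(gr))
    expect_true(all(chr %in% names(sizes)))
    expect_true(all(BiocGenerics::start(gr) >= 1))
    expect_true(all(BiocGenerics::end(gr) <= sizes[chr]))
  }
  arch <- computeArchitecture(g@genes, g@repeats,
                              conservation = g@conservation,
                              gc = g@gcTrack)
  cls <- g@geneClass[arch$gene_id]
  mir <- arch$density_MIR_intron
  expect_gt(mean(mir[cls == "regulatable"], na.rm = TRUE),
            mean(mir[cls == "independent"], na.rm = TRUE))
  expect_gt(mean(arch$gc_intron[cls == "regulatable"], na.rm = TRUE),
            mean(arch$gc_intron[cls == "independent"], na.rm = TRUE))
  expect_lt(mean(arch$cons_intron[cls == "regulatable"], na.rm = TRUE),
            mean(arch$cons_intron[cls == "independent"], na.rm = TRUE))
  # a usable MIR-zero pool exists
  mz <- g@config$mirZeroGenes
  expect_true(length(mz) > 5)
  expect_true(all(mir[match(mz, arch$gene_id)] == 0 |
                    is.na(mir[match(mz, arch$gene_id)])))
  # configured fractions of sites sit on MIRs and enhancers
  expect_gt(mean(g@sites$on_mir), 0.1)
  expect_gt(mean(g@sites$on_enhancer), 0.1)
})

test_that("every planted pair's gene and site share a TAD and groups are as configured", {
  co <- smallCohort()
  g <- smallGenome()
  truth <- groundTruth(co)
  expect_gt(nrow(truth$pairs), 0)
  part <- tadRanges(g@tads)
  bodies <- geneBodies(g@genes)
  sites <- g@sites
  gh <- GenomicRanges::findOverlaps(bodies, part)
  sh <- GenomicRanges::findOverlaps(sites, part)
  geneTads <- split(S4Vectors::subjectHits(gh),
                    bodies$gene_id[S4Vectors::queryHits(gh)])
  siteTads <- split(S4Vectors::subjectHits(sh),
                    sites$site_id[S4Vectors::queryHits(sh)])
  shareTad <- mapply(function(a, b) length(intersect(a, b)) > 0,
                     geneTads[truth$pairs$gene_id],
                     siteTads[truth$pairs$site_id])
  expect_true(all(shareTad))
  grp <- table(SummarizedExperiment::colData(cohortMethylation(co))$group)
  expect_equal(unname(grp[c("DNMT3A", "IDH", "DOUBLE")]),
               unname(table(c(rep(1, 16), rep(2, 9), rep(3, 11)))))
  # planted effect signs are overwhelmingly negative
  perGene <- unique(truth$pairs[, c("gene_id", "beta")])
  expect_gt(mean(perGene$beta < 0), 0.9)
  # non-dropout coverage respects the floor
  cv <- SummarizedExperiment::assay(cohortMethylation(co), "cov")
  expect_gt(mean(apply(cv, 1, min) >= 10), 0.9)
})

test_that("differentiation series has 211 samples over 15 types with recorded DE truth", {
  se <- smallSeries()
  expect_equal(ncol(se), 211L)
  grp <- SummarizedExperiment::colData(se)$group
  expect_equal(length(unique(grp)), 15L)
  deSets <- S4Vectors::metadata(se)$deSets
  expect_equal(length(deSets), 14L)  # every non-root type
  expect_true(all(vapply(deSets, function(x)
    length(x$up) > 0 && length(x$down) > 0, logical(1))))
  # upregulated genes are biased toward the regulatable class
  g <- smallGenome()
  upAll <- unlist(lapply(deSets, `[[`, "up"))
  downAll <- unlist(lapply(deSets, `[[`, "down"))
  expect_gt(mean(g@geneClass[upAll] == "regulatable"),
            mean(g@geneClass[downAll] == "regulatable"))
  # null design: no DE planted
  cfg <- defaultSeriesConfig()
  cfg$deFraction <- 0
  se0 <- generateDifferentiationSeries(g, cfg, seed = 2L)
  expect_true(all(vapply(S4Vectors::metadata(se0)$deSets, function(x)
    length(x$up) + length(x$down) == 0, logical(1))))
  expect_error(generateDifferentiationSeries(
    g, utils::modifyList(defaultSeriesConfig(),
                         list(cellTypes = "HSC")), seed = 1L),
    "design error")
})

test_that("fitted correlation signs recover planted effect signs", {
  d <- smallDiscovery()
  truth <- groundTruth(smallCohort())
  m <- merge(d$corr[d$corr$significant, ], truth$pairs,
             by = c("gene_id", "site_id"))
  expect_gt(nrow(m), 50)
  expect_gt(mean(sign(m$rho) == sign(m$beta)), 0.95)
})
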