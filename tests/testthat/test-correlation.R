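# Filtering rules, Spearman discovery, island aggregation, W sets,
# shared-site gene pairs and cohort comparison.

test_that("coverage, probe and expression filters follow the stated rules", {
  n <- 36
  sites <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100, 200, 300), width = 1),
    site_id = c("ok", "lowcov", "ok2"))
  m <- matrix(0.5, 3, n)
  cv <- matrix(50L, 3, n)
  cv[2, 17] <- 9L  # coverage 9 in one of 36 samples -> dropped
  meth <- MethylationSet(sites, m, cv, group = rep("DNMT3A", n))
  e <- matrix(rep(seq(100, 1, length.out = 100), n), 100, n,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  expr <- ExpressionMatrix(e, group = rep("DNMT3A", n))
  out <- filterFeatures(expr, meth)
  expect_equal(rownames(out$meth), c("ok", "ok2"))
  expect_equal(nrow(out$expr), 50L)  # 100 genes, top-50% rule
  expect_equal(rownames(out$expr), sprintf("g%03d", 1:50))

  # probe-level: all values <= 0.3 -> dropped; > 0.3 in > 3% kept
  mp <- rbind(allLow = rep(0.30, n),
              some = c(rep(0.9, 2), rep(0.1, n - 2)))
  probes <- MethylationSet(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 2), width = 1),
                           site_id = c("allLow", "some")),
    mp, NULL, group = rep("WT", n))
  outP <- filterFeatures(expr, probes)
  expect_equal(rownames(outP$meth), "some")

  # non-protein-coding genes never enter the expression ranking
  exprB <- ExpressionMatrix(e, group = rep("DNMT3A", n),
                            biotype = rep(c("protein-coding", "non-coding"),
                                          50))
  outB <- filterFeatures(exprB, meth)
  expect_equal(nrow(outB$expr), 25L)
  expect_error(filterFeatures(expr, meth, minCoverage = 100L),
               "no methylation sites")
})

test_that("monotone relationships give rho of exactly +1 and -1", {
  toy <- toyMonotone()
  corr <- correlateWithinTads(toy$expr, toy$meth, toy$partition, toy$genes)
  get <- function(g, s) corr$rho[corr$gene_id == g & corr$site_id == s]
  expect_equal(get("gU", "sA"), 1)
  expect_equal(get("gU", "sB"), -1)
  expect_equal(get("gD", "sA"), -1)
  expect_equal(get("gD", "sB"), 1)
  # distances and bins are populated and consistent
  expect_true(all(corr$bin == classifyDistance(corr$distance,
                                               corr$within_body)))
  expect_error(correlateWithinTads(toy$expr[, 1:2], toy$meth[, 1:2],
                                   toy$partition, toy$genes),
               "at least 3 shared samples")
})

test_that("vectorised Spearman matches cor.test pair by pair", {
  d <- smallDiscovery()
  corr <- d$corr
  E <- SummarizedExperiment::assay(d$filt$expr, "expr")
  M <- SummarizedExperiment::assay(d$filt$meth, "meth")
  set.seed(3)
  idx <- sample.int(nrow(corr), 25)
  for (i in idx) {
    ct <- suppressWarnings(cor.test(E[corr$gene_id[i], ],
                                    M[corr$site_id[i], ],
                                    method = "spearman"))
    expect_equal(corr$rho[i], unname(ct$estimate), tolerance = 1e-10)
  }
  # t-approximation p-values agree with the analytic formula
  i <- idx[1]
  n <- ncol(E)
  tt <- corr$rho[i] * sqrt((n - 2) / (1 - corr$rho[i]^2))
  expect_equal(corr$p[i], 2 * pt(-abs(tt), n - 2))
  # zero-variance pairs are skipped and counted
  E2 <- E; E2[1, ] <- 5
  expr2 <- ExpressionMatrix(E2,
    group = SummarizedExperiment::colData(d$filt$expr)$group)
  g <- smallGenome()
  corr2 <- correlateWithinTads(expr2, d$filt$meth, g@tads, g@genes)
  expect_gt(attr(corr2, "nSkipped"), 0)
  expect_false(rownames(E2)[1] %in% corr2$gene_id)
})

test_that("significance demands both the rho and the FDR threshold", {
  corr <- smallDiscovery()$corr
  expect_true(all(abs(corr$rho[corr$significant]) > 0.5))
  expect_true(all(corr$q[corr$significant] < 0.05))
  notSig <- !corr$significant
  expect_true(all(abs(corr$rho[notSig]) <= 0.5 | corr$q[notSig] >= 0.05))
  # bin counts partition the significant records
  expect_equal(sum(table(corr$bin[corr$significant])),
               sum(corr$significant))
})

test_that("island aggregation averages member sites and drops empty islands", {
  sites <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100, 150, 900), width = 1),
    site_id = c("s1", "s2", "s3"))
  m <- matrix(c(0.2, 0.4, 0.9), 3, 2)
  meth <- MethylationSet(sites, m, matrix(50L, 3, 2),
                         group = c("DNMT3A", "IDH"))
  islands <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(50, 800, 5000), c(200, 950, 5100)),
    island_id = c("i1", "i2", "i3"))
  agg <- islandMeanMethylation(meth, islands)
  a <- SummarizedExperiment::assay(agg, "meth")
  expect_equal(nrow(agg), 2L)            # empty island dropped
  expect_equal(unname(a["i1", 1]), 0.3)  # mean of 0.2 and 0.4
  expect_equal(unname(a["i2", 1]), 0.9)  # single-site island: identity
})

test_that("significant islands usually contain a significant member site", {
  g <- smallGenome()
  d <- smallDiscovery()
  agg <- islandMeanMethylation(d$filt$meth, g@islands)
  corrI <- correlateWithinTads(d$filt$expr, agg, g@tads, g@genes)
  sigI <- unique(corrI$site_id[corrI$significant])
  if (length(sigI) >= 3) {
    sigSiteIds <- unique(d$corr$site_id[d$corr$significant])
    sigSites <- SummarizedExperiment::rowRanges(d$filt$meth)
    sigSites <- sigSites[sigSites$site_id %in% sigSiteIds]
    isl <- SummarizedExperiment::rowRanges(agg)
    contains <- GenomicRanges::countOverlaps(
      isl[isl$site_id %in% sigI], sigSites) > 0
    # report-style containment check: a clear majority, not a constant
    expect_gt(mean(contains), 0.5)
  } else {
    succeed("too few significant islands to assess containment")
  }
})

test_that("W sets take the weakest-correlated genes with deterministic ties", {
  tbl <- data.frame(
    gene_id = rep(c("gE", "gD", "gC", "gB", "gA"), each = 2),
    site_id = paste0("s", 1:10),
    rho = c(0.5, 0.1, 0.4, 0.2, 0.3, 0.1, 0.2, 0.05, 0.1, 0.02),
    bin = "proximal", stringsAsFactors = FALSE)
  # per-gene max |rho|: gE .5, gD .4, gC .3, gB .2, gA .1
  expect_equal(weakestGeneSet(tbl, n = 2, bin = "proximal"),
               c("gA", "gB"))
  expect_warning(all5 <- weakestGeneSet(tbl, n = 10, bin = "proximal"),
                 "only 5 genes")
  expect_equal(sort(all5), c("gA", "gB", "gC", "gD", "gE"))
  # a zero-correlation gene precedes any non-zero one
  tbl2 <- rbind(tbl, data.frame(gene_id = "gZ", site_id = "s11", rho = 0,
                                bin = "proximal"))
  expect_true("gZ" %in% weakestGeneSet(tbl2, n = 1, bin = "proximal"))
  # ranking for enrichment input is the reverse ordering
  rk <- rankGenesByCorrelation(tbl, bin = "proximal")
  expect_equal(rk$gene_id[1], "gE")
  expect_equal(rk$score[1], 0.5)
})

test_that("shared-site gene pairs follow the closed-form hypergeometric", {
  mkTbl <- function(sig2) {
    rbind(
      data.frame(gene_id = "g1", site_id = sprintf("s%02d", 1:10),
                 significant = c(rep(TRUE, 5), rep(FALSE, 5)),
                 stringsAsFactors = FALSE),
      data.frame(gene_id = "g2", site_id = sprintf("s%02d", 1:10),
                 significant = sig2, stringsAsFactors = FALSE))
  }
  # identical significant sets of 5 among 10 shared sites: p = 1/252
  out <- sharedSiteGenePairs(mkTbl(c(rep(TRUE, 5), rep(FALSE, 5))))
  expect_equal(out$shared_significant, 5)
  expect_equal(out$p, 1 / choose(10, 5), tolerance = 1e-12)
  # disjoint significant sets: observed 0, fold 0, p = 1
  out0 <- sharedSiteGenePairs(mkTbl(c(rep(FALSE, 5), rep(TRUE, 5))))
  expect_equal(out0$shared_significant, 0)
  expect_equal(out0$fold, 0)
  expect_equal(out0$p, 1)
})

test_that("random significant subsets give fold about 1 on average", {
  set.seed(42)
  folds <- replicate(400, {
    sig2 <- seq_len(20) %in% sample.int(20, 8)
    tbl <- rbind(
      data.frame(gene_id = "g1", site_id = sprintf("s%02d", 1:20),
                 significant = seq_len(20) <= 10),
      data.frame(gene_id = "g2", site_id = sprintf("s%02d", 1:20),
                 significant = sig2))
    sharedSiteGenePairs(tbl)$fold
  })
  expect_equal(mean(folds), 1, tolerance = 0.1)
})

test_that("coefficients drop in a WT cohort without the planted link", {
  g <- smallGenome()
  d <- smallDiscovery()
  sig <- d$corr[d$corr$significant, ]
  # identical alternate cohort: no shift, p = 0.5
  same <- compareCohortCoefficients(sig, d$filt$expr, d$filt$meth)
  expect_equal(same$p, 0.5)
  expect_equal(same$nExcluded, 0)
  # WT-only cohort (wtBeta = 0): planted links vanish
  des <- defaultCohortDesign()
  des$groupSizes <- c(DNMT3A = 0L, IDH = 0L, DOUBLE = 0L, WT = 24L)
  wt <- generateCohort(g, des, seed = 21L)
  cmp <- compareCohortCoefficients(sig, cohortExpression(wt),
                                   cohortMethylation(wt))
  expect_lt(cmp$p, 1e-4)
  expect_gt(cmp$meanAbsDiscovery, cmp$meanAbsAlternate)
  expect_error(compareCohortCoefficients(sig[1:5, ], cohortExpression(wt),
                                         cohortMethylation(wt)),
               "fewer than 10 comparable")
})

test_that("negative correlations dominate and concentrate proximally", {
  corr <- smallDiscovery()$corr
  sig <- corr[corr$significant, ]
  expect_gt(mean(sig$rho < 0), 0.9)
  pe <- proximalEnrichmentTest(corr, "negative")
  expect_true(is.finite(pe$p))
  expect_gte(pe$observed, 0)
})
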