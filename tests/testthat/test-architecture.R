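# Architecture metrics, ECDF-shift curves, containment enrichment, B-box
# scanning, boundary distances and the MIR-zero matched comparison.

test_that("architecture metrics follow their definitions on a toy gene", {
  gm <- GeneModels(GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1001, 3001), c(1400, 3400)),
    gene_id = "g1"))
  # intron is 1401..3000 (1600 bp); exons 800 bp
  mir <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1401, 3000),
                                family = "MIR")
  gc <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1001, 1401), c(1400, 3000)))
  gc$score <- c(0.5, 0.7)
  arch <- computeArchitecture(gm, mir, gc = gc)
  expect_equal(arch$exonic_length, 800)
  expect_equal(arch$intronic_length, 1600)
  expect_equal(arch$density_MIR_intron, 1)   # intron fully covered
  expect_equal(arch$density_MIR_exon, 0)
  expect_equal(arch$gc_exon, 0.5)
  expect_equal(arch$gc_intron, 0.7)
  # single-exon gene: intronic metrics undefined
  gm1 <- GeneModels(GenomicRanges::GRanges("chr1",
    IRanges::IRanges(501, 900), gene_id = "solo"))
  arch1 <- computeArchitecture(gm1, mir, gc = gc)
  expect_true(is.na(arch1$intronic_length))
  expect_true(is.na(arch1$density_MIR_intron))
})

test_that("ECDF shift curve matches its sign convention and the KS statistic", {
  bg <- 1:100 / 10
  # set drawn exactly at background values: flat curve
  flat <- ecdfShiftTest(bg, bg)
  expect_lt(flat$D, 1e-12)
  # all set values at the background maximum
  top <- ecdfShiftTest(rep(max(bg), 20), bg)
  expect_true(all(top$curve >= 0))
  expect_equal(top$D, 99 / 100)
  # upward shift by a constant: non-negative curve, positive interior
  up <- ecdfShiftTest(bg + 0.05, bg)
  expect_true(all(up$curve >= 0))
  inner <- up$curve[up$grid > min(bg) + 0.5 & up$grid < max(bg) - 0.5]
  expect_gt(max(inner), 0)
  # small sets are flagged
  expect_true(ecdfShiftTest(c(1, 2), bg)$warning)
})

test_that("curve maximum equals ks.test on tie-free data", {
  for (s in 1:5) {
    set.seed(s)
    bg <- rnorm(400)
    st <- rnorm(60, mean = 0.5)
    ours <- ecdfShiftTest(st, bg)
    ref <- suppressWarnings(ks.test(st, ecdf(bg)))
    expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-10)
    expect_lt(abs(ours$p - ref$p.value), 0.02)
  }
})

test_that("containment enrichment reproduces the closed-form hypergeometric", {
  gm <- GeneModels(GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1000, by = 2000, length.out = 10), width = 500),
    gene_id = sprintf("g%02d", 1:10)))
  bodies <- geneBodies(gm)
  # MIRs inside genes 1..5 only
  mir <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(BiocGenerics::start(bodies)[1:5] + 10, width = 50),
    family = "MIR")
  bg <- bodies$gene_id
  res <- containsElementEnrichment(sprintf("g%02d", 1:5), bg, gm, mir,
                                   "MIR")
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$fold, 2)
  # set = background: fold 1
  resAll <- containsElementEnrichment(bg, bg, gm, mir, "MIR")
  expect_equal(resAll$fold, 1)
  # family absent genome-wide: flagged undefined
  resNA <- containsElementEnrichment(bg[1:3], bg, gm, mir, "ERV")
  expect_true(is.na(resNA$fold))
})

test_that("site architecture tests are null at identity and detect planted drivers", {
  g <- smallGenome()
  d <- smallDiscovery()
  sites <- SummarizedExperiment::rowRanges(d$filt$meth)
  idT <- siteArchitectureTests(sites, sites, g@repeats,
                               conservation = g@conservation,
                               enhancers = g@enhancers)
  expect_lt(idT$conservation$D, 1e-12)
  expect_true(all(abs(idT$repeats$fold - 1) < 1e-12))
  expect_equal(idT$enhancers$fold, 1)
  # significant sites are driver-heavy: MIR and enhancer enrichment at
  # the default (study-scale) design
  gS <- studyGenome()
  dS <- studyDiscovery(1)
  sitesS <- SummarizedExperiment::rowRanges(dS$filt$meth)
  sig <- sitesS[sitesS$site_id %in%
                  unique(dS$corr$site_id[dS$corr$significant])]
  st <- siteArchitectureTests(sig, sitesS, gS@repeats,
                              conservation = gS@conservation,
                              enhancers = gS@enhancers)
  expect_gt(st$repeats["MIR", "fold"], 1)
  expect_lt(st$repeats["MIR", "p"], 1e-4)
  expect_gt(st$enhancers$fold, 1)
  expect_lt(st$enhancers$p, 1e-4)
  # a family with no tested-site overlap is excluded and logged
  empty <- GenomicRanges::GRanges()
  nowhere <- setdiff(seq_len(5000),
                     BiocGenerics::start(sites)[
                       as.character(GenomeInfoDb::seqnames(sites)) == "chrA"])[1]
  fake <- GenomicRanges::GRanges("chrA",
                                 IRanges::IRanges(nowhere, nowhere),
                                 family = "ERV")
  st2 <- siteArchitectureTests(sig, sites, fake, families = "ERV")
  expect_true("ERV" %in% st2$skippedFamilies)
})

test_that("B-box scan matches the consensus motif and a sliding-window oracle", {
  expect_equal(bboxScan("GTTCAATTC"), 1L)
  expect_equal(bboxScan("GAATTGAAC"), 1L)  # reverse complement hit
  expect_equal(bboxScan("AAAAAAAAA"), 0L)
  expect_equal(bboxScan("GTTCXATTC"), 0L)  # non-ACGT at an N position fails
  # overlapping matches all count
  expect_equal(bboxScan("GTTCAAGTTCAAACC"), 1L)
  oracle <- function(s) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < 9) return(0L)
    hits <- 0L
    isMatch <- function(w, pat) {
      all(vapply(1:9, function(i) {
        pc <- substr(pat, i, i); wc <- substr(w, i, i)
        if (pc == "N") wc %in% c("A", "C", "G", "T") else wc == pc
      }, logical(1)))
    }
    for (i in 1:(n - 8)) {
      w <- substr(s, i, i + 8)
      if (isMatch(w, "GTTCNANNC")) hits <- hits + 1L
      if (isMatch(w, "GNNTNGAAC")) hits <- hits + 1L
    }
    hits
  }
  set.seed(12)
  seqs <- vapply(1:40, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    if (i %% 3 == 0)
      s <- paste0(substr(s, 1, 50), "GTTCGACTC", substr(s, 60, 120))
    s
  }, character(1))
  expect_identical(bboxScan(seqs), vapply(seqs, oracle, integer(1),
                                          USE.NAMES = FALSE))
  # planted MIR B-boxes in the synthetic genome are recoverable
  g <- smallGenome()
  mirSeqs <- g@repeatSeqs[g@repeats$repeat_id[g@repeats$family == "MIR"]]
  frac <- mean(bboxScan(mirSeqs) > 0)
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.6)
})

test_that("boundary distances are zero for straddlers and null at identity", {
  tp <- toyPartition()
  el <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(2950, 1500), c(3050, 1600)))
  bt <- boundaryDistanceTest(el, tp, el)
  expect_equal(bt$distances[1], 0)
  expect_gt(bt$distances[2], 0)
  expect_lt(bt$D, 1e-12)
  # elements planted at called-TAD centres sit further than uniform
  # background (gap TADs are narrow, so their centres are uninformative);
  # study-scale partition for adequate TAD counts
  g <- studyGenome()
  part <- tadRanges(g@tads)
  part <- part[part$origin == "called-domain"]
  centres <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(part),
    IRanges::IRanges(BiocGenerics::start(part) +
                       BiocGenerics::width(part) %/% 2, width = 1))
  set.seed(2)
  chr <- sample(names(g@chromSizes), 300, replace = TRUE)
  pos <- floor(runif(300, 1, g@chromSizes[chr]))
  unif <- GenomicRanges::GRanges(chr, IRanges::IRanges(pos, pos))
  bt2 <- boundaryDistanceTest(centres, g@tads, unif)
  expect_gt(bt2$medianSet, bt2$medianBackground)
  expect_lt(bt2$p, 0.01)
})

test_that("MIR-zero matching detects MIR-linked effects and stays null otherwise", {
  # constructed cohort of 250 genes: CpG densities comparable throughout,
  # intronic MIR density high for 25 genes, zero for 100
  mkWorld <- function(seed, mirLinked) {
    set.seed(seed)
    nG <- 250
    ids <- sprintf("g%03d", 1:nG)
    gm <- GeneModels(GenomicRanges::GRanges("chr1",
      IRanges::IRanges(seq(1, by = 20000, length.out = nG),
                       width = 10000), gene_id = ids))
    # ~10 CpGs per gene body for everyone
    pos <- unlist(lapply(seq_len(nG), function(i)
      (i - 1) * 20000 + sort(sample.int(10000, 10))))
    sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos))
    dens <- c(runif(25, 0.1, 0.2), rep(0, 100), runif(125, 0.01, 0.05))
    arch <- data.frame(gene_id = ids,
                       density_MIR_intron = dens,
                       density_MIR_exon = 0)
    maxRho <- if (mirLinked)
      c(runif(25, 0.6, 0.9), runif(225, 0, 0.4))
    else runif(nG, 0, 0.9)
    tbl <- data.frame(gene_id = ids, site_id = paste0("s", 1:nG),
                      rho = maxRho, bin = "proximal")
    list(tbl = tbl, arch = arch, gm = gm, sites = sites)
  }
  w <- mkWorld(1, mirLinked = TRUE)
  res <- mirZeroMatchedTest(w$tbl, w$arch, w$gm, w$sites)
  expect_gte(res$nMatched, 20)
  expect_lt(res$p, 1e-2)
  # effects independent of MIR density: p not systematically small
  ps <- vapply(1:10, function(s) {
    w0 <- mkWorld(100 + s, mirLinked = FALSE)
    mirZeroMatchedTest(w0$tbl, w0$arch, w0$gm, w0$sites)$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.3)
  # no MIR-zero genes at all: insufficient data
  archNoZero <- w$arch
  archNoZero$density_MIR_intron[] <- 0.5
  expect_error(mirZeroMatchedTest(w$tbl, archNoZero, w$gm, w$sites),
               "no MIR-zero genes")
})

test_that("divergence-score shifts reuse the ECDF machinery on repeat annotations", {
  g <- smallGenome()
  rep_ <- g@repeats
  mirDiv <- rep_$divergence[rep_$family == "MIR"]
  aluDiv <- rep_$divergence[rep_$family == "Alu"]
  sh <- ecdfShiftTest(mirDiv, c(mirDiv, aluDiv))
  # MIRs are older (higher divergence) than Alus by construction
  expect_gt(sh$curve[which.max(abs(sh$curve))], 0)
  expect_lt(sh$p, 1e-4)
})
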