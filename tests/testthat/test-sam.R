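# SAM permutation statistic, BH FDR, and the DMC / DE pipelines on top.

test_that("identical class means give d near zero everywhere", {
  set.seed(1)
  half <- matrix(rnorm(200 * 4), 200, 4)
  X <- cbind(half, half)  # class 2 duplicates class 1
  res <- samTwoClass(X, rep(c("a", "b"), each = 4), nPerm = 100L, seed = 1L)
  expect_true(all(abs(res@d) < 1e-8))
  expect_equal(nrow(res@significant), 0L)
})

test_that("SAM is calibrated on pure-null matrices", {
  counts <- vapply(1:10, function(s) {
    X <- withr::with_seed(s, matrix(rnorm(500 * 10), 500, 10))
    res <- samTwoClass(X, rep(c("a", "b"), each = 5), nPerm = 252L,
                       seed = s)
    nrow(res@significant)
  }, numeric(1))
  expect_lte(median(counts), 2)
})

test_that("SAM recovers 3-SD shifts with controlled empirical FDR", {
  powers <- fdrs <- numeric(5)
  for (s in 1:5) {
    set.seed(100 + s)
    p <- 1000
    X <- matrix(rnorm(p * 10), p, 10)
    shifted <- 1:50
    X[shifted, 6:10] <- X[shifted, 6:10] + 3
    res <- samTwoClass(X, rep(c("a", "b"), each = 5), nPerm = 252L,
                       seed = s)
    called <- as.integer(sub("f", "", res@significant$feature))
    powers[s] <- mean(shifted %in% called)
    fdrs[s] <- if (length(called)) mean(!called %in% shifted) else 0
    # direction agrees with the planted shift (up in class 2)
    dirUp <- res@significant$direction[
      res@significant$feature %in% sprintf("f%05d", shifted)]
    expect_true(all(dirUp == "up"))
  }
  expect_gte(mean(powers), 0.9)
  expect_lte(mean(fdrs), 0.10)
})

test_that("significant set is invariant to sample order", {
  set.seed(9)
  X <- matrix(rnorm(300 * 8), 300, 8)
  X[1:20, 5:8] <- X[1:20, 5:8] + 2.5
  lab <- rep(c("a", "b"), each = 4)
  r1 <- samTwoClass(X, lab, nPerm = 70L)
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  r2 <- samTwoClass(X[, perm], lab[perm], nPerm = 70L)
  expect_equal(sort(r1@significant$feature), sort(r2@significant$feature))
  expect_equal(r1@d, r2@d, tolerance = 1e-10)
})

test_that("bhFdr equals the brute-force step-up and validates input", {
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0,1\\]")
  bruteBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[order(o)]
  }
  for (s in 1:5) {
    set.seed(s)
    p <- runif(sample(5:1000, 1))^2
    expect_equal(bhFdr(p), bruteBH(p), tolerance = 1e-12)
  }
})

test_that("repeat-family DMCs recover planted IDH hypermethylation on MIRs", {
  set.seed(4)
  n1 <- 8; n2 <- 8; n <- n1 + n2
  nPerFam <- 120
  repeats <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1000, by = 1000, length.out = 3 * nPerFam),
                     width = 300),
    family = rep(c("MIR", "Alu", "L1"), each = nPerFam))
  pos <- BiocGenerics::start(repeats) + 50
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos),
                                  site_id = sprintf("s%04d", seq_along(pos)))
  m <- matrix(pmin(0.95, pmax(0.02, rnorm(length(pos) * n, 0.4, 0.05))),
              length(pos), n)
  # plant IDH hypermethylation on half the MIR sites only
  planted <- 1:(nPerFam / 2)
  m[planted, (n1 + 1):n] <- pmin(0.98, m[planted, (n1 + 1):n] + 0.4)
  meth <- MethylationSet(sites, m, matrix(60L, length(pos), n),
                         group = rep(c("DNMT3A", "IDH"), c(n1, n2)))
  res <- lapply(setNames(nm = c("MIR", "Alu", "L1")), function(fam)
    dmcByRepeatFamily(meth, c("DNMT3A", "IDH"), repeats, fam,
                      nPerm = 500L, seed = 2L))
  expect_gt(res$MIR$pctDmc, res$Alu$pctDmc)
  expect_gt(res$MIR$pctDmc, res$L1$pctDmc)
  expect_equal(res$MIR$nHypo, 0L)  # 100% hypermethylated in IDH
  expect_gt(res$MIR$nHyper, 0L)
  expect_error(dmcByRepeatFamily(meth, c("DNMT3A", "IDH"), repeats,
                                 "ERV"),
               "insufficient data")
})

test_that("DMC annotation categories and enrichments behave at the extremes", {
  g <- smallGenome()
  sites <- g@sites
  # DMCs = all tested sites: every fold is 1
  out <- dmcAnnotationTests(sites, sites, g@genes,
                            enhancers = g@enhancers,
                            geneSets = list(all = geneBodies(g@genes)$gene_id))
  expect_equal(out$enhancers$fold, 1)
  expect_equal(out$geneSets$all$fold, 1)
  expect_equal(sum(out$categories$dmc), length(sites))
  # planted enhancer-only DMCs enrich strongly
  enhSites <- sites[sites$on_enhancer]
  out2 <- dmcAnnotationTests(enhSites, sites, g@genes,
                             enhancers = g@enhancers)
  expect_gt(out2$enhancers$fold, 2)
  expect_lt(out2$enhancers$p, 1e-5)
  # uniform draws: chi-squared p is not systematically extreme
  set.seed(8)
  ps <- replicate(20, {
    dmc <- sites[sample.int(length(sites), 150)]
    dmcAnnotationTests(dmc, sites, g@genes)$chisq$p
  })
  expect_gt(mean(ps > 0.05), 0.6)
})

test_that("pseudo-replicate DE appends class means and validates design", {
  set.seed(5)
  e <- matrix(2^rnorm(200 * 4, 5), 200, 4,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  e[1:15, 3:4] <- e[1:15, 3:4] * 8
  expr <- ExpressionMatrix(e, group = rep(c("wt", "mut"), each = 2))
  res <- deTwoClass(expr, c("wt", "mut"), pseudoReplicate = TRUE,
                    nPerm = 100L, seed = 1L, minMedian = 0)
  # 3 samples per class after augmentation: C(6,3) = 20 permutations
  expect_equal(res$sam@nPerm, 20L)
  expect_gt(length(res$up), 0)
  expect_gt(mean(sprintf("g%03d", 1:15) %in% res$up), 0.5)
  expr3 <- ExpressionMatrix(e[, c(1, 2, 3, 3, 4)],
                            group = c("wt", "wt", "mut", "mut", "mut"))
  expect_error(deTwoClass(expr3, c("wt", "mut"), pseudoReplicate = TRUE),
               "design error")
})
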