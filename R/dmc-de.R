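# Differential methylation of retrotransposon-overlapping cytosines and
# differential expression with the pseudo-replicate rule, both built on the
# SAM permutation machinery.

#' Differential methylation of cytosines on one retrotransposon family
#'
#' Restricts the methylation table to two genotype groups and to sites that
#' overlap the requested repeat family, have coverage above `minCoverage`
#' in every retained sample, and show non-zero methylation in at least two
#' samples of each class; runs the SAM two-class test on the methylation
#' fractions; and summarises the percentage of differentially methylated
#' cytosines (DMCs) and their hyper/hypomethylation split (direction `up`
#' means higher methylation in the second group).
#'
#' @param meth A [MethylationSet-class] (site-level, with coverage).
#' @param groups Length-2 character: the two genotype groups to contrast,
#'   e.g. `c("DNMT3A", "IDH")`; `d > 0` means hypermethylated in the
#'   second.
#' @param repeats Repeat annotation with `family`.
#' @param family Family to test (e.g. `"MIR"`).
#' @param minCoverage Coverage floor (strictly greater than; default 10).
#' @param nPerm,fdrTarget,seed Passed to [samTwoClass()].
#' @return `list(sam = SamResult, nTested =, nDmc =, pctDmc =, nHyper =,
#'   nHypo =, dmcSites =)`.
#' @export
dmcByRepeatFamily <- function(meth, groups, repeats, family,
                              minCoverage = 10L, nPerm = 1000L,
                              fdrTarget = 0.05, seed = 1L) {
  grp <- SummarizedExperiment::colData(meth)$group
  keepS <- grp %in% groups
  if (length(unique(grp[keepS])) != 2)
    stop("both genotype groups must be present")
  meth <- meth[, keepS]
  grp <- factor(SummarizedExperiment::colData(meth)$group,
                levels = groups)
  sites <- SummarizedExperiment::rowRanges(meth)
  el <- repeats[repeats$family == family]
  onFam <- GenomicRanges::countOverlaps(sites, el,
                                        ignore.strand = TRUE) > 0
  m <- SummarizedExperiment::assay(meth, "meth")
  covOk <- if ("cov" %in% SummarizedExperiment::assayNames(meth))
    rowSums(SummarizedExperiment::assay(meth, "cov") <= minCoverage) == 0
  else rep(TRUE, nrow(m))
  nz1 <- rowSums(m[, grp == groups[1], drop = FALSE] > 0) >= 2
  nz2 <- rowSums(m[, grp == groups[2], drop = FALSE] > 0) >= 2
  keep <- onFam & covOk & nz1 & nz2
  if (sum(keep) < 10)
    stop("insufficient data: fewer than 10 eligible ", family, " sites")
  sam <- samTwoClass(m[keep, , drop = FALSE], grp, nPerm = nPerm,
                     fdrTarget = fdrTarget, seed = seed)
  sig <- sam@significant
  list(sam = sam, nTested = sum(keep), nDmc = nrow(sig),
       pctDmc = 100 * nrow(sig) / sum(keep),
       nHyper = sum(sig$direction == "up"),
       nHypo = sum(sig$direction == "down"),
       dmcSites = sig$feature)
}

#' Annotation tests for differentially methylated cytosines
#'
#' Classifies each site as protein-coding, non-coding or intergenic
#' (precedence: protein-coding > non-coding > intergenic, by gene-body
#' overlap), compares the DMC category counts to the tested-site
#' proportions with a chi-squared test (falling back to a Monte-Carlo
#' exact p when any expected count drops below 5, flagged), and computes
#' hypergeometric fold enrichments of the DMCs in enhancers and in
#' supplied gene sets (a DMC hits a gene set when it falls in one of its
#' gene bodies).
#'
#' @param dmcs,allSites [GenomicRanges::GRanges] with `site_id`; `dmcs`
#'   must be a subset of `allSites`.
#' @param genes A [GeneModels-class].
#' @param enhancers Optional enhancer intervals.
#' @param geneSets Optional named list of gene-id vectors (e.g. proximal
#'   and W sets).
#' @return `list(categories =, chisq =, enhancers =, geneSets =)`.
#' @export
dmcAnnotationTests <- function(dmcs, allSites, genes, enhancers = NULL,
                               geneSets = NULL) {
  bodies <- geneBodies(genes)
  categorise <- function(s) {
    pc <- GenomicRanges::countOverlaps(
      s, bodies[bodies$biotype == "protein-coding"],
      ignore.strand = TRUE) > 0
    nc <- GenomicRanges::countOverlaps(
      s, bodies[bodies$biotype == "non-coding"],
      ignore.strand = TRUE) > 0
    factor(ifelse(pc, "protein-coding",
                  ifelse(nc, "non-coding", "intergenic")),
           levels = c("protein-coding", "non-coding", "intergenic"))
  }
  catDmc <- table(categorise(dmcs))
  catAll <- table(categorise(allSites))
  props <- as.numeric(catAll) / length(allSites)
  nz <- props > 0
  expected <- sum(catDmc) * props
  exactFallback <- any(expected[nz] < 5)
  ct <- suppressWarnings(
    chisq.test(as.numeric(catDmc)[nz], p = props[nz],
               simulate.p.value = exactFallback, B = 2000))
  out <- list(categories = data.frame(
    category = names(catDmc),
    dmc = as.integer(catDmc),
    tested = as.integer(catAll),
    expected = as.numeric(expected)),
    chisq = list(statistic = unname(ct$statistic), p = ct$p.value,
                 exactFallback = exactFallback))
  N <- length(allSites); nD <- length(dmcs)
  if (!is.null(enhancers)) {
    K <- sum(GenomicRanges::countOverlaps(allSites, enhancers,
                                          ignore.strand = TRUE) > 0)
    k <- sum(GenomicRanges::countOverlaps(dmcs, enhancers,
                                          ignore.strand = TRUE) > 0)
    out$enhancers <- hyperEnrichment(k, K, nD, N)
  }
  if (!is.null(geneSets)) {
    out$geneSets <- lapply(geneSets, function(gs) {
      gb <- bodies[bodies$gene_id %in% gs]
      K <- sum(GenomicRanges::countOverlaps(allSites, gb,
                                            ignore.strand = TRUE) > 0)
      k <- sum(GenomicRanges::countOverlaps(dmcs, gb,
                                            ignore.strand = TRUE) > 0)
      hyperEnrichment(k, K, nD, N)
    })
  }
  out
}

#' Differential expression with the two-replicate pseudo-replicate rule
#'
#' Log2-transforms the expression matrix (with `+offset`) and runs the SAM
#' two-class test.  When `pseudoReplicate` is set, each class must have
#' exactly two samples and their per-gene mean is appended as a third
#' pseudo-replicate before testing, mirroring the handling of
#' two-replicate mouse designs.
#'
#' @param expr Expression `SummarizedExperiment` (assay `expr`).
#' @param groups Length-2 character: groups to contrast; `d > 0` means
#'   upregulated in the second.
#' @param pseudoReplicate Apply the pseudo-replicate rule.
#' @param offset Log2 offset (default 1, FPKM-like data).
#' @param minMedian Keep genes with median expression at least this value
#'   (default 1).
#' @param nPerm,fdrTarget,seed Passed to [samTwoClass()].
#' @return `list(sam = SamResult, up =, down =, nTested =)`.
#' @export
deTwoClass <- function(expr, groups, pseudoReplicate = FALSE, offset = 1,
                       minMedian = 1, nPerm = 1000L, fdrTarget = 0.05,
                       seed = 1L) {
  grp <- SummarizedExperiment::colData(expr)$group
  keepS <- grp %in% groups
  expr <- expr[, keepS]
  grp <- SummarizedExperiment::colData(expr)$group
  x <- SummarizedExperiment::assay(expr, "expr")
  keepG <- apply(x, 1, median) >= minMedian
  if (!any(keepG)) stop("no genes pass the median-expression filter")
  x <- log2(x[keepG, , drop = FALSE] + offset)
  if (pseudoReplicate) {
    if (any(table(grp) != 2))
      stop("design error: pseudo-replicate rule needs exactly 2 samples",
           " per class")
    for (g in groups) {
      idx <- which(grp == g)
      x <- cbind(x, rowMeans(x[, idx, drop = FALSE]))
      colnames(x)[ncol(x)] <- paste0(g, ".pseudo")
      grp <- c(grp, g)
    }
  }
  sam <- samTwoClass(x, factor(grp, levels = groups), nPerm = nPerm,
                     fdrTarget = fdrTarget, seed = seed)
  sig <- sam@significant
  list(sam = sam,
       up = sig$feature[sig$direction == "up"],
       down = sig$feature[sig$direction == "down"],
       nTested = nrow(x))
}
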