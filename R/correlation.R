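# Within-TAD expression-methylation correlation discovery: filtering,
# all-pairs Spearman with genome-wide BH correction, distance binning,
# CpG-island aggregation, W sets, shared-site gene pairs, and cross-cohort
# coefficient comparison.

#' Filter methylation sites/probes and expressed genes
#'
#' Site-level mode drops any site whose coverage falls below `minCoverage`
#' in any sample; probe-level mode keeps probes whose methylation value
#' exceeds `probeValue` in more than `probeFraction` of samples.  Expression
#' keeps the top `exprTopFraction` of protein-coding genes ranked by mean
#' expression.
#'
#' @param expr Expression `SummarizedExperiment` (assay `expr`; optional
#'   `rowData(x)$biotype`).
#' @param meth A [MethylationSet-class]; mode is site-level when a `cov`
#'   assay is present, probe-level otherwise.
#' @param minCoverage Site-level coverage floor (default 10: sites with
#'   coverage below 10 in any sample are dropped).
#' @param probeValue,probeFraction Probe-level retention rule (default:
#'   value > 0.3 in more than 3% of samples).
#' @param exprTopFraction Fraction of protein-coding genes kept (default
#'   0.5).
#' @return `list(expr = , meth = )` with the filtered objects.
#' @export
filterFeatures <- function(expr, meth, minCoverage = 10L,
                           probeValue = 0.3, probeFraction = 0.03,
                           exprTopFraction = 0.5) {
  if ("cov" %in% SummarizedExperiment::assayNames(meth)) {
    cv <- SummarizedExperiment::assay(meth, "cov")
    keep <- rowSums(cv < minCoverage) == 0
  } else {
    m <- SummarizedExperiment::assay(meth, "meth")
    keep <- rowMeans(m > probeValue) > probeFraction
  }
  if (!any(keep)) stop("no methylation sites pass filtering")
  meth <- meth[keep, ]

  e <- SummarizedExperiment::assay(expr, "expr")
  bt <- SummarizedExperiment::rowData(expr)$biotype
  coding <- if (is.null(bt)) rep(TRUE, nrow(e)) else bt == "protein-coding"
  if (!any(coding)) stop("no protein-coding genes in expression matrix")
  expr <- expr[coding, ]
  e <- e[coding, , drop = FALSE]
  nKeep <- round(nrow(e) * exprTopFraction)
  if (nKeep < 1) stop("no genes pass expression filtering")
  ord <- order(rowMeans(e), decreasing = TRUE)
  expr <- expr[sort(ord[seq_len(nKeep)]), ]
  list(expr = expr, meth = meth)
}

# Spearman rho + p for all row pairs of two matrices over shared columns.
# Average ranks for ties; exact p (via cor.test) for n <= 9, t
# approximation otherwise.  Zero-variance rows give NA.
.spearmanAllPairs <- function(E, M) {
  n <- ncol(E)
  rankRows <- function(X) t(apply(X, 1, rank))
  zscale <- function(R) {
    mu <- rowMeans(R)
    sdv <- sqrt(rowSums((R - mu)^2) / (n - 1))
    out <- (R - mu) / sdv
    out[sdv == 0, ] <- NA_real_
    out
  }
  ZE <- zscale(rankRows(E))
  ZM <- zscale(rankRows(M))
  rho <- tcrossprod(ZE, ZM) / (n - 1)
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  rho
}

.spearmanP <- function(rho, n) {
  tt <- rho * sqrt((n - 2) / pmax(1e-12, 1 - rho^2))
  2 * pt(-abs(tt), df = n - 2)
}

#' Discover within-TAD gene-mCpG Spearman correlations
#'
#' Correlates every gene with every methylation site that overlaps (at
#' least partially) the same TAD.  Spearman coefficients use average ranks
#' for ties; p-values use the exact distribution for \eqn{n \le 9} samples
#' and the t approximation otherwise, and are corrected by
#' Benjamini-Hochberg across all tested pairs genome-wide.  A pair is
#' significant when `|rho| > rhoThreshold` and `q < fdrThreshold`.  Pairs
#' eligible through several TADs are tested once; zero-variance pairs are
#' skipped and counted.
#'
#' @param expr Filtered expression `SummarizedExperiment`.
#' @param meth Filtered [MethylationSet-class].
#' @param partition A [TadPartition-class].
#' @param genes A [GeneModels-class] covering the expression gene ids.
#' @param rhoThreshold,fdrThreshold Significance thresholds (defaults 0.5
#'   and 0.05).
#' @param proximalBp,longBp Distance-bin edges (defaults 2 kb and 500 kb).
#' @return `data.frame` with one row per tested pair: `gene_id`, `site_id`,
#'   `tad_ids`, `rho`, `p`, `q`, `distance`, `within_body`, `bin`,
#'   `significant`.  Attributes `nTested` and `nSkipped` record totals.
#' @export
correlateWithinTads <- function(expr, meth, partition, genes,
                                rhoThreshold = 0.5, fdrThreshold = 0.05,
                                proximalBp = 2000L, longBp = 500000L) {
  shared <- intersect(colnames(expr), colnames(meth))
  if (length(shared) < 3)
    stop("insufficient data: need at least 3 shared samples")
  E <- SummarizedExperiment::assay(expr, "expr")[, shared, drop = FALSE]
  M <- SummarizedExperiment::assay(meth, "meth")[, shared, drop = FALSE]
  bodies <- geneBodies(genes)
  bodies <- bodies[match(rownames(E), bodies$gene_id)]
  if (anyNA(BiocGenerics::start(bodies)))
    stop("expression rows missing from gene models")
  sites <- SummarizedExperiment::rowRanges(meth)
  part <- tadRanges(partition)

  gh <- GenomicRanges::findOverlaps(bodies, part, ignore.strand = TRUE)
  sh <- GenomicRanges::findOverlaps(sites, part, ignore.strand = TRUE)
  gdt <- data.table(g = S4Vectors::queryHits(gh),
                    tad = S4Vectors::subjectHits(gh))
  sdt <- data.table(s = S4Vectors::queryHits(sh),
                    tad = S4Vectors::subjectHits(sh))
  pairsDt <- merge(gdt, sdt, by = "tad", allow.cartesian = TRUE)
  if (!nrow(pairsDt)) stop("no within-TAD gene-site pairs to test")
  tadIds <- part$tad_id
  pairsDt <- pairsDt[, list(tad_ids = collapseIds(tadIds[sort(unique(tad))])),
                     by = list(g, s)]

  n <- length(shared)
  rho <- .spearmanAllPairs(E, M)[cbind(pairsDt$g, pairsDt$s)]
  skip <- is.na(rho)
  nSkipped <- sum(skip)
  pairsDt <- pairsDt[!skip]
  rho <- rho[!skip]
  if (n > 9) {
    p <- .spearmanP(rho, n)
  } else {
    p <- vapply(seq_len(nrow(pairsDt)), function(i)
      suppressWarnings(cor.test(E[pairsDt$g[i], ], M[pairsDt$s[i], ],
                                method = "spearman"))$p.value,
      numeric(1))
  }
  q <- bhFdr(p)
  d <- geneSiteDistance(bodies, sites, pairsDt$g, pairsDt$s)
  withinBody <- d == 0L
  bin <- classifyDistance(d, withinBody, proximalBp, longBp)
  out <- data.frame(
    gene_id = bodies$gene_id[pairsDt$g],
    site_id = sites$site_id[pairsDt$s],
    tad_ids = pairsDt$tad_ids,
    rho = rho, p = p, q = q,
    distance = d, within_body = withinBody, bin = bin,
    significant = abs(rho) > rhoThreshold & q < fdrThreshold,
    stringsAsFactors = FALSE)
  attr(out, "nTested") <- nrow(out)
  attr(out, "nSkipped") <- nSkipped
  attr(out, "thresholds") <- c(rho = rhoThreshold, fdr = fdrThreshold)
  out
}

#' Aggregate site-level methylation to CpG-island means
#'
#' Per island and sample, the unweighted mean of the (already filtered)
#' member sites' methylation fractions; islands without passing sites are
#' dropped.
#'
#' @param meth Site-level [MethylationSet-class] (post-filtering).
#' @param islands A [GenomicRanges::GRanges] of CpG islands with an
#'   `island_id` column.
#' @return A [MethylationSet-class] whose rows are islands.
#' @export
islandMeanMethylation <- function(meth, islands) {
  sites <- SummarizedExperiment::rowRanges(meth)
  h <- GenomicRanges::findOverlaps(islands, sites, ignore.strand = TRUE)
  if (!length(h)) stop("no islands overlap any passing site")
  m <- SummarizedExperiment::assay(meth, "meth")
  byIsland <- split(S4Vectors::subjectHits(h), S4Vectors::queryHits(h))
  keep <- as.integer(names(byIsland))
  agg <- t(vapply(byIsland, function(i)
    colMeans(m[i, , drop = FALSE]), numeric(ncol(m))))
  isl <- islands[keep]
  if (is.null(isl$island_id))
    isl$island_id <- sprintf("cgi_%03d", keep)
  isl$site_id <- isl$island_id
  rownames(agg) <- isl$site_id
  MethylationSet(isl, agg, NULL,
                 group = SummarizedExperiment::colData(meth)$group)
}

#' Extract the W set: genes with the weakest correlations in a bin
#'
#' Genes are scored by the maximum absolute Spearman coefficient over their
#' sites in the requested distance bin; the `n` lowest-scoring genes are
#' returned, ties broken by gene id.
#'
#' @param table Output of [correlateWithinTads()].
#' @param n Number of genes (default 1000).
#' @param bin `"proximal"`, `"intermediate"` or `"long"`.
#' @return Character vector of gene ids; when fewer than `n` genes exist in
#'   the bin, all are returned with a warning.
#' @export
weakestGeneSet <- function(table, n = 1000L, bin = "proximal") {
  sub <- table[table$bin == bin, ]
  if (!nrow(sub)) stop("no tested pairs in bin '", bin, "'")
  score <- tapply(abs(sub$rho), sub$gene_id, max)
  ord <- order(score, names(score))
  if (length(score) < n) {
    warning("only ", length(score), " genes available in bin '", bin, "'")
    n <- length(score)
  }
  names(score)[ord][seq_len(n)]
}

#' Rank genes for enrichment-analysis input
#'
#' Genes ranked by the maximum absolute correlation coefficient of their
#' sites in a distance bin (strongest first), the ranking the GSEA-style
#' engines consume; the enrichment engines themselves are not part of this
#' package.
#'
#' @inheritParams weakestGeneSet
#' @return `data.frame` with `gene_id` and `score`, strongest first.
#' @export
rankGenesByCorrelation <- function(table, bin = "proximal") {
  sub <- table[table$bin == bin, ]
  if (!nrow(sub)) stop("no tested pairs in bin '", bin, "'")
  score <- tapply(abs(sub$rho), sub$gene_id, max)
  ord <- order(-score, names(score))
  data.frame(gene_id = names(score)[ord], score = unname(score)[ord],
             stringsAsFactors = FALSE)
}

#' Shared-mCpG analysis of within-TAD gene pairs
#'
#' For each pair of genes tested against common sites (and each having at
#' least one significant site), evaluates whether the sites significant for
#' one gene are enriched among the sites significant for the other, with a
#' one-sided hypergeometric test over the shared tested sites, BH-corrected
#' across pairs.
#'
#' @param table Output of [correlateWithinTads()].
#' @return `data.frame` with one row per gene pair: `gene1`, `gene2`,
#'   `shared_tested`, `sig1`, `sig2`, `shared_significant`, `fold`, `p`,
#'   `q`.
#' @export
sharedSiteGenePairs <- function(table) {
  dt <- as.data.table(table[, c("gene_id", "site_id", "significant")])
  sigGenes <- unique(dt$gene_id[dt$significant])
  dt <- dt[dt$gene_id %in% sigGenes]
  if (length(sigGenes) < 2)
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      shared_tested = integer(0), sig1 = integer(0),
                      sig2 = integer(0), shared_significant = integer(0),
                      fold = numeric(0), p = numeric(0), q = numeric(0)))
  tested <- split(dt$site_id, dt$gene_id)
  sig <- split(dt$site_id[dt$significant], dt$gene_id[dt$significant])
  genes <- sort(names(tested))
  rows <- list()
  for (i in seq_along(genes)[-length(genes)]) {
    for (j in seq((i + 1), length(genes))) {
      g1 <- genes[i]; g2 <- genes[j]
      pop <- intersect(tested[[g1]], tested[[g2]])
      if (!length(pop)) next
      K <- sum(sig[[g1]] %in% pop)
      nn <- sum(sig[[g2]] %in% pop)
      k <- length(intersect(intersect(sig[[g1]], sig[[g2]]), pop))
      he <- hyperEnrichment(k, K, nn, length(pop))
      rows[[length(rows) + 1L]] <- data.frame(
        gene1 = g1, gene2 = g2, shared_tested = length(pop),
        sig1 = K, sig2 = nn, shared_significant = k,
        fold = if (k == 0 && he$expected == 0) NA_real_
               else if (k == 0) 0 else he$fold,
        p = he$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$q <- bhFdr(out$p)
  out
}

#' Compare correlation coefficients in an alternate sample set
#'
#' Recomputes the Spearman coefficient of the supplied gene-site pairs in
#' an alternate cohort (e.g. samples without the mutations) and tests,
#' with a paired one-sided Wilcoxon signed-rank test, whether the absolute
#' coefficients are lower there than in discovery.
#'
#' @param pairs `data.frame` with `gene_id`, `site_id` and discovery `rho`
#'   (a subset of [correlateWithinTads()] output, typically the significant
#'   pairs).
#' @param altExpr,altMeth Alternate-cohort expression and methylation
#'   objects sharing the feature ids.
#' @return `list(statistic =, p =, nPairs =, nExcluded =, meanAbsDiscovery
#'   =, meanAbsAlternate =)`.
#' @export
compareCohortCoefficients <- function(pairs, altExpr, altMeth) {
  shared <- intersect(colnames(altExpr), colnames(altMeth))
  E <- SummarizedExperiment::assay(altExpr, "expr")[, shared, drop = FALSE]
  M <- SummarizedExperiment::assay(altMeth, "meth")[, shared, drop = FALSE]
  gi <- match(pairs$gene_id, rownames(E))
  si <- match(pairs$site_id, rownames(M))
  ok <- !is.na(gi) & !is.na(si)
  altRho <- rep(NA_real_, nrow(pairs))
  for (i in which(ok)) {
    x <- E[gi[i], ]; y <- M[si[i], ]
    if (sd(x) == 0 || sd(y) == 0) next
    altRho[i] <- cor(x, y, method = "spearman")
  }
  comparable <- which(!is.na(altRho))
  if (length(comparable) < 10)
    stop("insufficient data: fewer than 10 comparable pairs")
  disc <- abs(pairs$rho[comparable])
  alt <- abs(altRho[comparable])
  if (all(abs(disc - alt) < 1e-12)) {
    # no shift anywhere (e.g. alternate cohort identical to discovery)
    wt <- list(statistic = NA_real_, p.value = 0.5)
  } else {
    wt <- suppressWarnings(wilcox.test(disc, alt, paired = TRUE,
                                       alternative = "greater"))
  }
  list(statistic = unname(wt$statistic), p = wt$p.value,
       nPairs = length(comparable),
       nExcluded = nrow(pairs) - length(comparable),
       meanAbsDiscovery = mean(disc), meanAbsAlternate = mean(alt))
}

#' One-sided enrichment of a correlation sign in proximal pairs
#'
#' Tests whether significant positive (or negative) correlations are
#' enriched in the proximal bin relative to the bin proportions of all
#' tested pairs (chi-squared, one-sided toward enrichment).
#'
#' @param table Output of [correlateWithinTads()].
#' @param sign `"positive"` or `"negative"`.
#' @return `list(observed =, expected =, p =)` for the proximal bin.
#' @export
proximalEnrichmentTest <- function(table, sign = c("negative", "positive")) {
  sign <- match.arg(sign)
  sel <- table$significant &
    (if (sign == "positive") table$rho > 0 else table$rho < 0)
  if (!any(sel)) stop("no significant ", sign, " correlations")
  p0 <- mean(table$bin == "proximal")
  obs <- sum(table$bin[sel] == "proximal")
  nSig <- sum(sel)
  ct <- suppressWarnings(chisq.test(c(obs, nSig - obs),
                                    p = c(p0, 1 - p0)))
  pOne <- if (obs >= nSig * p0) ct$p.value / 2 else 1 - ct$p.value / 2
  list(observed = obs, expected = nSig * p0, p = pOne)
}
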