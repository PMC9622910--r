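# Gene and site architecture: lengths, GC, conservation, repeat-family
# densities, ECDF-shift curves with one-sample KS tests, hypergeometric
# containment tests, B-box scanning, TAD-boundary distances and the
# MIR-zero matched comparison.

# Weighted overlap statistics of a track over a set of ranges grouped by
# gene: returns per-gene weighted mean, weighted median and covered bases.
.trackStats <- function(regions, geneIds, track, nGenes, geneKey) {
  h <- GenomicRanges::findOverlaps(regions, track, ignore.strand = TRUE)
  if (!length(h))
    return(list(mean = rep(NA_real_, nGenes),
                median = rep(NA_real_, nGenes),
                covered = rep(0, nGenes)))
  ov <- BiocGenerics::width(IRanges::pintersect(
    IRanges::ranges(regions)[S4Vectors::queryHits(h)],
    IRanges::ranges(track)[S4Vectors::subjectHits(h)]))
  g <- geneIds[S4Vectors::queryHits(h)]
  sc <- track$score[S4Vectors::subjectHits(h)]
  dt <- data.table(g = g, sc = sc, w = ov)
  agg <- dt[, list(mean = sum(sc * w) / sum(w),
                   median = weightedMedian(sc, w),
                   covered = sum(w)), by = g]
  idx <- match(geneKey, agg$g)
  list(mean = agg$mean[idx], median = agg$median[idx],
       covered = ifelse(is.na(idx), 0, agg$covered[idx]))
}

# Per-gene fraction of region bases overlapped by a (reduced) element set.
.densityOver <- function(regions, geneIds, elements, geneKey, regionLen) {
  red <- GenomicRanges::reduce(elements, ignore.strand = TRUE)
  h <- GenomicRanges::findOverlaps(regions, red, ignore.strand = TRUE)
  cov <- rep(0, length(geneKey))
  if (length(h)) {
    ov <- BiocGenerics::width(IRanges::pintersect(
      IRanges::ranges(regions)[S4Vectors::queryHits(h)],
      IRanges::ranges(red)[S4Vectors::subjectHits(h)]))
    agg <- data.table(g = geneIds[S4Vectors::queryHits(h)],
                      w = ov)[, list(w = sum(w)), by = g]
    cov[match(agg$g, geneKey)] <- agg$w
  }
  ifelse(regionLen > 0, cov / regionLen, NA_real_)
}

#' Per-gene architecture metrics
#'
#' For each gene: exonic and intronic length (union of merged exons and the
#' gaps between them), GC content and median per-base conservation of exons
#' and introns (from binned tracks; bases without track coverage are
#' excluded, and genes with under half their bases covered are flagged),
#' and the fraction of exonic/intronic bases overlapped by each repeat
#' family.  Intronless genes carry `NA` intronic fields.
#'
#' @param genes A [GeneModels-class].
#' @param repeats A [GenomicRanges::GRanges] with a `family` column.
#' @param conservation,gc Optional score tracks
#'   ([GenomicRanges::GRanges] with `score`), e.g. phyloP-like and GC
#'   fraction per bin.
#' @param families Repeat families to profile.
#' @return `data.frame`, one row per gene: lengths, `gc_exon`, `gc_intron`,
#'   `cons_exon`, `cons_intron`, `density_<family>_exon` /
#'   `_intron`, plus `low_coverage` flag.
#' @export
computeArchitecture <- function(genes, repeats, conservation = NULL,
                                gc = NULL,
                                families = c("MIR", "Alu", "L1")) {
  ex <- exonsByGene(genes)
  intr <- intronsByGene(genes)
  ids <- geneBodies(genes)$gene_id
  exFlat <- BiocGenerics::unlist(ex)
  exIds <- rep(names(ex), S4Vectors::elementNROWS(ex))
  inFlat <- BiocGenerics::unlist(intr)
  inIds <- rep(names(intr), S4Vectors::elementNROWS(intr))
  exLen <- setNames(rep(0, length(ids)), ids)
  tmp <- tapply(BiocGenerics::width(exFlat), exIds, sum)
  exLen[names(tmp)] <- tmp
  inLen <- setNames(rep(0, length(ids)), ids)
  tmp <- tapply(BiocGenerics::width(inFlat), inIds, sum)
  inLen[names(tmp)] <- tmp

  out <- data.frame(gene_id = ids, exonic_length = unname(exLen),
                    intronic_length = unname(inLen),
                    stringsAsFactors = FALSE)
  lowCov <- rep(FALSE, length(ids))
  if (!is.null(gc)) {
    sEx <- .trackStats(exFlat, exIds, gc, length(ids), ids)
    sIn <- .trackStats(inFlat, inIds, gc, length(ids), ids)
    out$gc_exon <- sEx$mean
    out$gc_intron <- sIn$mean
  }
  if (!is.null(conservation)) {
    sEx <- .trackStats(exFlat, exIds, conservation, length(ids), ids)
    sIn <- .trackStats(inFlat, inIds, conservation, length(ids), ids)
    out$cons_exon <- sEx$median
    out$cons_intron <- sIn$median
    lowCov <- (sEx$covered + sIn$covered) < 0.5 * (exLen + inLen)
  }
  for (fam in families) {
    el <- repeats[repeats$family == fam]
    out[[paste0("density_", fam, "_exon")]] <-
      .densityOver(exFlat, exIds, el, ids, exLen)
    out[[paste0("density_", fam, "_intron")]] <-
      .densityOver(inFlat, inIds, el, ids, inLen)
  }
  out$intronic_length[out$intronic_length == 0] <- NA_integer_
  intronCols <- grep("intron", colnames(out), value = TRUE)
  out[is.na(out$intronic_length), setdiff(intronCols, "intronic_length")] <-
    NA_real_
  out$low_coverage <- lowCov
  out
}

# Asymptotic Kolmogorov distribution upper tail.
.ksPvalue <- function(D, n) {
  if (is.na(D) || D <= 0) return(1)
  x <- sqrt(n) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(1, max(0, p))
}

#' ECDF-shift curve and one-sample KS test against a background
#'
#' Evaluates, on the combined grid of observed values, the difference
#' between the background ECDF and the set ECDF: positive values mean the
#' set is shifted toward higher values.  The KS statistic is the maximum
#' absolute curve value (the two are computed on the identical grid), with
#' an asymptotic one-sample p-value at the set size.
#'
#' @param setValues Numeric values of the gene/site set.
#' @param backgroundValues Numeric values of the background population.
#' @return `list(grid =, curve =, D =, p =, n =, warning =)`; `warning` is
#'   set for sets smaller than 5.
#' @export
ecdfShiftTest <- function(setValues, backgroundValues) {
  setValues <- setValues[is.finite(setValues)]
  backgroundValues <- backgroundValues[is.finite(backgroundValues)]
  if (!length(setValues) || !length(backgroundValues))
    stop("both value sets must be non-empty")
  grid <- sort(unique(c(setValues, backgroundValues)))
  Fb <- ecdf(backgroundValues)
  Fs <- ecdf(setValues)
  curve <- Fb(grid) - Fs(grid)
  D <- max(abs(curve))
  list(grid = grid, curve = curve, D = D,
       p = .ksPvalue(D, length(setValues)),
       n = length(setValues), warning = length(setValues) < 5)
}

#' Hypergeometric test for containing at least one repeat element
#'
#' Tests whether genes of a set are more likely than background genes to
#' contain at least one element of a repeat family.
#'
#' @param geneSet Character vector of gene ids (subset of background).
#' @param backgroundGenes Character vector of all background gene ids.
#' @param genes A [GeneModels-class].
#' @param repeats Repeat [GenomicRanges::GRanges] with `family`.
#' @param family Family name.
#' @return `list(fold =, p =, observed =, expected =)`; `fold` is `NA` when
#'   the family overlaps no background gene.
#' @export
containsElementEnrichment <- function(geneSet, backgroundGenes, genes,
                                      repeats, family) {
  bodies <- geneBodies(genes)
  el <- repeats[repeats$family == family]
  hasEl <- bodies$gene_id[GenomicRanges::countOverlaps(
    bodies, el, ignore.strand = TRUE) > 0]
  N <- length(backgroundGenes)
  K <- sum(backgroundGenes %in% hasEl)
  nDraw <- length(geneSet)
  k <- sum(geneSet %in% hasEl)
  if (K == 0)
    return(list(fold = NA_real_, p = NA_real_, observed = k,
                expected = 0))
  he <- hyperEnrichment(k, K, nDraw, N)
  list(fold = he$fold, p = he$p, observed = k, expected = he$expected)
}

#' Architecture tests of significant mCpGs against all tested sites
#'
#' Per-site conservation (KS shift of significant sites against the tested
#' background) plus hypergeometric fold enrichments of the significant
#' sites in each repeat family and in enhancers, background = all tested
#' sites.
#'
#' @param sitesSig,sitesAll [GenomicRanges::GRanges]; `sitesSig` must be a
#'   subset of `sitesAll`.
#' @param repeats Repeat annotation with `family`.
#' @param conservation Optional score track for per-site conservation.
#' @param enhancers Optional enhancer intervals.
#' @param families Families to test.
#' @return `list(conservation =, repeats = data.frame, enhancers =)`;
#'   families overlapping no tested site are dropped (recorded in
#'   `skippedFamilies`).
#' @export
siteArchitectureTests <- function(sitesSig, sitesAll, repeats,
                                  conservation = NULL, enhancers = NULL,
                                  families = c("MIR", "Alu", "L1")) {
  if (!length(sitesSig))
    return(list(conservation = NULL, repeats = NULL, enhancers = NULL,
                skippedFamilies = character(0)))
  out <- list()
  if (!is.null(conservation)) {
    scoreOf <- function(s) {
      h <- GenomicRanges::findOverlaps(s, conservation,
                                       ignore.strand = TRUE)
      v <- rep(NA_real_, length(s))
      v[S4Vectors::queryHits(h)] <-
        conservation$score[S4Vectors::subjectHits(h)]
      v
    }
    out$conservation <- ecdfShiftTest(scoreOf(sitesSig),
                                      scoreOf(sitesAll))
  }
  N <- length(sitesAll)
  nDraw <- length(sitesSig)
  skipped <- character(0)
  rows <- list()
  for (fam in families) {
    el <- repeats[repeats$family == fam]
    K <- sum(GenomicRanges::countOverlaps(sitesAll, el,
                                          ignore.strand = TRUE) > 0)
    if (K == 0) { skipped <- c(skipped, fam); next }
    k <- sum(GenomicRanges::countOverlaps(sitesSig, el,
                                          ignore.strand = TRUE) > 0)
    he <- hyperEnrichment(k, K, nDraw, N)
    rows[[fam]] <- data.frame(family = fam, observed = k,
                              expected = he$expected, fold = he$fold,
                              p = he$p, stringsAsFactors = FALSE)
  }
  out$repeats <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(enhancers)) {
    K <- sum(GenomicRanges::countOverlaps(sitesAll, enhancers,
                                          ignore.strand = TRUE) > 0)
    k <- sum(GenomicRanges::countOverlaps(sitesSig, enhancers,
                                          ignore.strand = TRUE) > 0)
    he <- hyperEnrichment(k, K, nDraw, N)
    out$enhancers <- list(observed = k, expected = he$expected,
                          fold = he$fold, p = he$p)
  }
  out$skippedFamilies <- skipped
  out
}

#' Count B-box promoter motifs in repeat-element sequences
#'
#' Scans each segment for the internal RNA-polymerase-III B-box consensus
#' `GTTCNANNC` on the forward strand plus its reverse complement
#' (`GNNTNGAAC`) in the same segment; overlapping matches all count.  Any
#' non-ACGT character fails the fixed motif positions and the N positions
#' alike.
#'
#' @param sequences Character vector or [Biostrings::DNAStringSet] of
#'   segment sequences (e.g. under MIR footprints).
#' @return Integer vector of per-segment B-box counts.
#' @export
bboxScan <- function(sequences) {
  seqs <- toupper(as.character(sequences))
  sense <- "(?=GTTC[ACGT]A[ACGT][ACGT]C)"
  anti <- "(?=G[ACGT][ACGT]T[ACGT]GAAC)"
  countHits <- function(s, pat) {
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }
  vapply(seqs, function(s)
    countHits(s, sense) + countHits(s, anti), integer(1), USE.NAMES = FALSE)
}

#' Distance of elements to the nearest TAD boundary
#'
#' Computes, per element, the distance to the closest partition boundary
#' (zero for boundary-straddling elements) and compares element and
#' background distance distributions with a two-sample KS test.
#'
#' @param elements,backgroundElements [GenomicRanges::GRanges].
#' @param partition A [TadPartition-class].
#' @return `list(D =, p =, medianSet =, medianBackground =, distances =,
#'   backgroundDistances =)`.
#' @export
boundaryDistanceTest <- function(elements, partition, backgroundElements) {
  part <- tadRanges(partition)
  bnd <- GenomicRanges::GRanges(
    rep(GenomeInfoDb::seqnames(part), 2),
    IRanges::IRanges(c(BiocGenerics::start(part),
                       BiocGenerics::end(part)), width = 1L))
  distTo <- function(x) {
    h <- GenomicRanges::distanceToNearest(x, bnd, ignore.strand = TRUE)
    d <- rep(NA_real_, length(x))
    d[S4Vectors::queryHits(h)] <- S4Vectors::mcols(h)$distance
    d
  }
  dSet <- distTo(elements)
  dBg <- distTo(backgroundElements)
  kt <- suppressWarnings(ks.test(dSet, dBg))
  list(D = unname(kt$statistic), p = kt$p.value,
       medianSet = median(dSet, na.rm = TRUE),
       medianBackground = median(dBg, na.rm = TRUE),
       distances = dSet, backgroundDistances = dBg)
}

#' MIR-dense vs MIR-zero genes matched on CpG density
#'
#' Selects the top decile of genes by intronic MIR density and the genes
#' containing no MIR element at all, matches the two groups on CpG density
#' (nearest neighbour within a caliper of 0.2 SD, without replacement), and
#' compares their per-gene maximum absolute correlation coefficients with a
#' two-sample KS test.
#'
#' @param table Output of [correlateWithinTads()].
#' @param architecture Output of [computeArchitecture()].
#' @param genes A [GeneModels-class].
#' @param sites Tested site positions ([GenomicRanges::GRanges]), used for
#'   per-gene CpG density (sites per kb of gene body).
#' @param caliper Matching caliper in units of the CpG-density SD.
#' @return `list(D =, p =, nMatched =, mirDense =, mirZero =)`.
#' @export
mirZeroMatchedTest <- function(table, architecture, genes, sites,
                               caliper = 0.2) {
  bodies <- geneBodies(genes)
  cpg <- GenomicRanges::countOverlaps(bodies, sites,
                                      ignore.strand = TRUE) /
    BiocGenerics::width(bodies) * 1000
  names(cpg) <- bodies$gene_id
  arch <- architecture
  dens <- setNames(arch$density_MIR_intron, arch$gene_id)
  score <- tapply(abs(table$rho), table$gene_id, max)
  pool <- intersect(names(score), arch$gene_id)
  dens <- dens[pool]; cpgP <- cpg[pool]
  hasDens <- !is.na(dens)
  top <- names(dens)[hasDens & dens >= quantile(dens[hasDens], 0.9) &
                       dens > 0]
  exonD <- setNames(arch$density_MIR_exon, arch$gene_id)[pool]
  zero <- names(dens)[(is.na(dens) | dens == 0) &
                        (is.na(exonD) | exonD == 0)]
  if (!length(zero)) stop("insufficient data: no MIR-zero genes")
  cal <- caliper * sd(cpgP, na.rm = TRUE)
  used <- character(0)
  matched <- character(0)
  for (g in top) {
    cand <- setdiff(zero, used)
    if (!length(cand)) break
    dd <- abs(cpgP[cand] - cpgP[g])
    if (min(dd, na.rm = TRUE) > cal) next
    pick <- cand[which.min(dd)]
    used <- c(used, pick)
    matched <- c(matched, g)
  }
  if (length(matched) < 20)
    stop("insufficient data: fewer than 20 matched pairs")
  kt <- suppressWarnings(ks.test(score[matched], score[used]))
  list(D = unname(kt$statistic), p = kt$p.value,
       nMatched = length(matched), mirDense = matched, mirZero = used)
}
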