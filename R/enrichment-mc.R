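# Monte-Carlo interval-shuffling enrichment of DNA-binding proteins:
# uniform re-placement of peaks within a genomic space, Z-scores against
# the shuffled null, the MIR-space variant, and cumulative binding curves.

# Vectorised placement: n placements of intervals with widths `w` (recycled)
# uniformly over all start positions where the interval fits entirely in
# one segment of `space` (longer segments get proportionally more mass).
# Returns a data.table(iter, chrom, start, end).
.placeUniform <- function(w, iters, space) {
  segChrom <- as.character(GenomeInfoDb::seqnames(space))
  segStart <- BiocGenerics::start(space)
  segWidth <- BiocGenerics::width(space)
  out <- vector("list", length(unique(w)))
  i <- 0L
  for (ww in unique(w)) {
    idx <- which(w == ww)
    valid <- pmax(0L, segWidth - ww + 1L)
    if (sum(valid) == 0)
      stop(sprintf(
        "placement error: interval of %d bp longer than every segment", ww))
    seg <- sample.int(length(valid), length(idx), replace = TRUE,
                      prob = valid)
    off <- floor(runif(length(idx)) * valid[seg])
    s <- segStart[seg] + off
    i <- i + 1L
    out[[i]] <- data.table(iter = iters[idx], chrom = segChrom[seg],
                           start = s, end = s + ww - 1L)
  }
  data.table::rbindlist(out)
}

#' Shuffle intervals uniformly within a genomic space
#'
#' Each interval is independently re-placed, with its length preserved,
#' uniformly among all positions where it fits entirely inside one segment
#' of the space; shuffled intervals may overlap one another.
#'
#' @param intervals [GenomicRanges::GRanges] to shuffle.
#' @param space [GenomicRanges::GRanges] defining the admissible space
#'   (reduced internally).
#' @param seed RNG seed.
#' @return A [GenomicRanges::GRanges] of shuffled intervals (same widths,
#'   arbitrary order).
#' @export
shuffleWithinSpace <- function(intervals, space, seed = NULL) {
  space <- GenomicRanges::reduce(space, ignore.strand = TRUE)
  withSeed(seed, {
    dt <- .placeUniform(BiocGenerics::width(intervals),
                        seq_along(intervals), space)
    GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start, dt$end))
  })
}

#' Monte-Carlo Z-score for DBP peak enrichment in a feature set
#'
#' Counts the features overlapped by at least one peak, builds a null
#' distribution of that count from `nIter` shuffles of the peaks within the
#' genomic space, and reports the Z-score of the observed count.  The
#' conventional significance threshold is `|Z| > 10`.
#'
#' @param peaks Peak [GenomicRanges::GRanges] for one DBP.
#' @param features Feature set (e.g. gene bodies of a correlation gene
#'   set).
#' @param space Admissible shuffling space (e.g. the union of all genes
#'   participating in the correlations).
#' @param nIter Number of shuffles (default 1000; at least 100).
#' @param seed RNG seed.
#' @param dbp Label stored in the result.
#' @return An [McResult-class]; degenerate nulls (SD zero) are flagged
#'   rather than yielding infinite Z.
#' @export
mcEnrichmentZ <- function(peaks, features, space, nIter = 1000L,
                          seed = 1L, dbp = "DBP") {
  if (nIter < 100) stop("need at least 100 iterations")
  space <- GenomicRanges::reduce(space, ignore.strand = TRUE)
  observed <- sum(GenomicRanges::countOverlaps(
    features, peaks, ignore.strand = TRUE) > 0)
  if (!length(peaks)) {
    return(new("McResult", dbp = dbp, observed = 0, nullMean = 0,
               nullSd = 0, z = NA_real_, degenerate = TRUE,
               nIter = as.integer(nIter), seed = as.integer(seed)))
  }
  w <- BiocGenerics::width(peaks)
  nullCounts <- withSeed(seed, {
    dt <- .placeUniform(rep(w, nIter),
                        rep(seq_len(nIter), each = length(w)), space)
    shuf <- GenomicRanges::GRanges(dt$chrom,
                                   IRanges::IRanges(dt$start, dt$end))
    h <- GenomicRanges::findOverlaps(features, shuf,
                                     ignore.strand = TRUE)
    hitDt <- unique(data.table(
      f = S4Vectors::queryHits(h),
      iter = dt$iter[S4Vectors::subjectHits(h)]))
    counts <- hitDt[, list(nHit = .N), by = iter]
    full <- rep(0, nIter)
    full[counts$iter] <- counts$nHit
    full
  })
  mu <- mean(nullCounts)
  sdv <- sd(nullCounts)
  degenerate <- sdv == 0
  new("McResult", dbp = dbp, observed = observed, nullMean = mu,
      nullSd = sdv, z = if (degenerate) NA_real_ else (observed - mu) / sdv,
      degenerate = degenerate, nIter = as.integer(nIter),
      seed = as.integer(seed))
}

#' Monte-Carlo DBP enrichment restricted to intronic MIR space
#'
#' Asks whether a DBP's peaks concentrate on the intronic MIR elements of
#' a gene set beyond what uniform placement over the intronic MIR
#' footprint of the background genes predicts.  Peaks not overlapping the
#' MIR space carry no information about within-MIR preferences and are
#' dropped before shuffling, so a DBP with identical peak density inside
#' and outside the query set's MIRs scores `|Z|` near zero.
#'
#' @param peaks Peak set for one DBP (restricted internally to the MIR
#'   space).
#' @param geneSet Character vector of gene ids whose intronic MIRs are the
#'   features.
#' @param genes A [GeneModels-class].
#' @param repeats Repeat annotation with `family`.
#' @param backgroundGenes Gene ids defining the MIR shuffling space
#'   (default: all genes in `genes`).
#' @inheritParams mcEnrichmentZ
#' @return An [McResult-class].
#' @export
mirSpaceZ <- function(peaks, geneSet, genes, repeats,
                      backgroundGenes = NULL, nIter = 1000L,
                      seed = 1L, dbp = "DBP") {
  intr <- intronsByGene(genes)
  mirs <- repeats[repeats$family == "MIR"]
  mirsOf <- function(ids) {
    flat <- BiocGenerics::unlist(intr[names(intr) %in% ids])
    mirs[GenomicRanges::countOverlaps(mirs, flat,
                                      ignore.strand = TRUE) > 0]
  }
  feats <- mirsOf(geneSet)
  if (!length(feats))
    stop("insufficient space: gene set has no intronic MIR elements")
  if (is.null(backgroundGenes)) backgroundGenes <- names(intr)
  space <- GenomicRanges::reduce(mirsOf(union(backgroundGenes, geneSet)),
                                 ignore.strand = TRUE)
  inSpace <- peaks[GenomicRanges::countOverlaps(
    peaks, space, ignore.strand = TRUE) > 0]
  # shuffled placement needs every peak to fit inside one MIR segment
  w <- BiocGenerics::width(inSpace)
  inSpace <- inSpace[w <= max(BiocGenerics::width(space))]
  mcEnrichmentZ(inSpace, feats, space, nIter = nIter, seed = seed,
                dbp = dbp)
}

#' Cumulative count of unique entities bound by up to N DBPs
#'
#' DBPs are ordered (by default by descending per-DBP bound count) and the
#' curve value at N is the number of unique entities bound by at least one
#' of the first N DBPs; the final value is the size of the union.
#'
#' @param boundSets Named list of character vectors: entities bound per
#'   DBP.
#' @param order Optional character vector fixing the DBP order.
#' @return `data.frame` with `dbp`, `n_bound`, `cumulative_unique`.
#' @export
cumulativeBinding <- function(boundSets, order = NULL) {
  if (!length(boundSets))
    return(data.frame(dbp = character(0), n_bound = integer(0),
                      cumulative_unique = integer(0)))
  if (is.null(order))
    order <- names(sort(vapply(boundSets, function(x)
      length(unique(x)), integer(1)), decreasing = TRUE))
  seen <- character(0)
  cum <- integer(length(order))
  nb <- integer(length(order))
  for (i in seq_along(order)) {
    b <- unique(boundSets[[order[i]]])
    nb[i] <- length(b)
    seen <- union(seen, b)
    cum[i] <- length(seen)
  }
  data.frame(dbp = order, n_bound = nb, cumulative_unique = cum,
             stringsAsFactors = FALSE)
}
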