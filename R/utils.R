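# Internal helpers shared across modules.

.datatable.aware <- TRUE

#' @importFrom methods new is validObject slot
#' @importFrom stats median quantile sd mad rnorm runif rbeta rpois rgamma
#'   phyper pt p.adjust chisq.test wilcox.test ks.test cor cor.test ecdf
#'   prcomp setNames
#' @importFrom utils head tail combn
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Stop with the offending interval spelled out.
stopCoord <- function(msg, gr, i) {
  stop(sprintf("%s: %s:%d-%d", msg,
               as.character(GenomeInfoDb::seqnames(gr)[i]),
               BiocGenerics::start(gr)[i], BiocGenerics::end(gr)[i]),
       call. = FALSE)
}

# Validate that every range lies within the declared chromosome lengths.
checkWithinChromosomes <- function(gr, chromSizes, what = "interval") {
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  bad <- which(!chr %in% names(chromSizes))
  if (length(bad))
    stopCoord(sprintf("%s on undeclared chromosome", what), gr, bad[1L])
  bad <- which(BiocGenerics::start(gr) < 1L |
               BiocGenerics::end(gr) > unname(chromSizes[chr]))
  if (length(bad))
    stopCoord(sprintf("%s outside declared chromosome bounds", what),
              gr, bad[1L])
  invisible(TRUE)
}

# GRanges constructor bound to a declared genome (seqlengths attached).
grangesOn <- function(chrom, start, end, chromSizes, strand = "*", ...) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand,
    seqinfo = GenomeInfoDb::Seqinfo(names(chromSizes),
                                    unname(as.integer(chromSizes))),
    ...)
}

# Upper-tail hypergeometric test with fold enrichment.
# N population size, K successes in population, n draws, k observed successes.
hyperEnrichment <- function(k, K, n, N) {
  expected <- K * n / N
  fold <- if (expected > 0) k / expected else NA_real_
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(observed = k, expected = expected, fold = fold, p = p)
}

# Weighted median (used for per-base conservation medians over binned tracks).
weightedMedian <- function(x, w) {
  if (!length(x)) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1L]
  # midpoint rule at an exact 50% split
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1L]) / 2
  else x[i]
}

# Collapse an integer vector of ids to a comma-separated key.
collapseIds <- function(x) paste(x, collapse = ",")
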