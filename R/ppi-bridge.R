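# PPI bridging: which physically interacting protein pairs link correlated
# mCpG-gene pairs, with one protein bound at the site and the other at the
# gene (or at a MIR element in the gene's intronic space).

#' Per-entity DBP binding sets
#'
#' Builds, from per-DBP peak sets, the DBPs bound at each site (>=1 bp
#' overlap), at each gene body, and at each gene restricted to its intronic
#' MIR footprints.
#'
#' @param peaks Named [GenomicRanges::GRangesList] (or list of `GRanges`),
#'   one element per DBP.
#' @param sites Site positions with `site_id`.
#' @param genes A [GeneModels-class].
#' @param repeats Repeat annotation with `family` (for the MIR-restricted
#'   map).
#' @return `list(site =, gene =, geneMir =)`: logical matrices
#'   (entity x DBP).
#' @export
bindingMap <- function(peaks, sites, genes, repeats) {
  dbps <- names(peaks)
  bodies <- geneBodies(genes)
  intr <- BiocGenerics::unlist(intronsByGene(genes))
  intrIds <- rep(names(intronsByGene(genes)),
                 S4Vectors::elementNROWS(intronsByGene(genes)))
  mirs <- repeats[repeats$family == "MIR"]
  h <- GenomicRanges::findOverlaps(mirs, intr, ignore.strand = TRUE)
  mirFoot <- IRanges::pintersect(
    mirs[S4Vectors::queryHits(h)],
    intr[S4Vectors::subjectHits(h)], ignore.strand = TRUE)
  mirGene <- intrIds[S4Vectors::subjectHits(h)]

  mk <- function(nrow_, names_) {
    m <- matrix(FALSE, nrow_, length(dbps),
                dimnames = list(names_, dbps))
    m
  }
  siteMap <- mk(length(sites), sites$site_id)
  geneMap <- mk(length(bodies), bodies$gene_id)
  geneMirMap <- mk(length(bodies), bodies$gene_id)
  for (d in dbps) {
    pk <- peaks[[d]]
    siteMap[, d] <- GenomicRanges::countOverlaps(
      sites, pk, ignore.strand = TRUE) > 0
    geneMap[, d] <- GenomicRanges::countOverlaps(
      bodies, pk, ignore.strand = TRUE) > 0
    if (length(mirFoot)) {
      hit <- GenomicRanges::countOverlaps(mirFoot, pk,
                                          ignore.strand = TRUE) > 0
      geneMirMap[unique(mirGene[hit]), d] <- TRUE
    }
  }
  list(site = siteMap, gene = geneMap, geneMir = geneMirMap)
}

#' Enrichment of PPI pairs bridging correlated mCpG-gene pairs
#'
#' For each ordered PPI (A, B): over the population of correlated pairs,
#' the draws are pairs whose site is bound by A, the population successes
#' pairs whose gene is bound by B (gene body, or intronic MIR footprint in
#' `mir` mode), and the observed count pairs with both; a one-sided
#' hypergeometric p is BH-corrected across all tested PPIs.  The two
#' orientations of an interaction are tested separately, a protein bound at
#' both ends may contribute to either, and self-interactions are excluded.
#'
#' @param pairs `data.frame` with `gene_id` and `site_id` (the significant
#'   correlated pairs).
#' @param map Output of [bindingMap()].
#' @param ppi `data.frame` with columns `protein_a`, `protein_b`.
#' @param mode `"gene"` (protein B at the gene body) or `"mir"` (protein B
#'   at an intronic MIR of the gene).
#' @return `data.frame`: `protein_site`, `protein_gene`, `observed`,
#'   `expected`, `fold`, `p`, `q`.
#' @export
bridgeEnrichment <- function(pairs, map, ppi, mode = c("gene", "mir")) {
  mode <- match.arg(mode)
  geneMap <- if (mode == "gene") map$gene else map$geneMir
  empty <- data.frame(protein_site = character(0),
                      protein_gene = character(0), observed = integer(0),
                      expected = numeric(0), fold = numeric(0),
                      p = numeric(0), q = numeric(0))
  if (!nrow(ppi) || !nrow(pairs)) return(empty)
  # both orientations of each interaction, self-pairs excluded
  edges <- unique(rbind(
    data.frame(A = ppi$protein_a, B = ppi$protein_b,
               stringsAsFactors = FALSE),
    data.frame(A = ppi$protein_b, B = ppi$protein_a,
               stringsAsFactors = FALSE)))
  edges <- edges[edges$A != edges$B, , drop = FALSE]
  edges <- edges[edges$A %in% colnames(map$site) &
                   edges$B %in% colnames(geneMap), , drop = FALSE]
  if (!nrow(edges)) return(empty)
  si <- match(pairs$site_id, rownames(map$site))
  gi <- match(pairs$gene_id, rownames(geneMap))
  ok <- !is.na(si) & !is.na(gi)
  si <- si[ok]; gi <- gi[ok]
  N <- length(si)
  rows <- lapply(seq_len(nrow(edges)), function(i) {
    aAt <- map$site[si, edges$A[i]]
    bAt <- geneMap[gi, edges$B[i]]
    he <- hyperEnrichment(sum(aAt & bAt), sum(bAt), sum(aAt), N)
    data.frame(protein_site = edges$A[i], protein_gene = edges$B[i],
               observed = he$observed, expected = he$expected,
               fold = if (is.na(he$fold) && he$observed == 0) 0
                      else he$fold,
               p = he$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bhFdr(out$p)
  out[order(out$p), ]
}
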