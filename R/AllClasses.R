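#' @import methods
#' @importClassesFrom GenomicRanges GRanges CompressedGRangesList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#'   RangedSummarizedExperiment
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' TadPartition: a disjoint, exhaustive TAD cover of a genome
#'
#' Holds, per chromosome, an ordered set of disjoint intervals whose union is
#' the whole chromosome.  Each interval carries a `tad_id` and an `origin`
#' flag recording whether it came from a called domain (after merging
#' overlapping and book-ended domains) or from the complement of the called
#' domains.
#'
#' @slot partition A [GenomicRanges::GRanges] with `seqlengths` set and
#'   metadata columns `tad_id` (character) and
#'   `origin` (`"called-domain"` or `"complement"`).
#' @seealso [buildTadPartition()]
#' @export
setClass("TadPartition", representation(partition = "GRanges"))

setValidity("TadPartition", function(object) {
  gr <- object@partition
  sl <- GenomeInfoDb::seqlengths(gr)
  if (anyNA(sl)) return("all chromosome lengths must be declared")
  mc <- S4Vectors::mcols(gr)
  if (!all(c("tad_id", "origin") %in% colnames(mc)))
    return("partition needs 'tad_id' and 'origin' metadata columns")
  if (!all(mc$origin %in% c("called-domain", "complement")))
    return("origin must be 'called-domain' or 'complement'")
  if (anyDuplicated(mc$tad_id)) return("tad_id values must be unique")
  if (!S4Vectors::isSorted(gr)) return("partition must be sorted")
  if (!GenomicRanges::isDisjoint(gr))
    return("partition intervals must be disjoint")
  covered <- vapply(split(BiocGenerics::width(gr),
                          as.character(GenomeInfoDb::seqnames(gr))),
                    sum, numeric(1))
  if (!all(covered == sl[names(covered)]))
    return("partition must cover each chromosome exactly")
  TRUE
})

#' GeneModels: exon-resolved gene annotations
#'
#' Exons per gene plus derived gene bodies (the contiguous union of exons and
#' introns).  Introns are computed lazily as the gaps between merged exons.
#'
#' @slot exons A [GenomicRanges::GRangesList], one element per gene, named by
#'   gene id.
#' @slot genes A [GenomicRanges::GRanges] of gene bodies with metadata columns
#'   `gene_id`, `symbol` and `biotype`
#'   (`"protein-coding"` or `"non-coding"`).
#' @seealso [GeneModels()], [geneBodies()], [intronsByGene()]
#' @export
setClass("GeneModels",
         representation(exons = "CompressedGRangesList", genes = "GRanges"))

setValidity("GeneModels", function(object) {
  if (length(object@exons) != length(object@genes))
    return("exons and genes must have the same length")
  if (!identical(names(object@exons), object@genes$gene_id))
    return("exon list names must match gene ids")
  if (anyDuplicated(object@genes$gene_id))
    return("gene ids must be unique")
  if (any(S4Vectors::elementNROWS(object@exons) < 1L))
    return("every gene needs at least one exon")
  if (!all(object@genes$biotype %in% c("protein-coding", "non-coding")))
    return("biotype must be 'protein-coding' or 'non-coding'")
  nchrom <- S4Vectors::elementNROWS(unique(
    GenomeInfoDb::seqnames(object@exons)))
  if (any(nchrom != 1L))
    return("all exons of a gene must lie on one chromosome")
  TRUE
})

#' MethylationSet: per-site methylation fractions with optional coverage
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are
#' single-base CpG sites (or probes, or CpG islands after aggregation) and
#' whose columns are samples.  Assay `meth` holds methylation fractions in
#' \eqn{[0,1]}; the optional assay `cov` holds integer read coverage
#' (site-level mode).  `colData(x)$group` carries the genotype group.
#'
#' @seealso [MethylationSet()], [filterFeatures()]
#' @export
setClass("MethylationSet", contains = "RangedSummarizedExperiment")

setValidity("MethylationSet", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!"meth" %in% a) return("assay 'meth' is required")
  m <- SummarizedExperiment::assay(object, "meth")
  if (any(m < 0 | m > 1, na.rm = TRUE))
    return("methylation fractions must lie in [0,1]")
  if ("cov" %in% a) {
    cv <- SummarizedExperiment::assay(object, "cov")
    if (any(cv < 0, na.rm = TRUE)) return("coverage must be non-negative")
  }
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain a 'group' column")
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr)) {
    # rows are single-base sites/probes, or islands after aggregation
    key <- paste(GenomeInfoDb::seqnames(rr), BiocGenerics::start(rr),
                 BiocGenerics::end(rr))
    if (anyDuplicated(key)) return("site positions must be unique")
  }
  TRUE
})

#' SamResult: output of the SAM permutation test
#'
#' @slot d Named numeric: the observed relative-difference statistic per
#'   feature, \eqn{d_i = (\bar x_2 - \bar x_1)/(s_i + s_0)}.
#' @slot s Named numeric: the per-feature pooled scatter.
#' @slot s0 The fudge factor chosen by the coefficient-of-variation criterion.
#' @slot dbar Expected order statistics of `d` from permutations.
#' @slot delta The chosen threshold; `Inf` when no threshold attains the
#'   FDR target.
#' @slot fdr Estimated FDR (median false calls / calls) at `delta`.
#' @slot cutlow,cutup The lower and upper `d` cutoffs implied by `delta`.
#' @slot significant `data.frame` with columns `feature`, `d`, `direction`
#'   (`"up"` means higher in the second class).
#' @slot nPerm Number of permutations used.
#' @slot seed RNG seed (NA when all distinct permutations were enumerated).
#' @seealso [samTwoClass()]
#' @export
setClass("SamResult", representation(
  d = "numeric", s = "numeric", s0 = "numeric", dbar = "numeric",
  delta = "numeric", fdr = "numeric", cutlow = "numeric", cutup = "numeric",
  significant = "data.frame", nPerm = "integer", seed = "integer"))

#' McResult: Monte-Carlo interval-shuffling enrichment result
#'
#' @slot dbp Name of the DNA-binding protein / complex tested.
#' @slot observed Number of features overlapped by at least one peak.
#' @slot nullMean,nullSd Mean and SD of the shuffled null distribution.
#' @slot z Z-score `(observed - nullMean)/nullSd`; `NA` when degenerate.
#' @slot degenerate TRUE when the null SD is zero.
#' @slot nIter Number of shuffling iterations.
#' @slot seed RNG seed used.
#' @seealso [mcEnrichmentZ()]
#' @export
setClass("McResult", representation(
  dbp = "character", observed = "numeric", nullMean = "numeric",
  nullSd = "numeric", z = "numeric", degenerate = "logical",
  nIter = "integer", seed = "integer"))

#' SyntheticGenome: a simulated genome with planted regulatory architecture
#'
#' All annotations a run of the pipeline needs: TAD partition, gene models
#' labelled by architecture class, repeat elements with divergence scores,
#' CpG sites and islands, enhancers, binned GC and conservation tracks,
#' ChIP-seq-like peak sets for a roster of DNA-binding proteins, a PPI edge
#' list, and nucleotide sequence under repeat footprints (for B-box scans).
#'
#' @seealso [generateGenome()]
#' @export
setClass("SyntheticGenome", representation(
  chromSizes = "integer", tads = "TadPartition", genes = "GeneModels",
  geneClass = "character", repeats = "GRanges", sites = "GRanges",
  islands = "GRanges", enhancers = "GRanges", conservation = "GRanges",
  gcTrack = "GRanges", peaks = "CompressedGRangesList", ppi = "data.frame",
  repeatSeqs = "DNAStringSet", config = "list"))

#' SyntheticCohort: simulated methylation + expression cohort with truth
#'
#' @slot meth A [MethylationSet-class].
#' @slot expr A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `expr` (linear-scale, non-negative) and `colData(x)$group`.
#' @slot truth Ground-truth list: `pairs` (planted gene-site effect table),
#'   `regulated` (gene ids), `driverSites` (site ids), `bridgePairs`
#'   (planted bridging PPIs), `dbpTargets` (per-DBP planted target genes).
#' @seealso [generateCohort()]
#' @export
setClass("SyntheticCohort", representation(
  meth = "MethylationSet", expr = "SummarizedExperiment", truth = "list"))

#' ProjectionResult: reference-anchored PCA projection
#'
#' @slot loadings Gene-by-component orthonormal loadings fit on reference
#'   samples only.
#' @slot center Reference gene means used for centering.
#' @slot refScores,queryScores Sample scores for reference and query samples.
#' @slot varExplained Fraction of reference variance per component.
#' @seealso [fitAndProject()]
#' @export
setClass("ProjectionResult", representation(
  loadings = "matrix", center = "numeric", refScores = "matrix",
  queryScores = "matrix", varExplained = "numeric"))
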