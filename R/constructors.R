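#' @include AllClasses.R
NULL

#' Construct a GeneModels object from per-gene exons
#'
#' @param exons A named [GenomicRanges::GRangesList] (one element per gene)
#'   or a [GenomicRanges::GRanges] with a `gene_id` metadata column.
#' @param symbol Optional character vector of gene symbols (defaults to the
#'   gene ids).
#' @param biotype Character vector, `"protein-coding"` or `"non-coding"`,
#'   recycled to the number of genes.
#' @return A [GeneModels-class] object.  Gene bodies are the contiguous
#'   union of each gene's exons and introns.
#' @examples
#' ex <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(101, 501), c(200, 700)), gene_id = "g1")
#' gm <- GeneModels(ex)
#' geneBodies(gm)
#' intronsByGene(gm)
#' @export
GeneModels <- function(exons, symbol = NULL, biotype = "protein-coding") {
  if (is(exons, "GRanges")) {
    if (is.null(exons$gene_id))
      stop("exon GRanges needs a 'gene_id' metadata column")
    exons <- GenomicRanges::split(exons, exons$gene_id)
  }
  if (is.null(names(exons))) stop("exon list must be named by gene id")
  exons <- GenomicRanges::reduce(GenomicRanges::sort(exons))
  bodies <- BiocGenerics::unlist(range(exons))
  ids <- names(exons)
  if (is.null(symbol)) symbol <- ids
  bodies$gene_id <- ids
  bodies$symbol <- symbol
  bodies$biotype <- rep_len(biotype, length(ids))
  new("GeneModels", exons = exons, genes = bodies)
}

#' Construct a MethylationSet
#'
#' @param sites A [GenomicRanges::GRanges] of single-base site positions;
#'   a `site_id` metadata column is added when absent.
#' @param meth Numeric site-by-sample matrix of methylation fractions in
#'   \eqn{[0,1]}.
#' @param cov Optional integer site-by-sample coverage matrix (site-level
#'   mode); omit for probe-level data.
#' @param group Character/factor vector of per-sample genotype groups
#'   (e.g. `DNMT3A`, `IDH`, `DOUBLE`, `WT`).
#' @return A [MethylationSet-class].
#' @export
MethylationSet <- function(sites, meth, cov = NULL, group) {
  meth <- as.matrix(meth)
  if (is.null(sites$site_id))
    sites$site_id <- sprintf("site_%05d", seq_along(sites))
  if (is.null(rownames(meth))) rownames(meth) <- sites$site_id
  if (is.null(colnames(meth)))
    colnames(meth) <- sprintf("S%02d", seq_len(ncol(meth)))
  assays <- list(meth = meth)
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    dimnames(cov) <- dimnames(meth)
    assays$cov <- cov
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowRanges = sites,
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = colnames(meth)))
  new("MethylationSet", se)
}

#' Construct an expression SummarizedExperiment
#'
#' @param mat Non-negative gene-by-sample expression matrix with unique
#'   rownames (gene ids).
#' @param group Per-sample group labels (genotype group or cell type).
#' @param biotype Optional per-gene biotype vector
#'   (`"protein-coding"`/`"non-coding"`).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay `expr`.
#' @export
ExpressionMatrix <- function(mat, group, biotype = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("expression matrix needs unique gene-id rownames")
  if (any(!is.finite(mat))) stop("expression matrix has missing values")
  if (any(mat < 0)) stop("expression values must be non-negative")
  rd <- S4Vectors::DataFrame(row.names = rownames(mat))
  if (!is.null(biotype)) rd$biotype <- biotype
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = mat),
    rowData = rd,
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   row.names = colnames(mat)))
}
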