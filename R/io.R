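# Readers and writers for the interval and matrix formats the pipeline
# consumes: BED3/6 (+ RepeatMasker-style extension), GTF / BED12 gene models,
# bedGraph tracks, tab-delimited methylation and expression matrices, and
# two-column PPI edge lists.  BED/bedGraph files are 0-based half-open on
# disk and converted to 1-based closed GRanges on read (and back on write).

#' @importFrom data.table fread fwrite data.table as.data.table setnames :=
NULL

.bedToGRanges <- function(dt, chromSizes = NULL) {
  strand <- if (ncol(dt) >= 6) dt[[6]] else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    dt[[1]], IRanges::IRanges(dt[[2]] + 1L, dt[[3]]), strand = strand)
  if (ncol(dt) >= 4) gr$name <- as.character(dt[[4]])
  if (!is.null(chromSizes)) {
    # validate before attaching seqlengths so out-of-bound records raise
    # the package's coordinate error, not a seqinfo validity failure
    checkWithinChromosomes(gr, chromSizes)
    GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
    GenomeInfoDb::seqlengths(gr) <- unname(as.integer(chromSizes))
  }
  gr
}

#' Read a BED3/BED6 file of genomic intervals
#'
#' @param path File path.
#' @param chromSizes Optional named integer vector; when given, seqlengths
#'   are attached and out-of-bounds records raise an error.
#' @return A [GenomicRanges::GRanges] (1-based closed coordinates).
#' @export
readBed <- function(path, chromSizes = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t")
  .bedToGRanges(dt, chromSizes)
}

#' Read a RepeatMasker-style extended BED of repeat elements
#'
#' Columns 1-6 are standard BED; columns 7-11 are `family`
#' (MIR/Alu/L1/other), `subfamily`, and percent substitutions, insertions
#' and deletions.  The divergence score is the sum of the three percentages.
#'
#' @inheritParams readBed
#' @return A [GenomicRanges::GRanges] with metadata columns `family`,
#'   `subfamily` and `divergence`.
#' @export
readRepeats <- function(path, chromSizes = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t")
  gr <- .bedToGRanges(dt[, 1:min(6L, ncol(dt))], chromSizes)
  gr$family <- if (ncol(dt) >= 7) as.character(dt[[7]]) else "other"
  gr$subfamily <- if (ncol(dt) >= 8) as.character(dt[[8]]) else gr$family
  gr$divergence <- if (ncol(dt) >= 11)
    as.numeric(dt[[9]]) + as.numeric(dt[[10]]) + as.numeric(dt[[11]])
  else NA_real_
  gr
}

#' Write intervals as BED
#'
#' @param gr A [GenomicRanges::GRanges].
#' @param path Output path.
#' @param extraCols Character vector of metadata columns to append after
#'   column 6.
#' @export
writeBed <- function(gr, path, extraCols = character()) {
  dt <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = 0L,
    strand = as.character(BiocGenerics::strand(gr)))
  dt$strand[dt$strand == "*"] <- "."
  for (cc in extraCols) dt[[cc]] <- S4Vectors::mcols(gr)[[cc]]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene models from GTF or BED12
#'
#' GTF input uses the `exon` features' `gene_id` (and optional `gene_name`,
#' `gene_biotype`) attributes and is converted from 1-based inclusive
#' coordinates on read; BED12 input derives exons from the block fields.
#'
#' @param path File path.
#' @param format `"gtf"` or `"bed12"`; guessed from the file extension by
#'   default.
#' @return A [GeneModels-class].
#' @export
readGeneModels <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path)) "gtf" else "bed12"
  if (format == "gtf") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    bt <- if (!is.null(gr$gene_biotype))
      ifelse(gr$gene_biotype == "protein_coding",
             "protein-coding", "non-coding")
    else "protein-coding"
    ex <- GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(gr), IRanges::ranges(gr),
      strand = BiocGenerics::strand(gr), gene_id = gr$gene_id)
    first <- !duplicated(gr$gene_id)
    ord <- order(gr$gene_id[first])
    GeneModels(ex,
               symbol = (if (!is.null(gr$gene_name)) gr$gene_name
                         else gr$gene_id)[first][ord],
               biotype = rep_len(bt, length(gr))[first][ord])
  } else {
    dt <- fread(path, header = FALSE, sep = "\t",
                colClasses = list(character = 11:12))
    if (ncol(dt) < 12) stop("BED12 input needs 12 columns")
    n <- nrow(dt)
    sizes <- lapply(strsplit(dt[[11]], ","), as.integer)
    starts <- lapply(strsplit(dt[[12]], ","), as.integer)
    k <- lengths(sizes)
    ex <- GenomicRanges::GRanges(
      rep(dt[[1]], k),
      IRanges::IRanges(start = rep(dt[[2]], k) + unlist(starts) + 1L,
                       width = unlist(sizes)),
      strand = rep(dt[[6]], k),
      gene_id = rep(dt[[4]], k))
    GeneModels(ex)
  }
}

#' Read a bedGraph score track (e.g. per-base conservation, binned)
#'
#' @inheritParams readBed
#' @return A [GenomicRanges::GRanges] with a numeric `score` column.
#' @export
readBedGraph <- function(path, chromSizes = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t")
  gr <- .bedToGRanges(dt[, 1:3], chromSizes)
  gr$score <- as.numeric(dt[[4]])
  gr
}

#' @rdname readBedGraph
#' @param gr Track to write.
#' @export
writeBedGraph <- function(gr, path) {
  fwrite(data.table(as.character(GenomeInfoDb::seqnames(gr)),
                    BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                    gr$score),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited methylation table
#'
#' Site-level mode expects columns `chrom`, `pos`, `site_id`, then per
#' sample `<sample>.meth` and `<sample>.cov`; probe-level mode expects
#' `<sample>` fraction columns only.  A sidecar metadata table supplies the
#' per-sample genotype group.
#'
#' @param path Methylation table path.
#' @param metadataPath Two-column TSV (`sample_id`, `group`).
#' @return A [MethylationSet-class].
#' @export
readMethylationTable <- function(path, metadataPath) {
  dt <- fread(path, sep = "\t")
  meta <- fread(metadataPath, sep = "\t")
  sites <- GenomicRanges::GRanges(dt$chrom,
                                  IRanges::IRanges(dt$pos, width = 1L),
                                  site_id = dt$site_id)
  other <- setdiff(colnames(dt), c("chrom", "pos", "site_id"))
  methCols <- grep("\\.meth$", other, value = TRUE)
  if (length(methCols)) {
    samples <- sub("\\.meth$", "", methCols)
    meth <- as.matrix(dt[, paste0(samples, ".meth"), with = FALSE])
    cov <- as.matrix(dt[, paste0(samples, ".cov"), with = FALSE])
    colnames(meth) <- colnames(cov) <- samples
    MethylationSet(sites, meth, cov,
                   group = meta$group[match(samples, meta$sample_id)])
  } else {
    meth <- as.matrix(dt[, other, with = FALSE])
    MethylationSet(sites, meth, NULL,
                   group = meta$group[match(other, meta$sample_id)])
  }
}

#' @rdname readMethylationTable
#' @param x A [MethylationSet-class] to write.
#' @export
writeMethylationTable <- function(x, path, metadataPath) {
  rr <- SummarizedExperiment::rowRanges(x)
  dt <- data.table(chrom = as.character(GenomeInfoDb::seqnames(rr)),
                   pos = BiocGenerics::start(rr), site_id = rr$site_id)
  m <- SummarizedExperiment::assay(x, "meth")
  if ("cov" %in% SummarizedExperiment::assayNames(x)) {
    cv <- SummarizedExperiment::assay(x, "cov")
    for (s in colnames(m)) {
      dt[[paste0(s, ".meth")]] <- m[, s]
      dt[[paste0(s, ".cov")]] <- cv[, s]
    }
  } else {
    for (s in colnames(m)) dt[[s]] <- m[, s]
  }
  fwrite(dt, path, sep = "\t")
  fwrite(data.table(sample_id = colnames(x),
                    group = SummarizedExperiment::colData(x)$group),
         metadataPath, sep = "\t")
  invisible(path)
}

#' Read an expression matrix with a sample-metadata sidecar
#'
#' @param path Gene-by-sample TSV; first column `gene_id`.
#' @param metadataPath Two-column TSV (`sample_id`, `group`).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay `expr`.
#' @export
readExpressionMatrix <- function(path, metadataPath) {
  dt <- fread(path, sep = "\t")
  meta <- fread(metadataPath, sep = "\t")
  mat <- as.matrix(dt[, -1, with = FALSE])
  rownames(mat) <- dt[[1]]
  ExpressionMatrix(mat, group = meta$group[match(colnames(mat),
                                                 meta$sample_id)])
}

#' @rdname readExpressionMatrix
#' @param x Expression `SummarizedExperiment` to write.
#' @export
writeExpressionMatrix <- function(x, path, metadataPath) {
  m <- SummarizedExperiment::assay(x, "expr")
  dt <- data.table(gene_id = rownames(m))
  for (s in colnames(m)) dt[[s]] <- m[, s]
  fwrite(dt, path, sep = "\t")
  fwrite(data.table(sample_id = colnames(x),
                    group = SummarizedExperiment::colData(x)$group),
         metadataPath, sep = "\t")
  invisible(path)
}

#' Read a two-column PPI edge list
#'
#' @param path TSV with columns `protein_a`, `protein_b` (header optional).
#' @return A `data.frame` with columns `protein_a`, `protein_b`.
#' @export
readPpi <- function(path) {
  dt <- fread(path, sep = "\t", header = "auto")
  out <- data.frame(protein_a = as.character(dt[[1]]),
                    protein_b = as.character(dt[[2]]),
                    stringsAsFactors = FALSE)
  out[out$protein_a != "protein_a", , drop = FALSE]
}
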