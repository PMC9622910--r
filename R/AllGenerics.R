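#' @include AllClasses.R
NULL

#' Accessors for methylTAD classes
#'
#' Small accessor generics: `tadRanges()` returns the partition
#' [GenomicRanges::GRanges]; `tadCount()` the number of TADs;
#' `geneBodies()` the gene-body ranges; `exonsByGene()` /
#' `intronsByGene()` the per-gene exon / intron lists;
#' `groundTruth()`, `cohortMethylation()` and `cohortExpression()` the
#' components of a [SyntheticCohort-class].
#'
#' @param x An object of the documented class.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tadRanges", function(x) standardGeneric("tadRanges"))
#' @rdname accessors
#' @export
setGeneric("tadCount", function(x) standardGeneric("tadCount"))
#' @rdname accessors
#' @export
setGeneric("geneBodies", function(x) standardGeneric("geneBodies"))
#' @rdname accessors
#' @export
setGeneric("exonsByGene", function(x) standardGeneric("exonsByGene"))
#' @rdname accessors
#' @export
setGeneric("intronsByGene", function(x) standardGeneric("intronsByGene"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("cohortMethylation",
           function(x) standardGeneric("cohortMethylation"))
#' @rdname accessors
#' @export
setGeneric("cohortExpression",
           function(x) standardGeneric("cohortExpression"))

#' @rdname accessors
#' @export
setMethod("tadRanges", "TadPartition", function(x) x@partition)

#' @rdname accessors
#' @export
setMethod("tadCount", "TadPartition", function(x) length(x@partition))

#' @rdname accessors
#' @export
setMethod("geneBodies", "GeneModels", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("exonsByGene", "GeneModels", function(x) x@exons)

#' @rdname accessors
#' @export
setMethod("intronsByGene", "GeneModels", function(x) {
  bodies <- BiocGenerics::unlist(range(x@exons))
  introns <- GenomicRanges::psetdiff(bodies, x@exons)
  names(introns) <- names(x@exons)
  introns
})

#' @rdname accessors
#' @export
setMethod("geneBodies", "SyntheticGenome", function(x) geneBodies(x@genes))

#' @rdname accessors
#' @export
setMethod("tadRanges", "SyntheticGenome", function(x) tadRanges(x@tads))

#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticCohort", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("cohortMethylation", "SyntheticCohort", function(x) x@meth)

#' @rdname accessors
#' @export
setMethod("cohortExpression", "SyntheticCohort", function(x) x@expr)

setMethod("show", "TadPartition", function(object) {
  gr <- object@partition
  cat("TadPartition with", length(gr), "TADs on",
      length(GenomeInfoDb::seqlengths(gr)), "chromosome(s)\n")
  tab <- table(gr$origin)
  cat("  called-domain:", tab["called-domain"],
      " complement:", tab["complement"], "\n")
  cat("  mean TAD width:", round(mean(BiocGenerics::width(gr))), "bp\n")
})

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels with", length(object@genes), "genes (",
      sum(object@genes$biotype == "protein-coding"), "protein-coding )\n")
})

setMethod("show", "SamResult", function(object) {
  cat("SamResult:", length(object@d), "features,",
      object@nPerm, "permutations\n")
  cat("  s0 =", signif(object@s0, 4), " delta =", signif(object@delta, 4),
      " estimated FDR =", signif(object@fdr, 3), "\n")
  cat("  significant:", nrow(object@significant), "(",
      sum(object@significant$direction == "up"), "up /",
      sum(object@significant$direction == "down"), "down )\n")
})

setMethod("show", "McResult", function(object) {
  cat("McResult [", object@dbp, "]: observed =", object@observed,
      " null =", signif(object@nullMean, 4), "+/-",
      signif(object@nullSd, 4), "\n")
  if (object@degenerate) cat("  degenerate null (sd = 0)\n")
  else cat("  Z =", signif(object@z, 4), "\n")
})

setMethod("show", "SyntheticGenome", function(object) {
  cat("SyntheticGenome:", length(object@chromSizes), "chromosome(s),",
      sum(as.numeric(object@chromSizes)), "bp total\n")
  cat("  ", tadCount(object@tads), "TADs;",
      length(object@genes@genes), "genes;",
      length(object@repeats), "repeat elements;",
      length(object@sites), "CpG sites\n")
  cat("  ", length(object@enhancers), "enhancers;",
      length(object@peaks), "DBP peak sets;",
      nrow(object@ppi), "PPI edges\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", ncol(object@expr), "samples (",
      paste(sprintf("%s=%d", names(table(object@expr$group)),
                    table(object@expr$group)), collapse = ", "), ")\n")
  cat("  ", nrow(object@meth), "methylation sites,",
      nrow(object@expr), "genes,",
      nrow(object@truth$pairs), "planted pairs\n")
})

setMethod("show", "ProjectionResult", function(object) {
  cat("ProjectionResult:", ncol(object@loadings), "components,",
      nrow(object@refScores), "reference and",
      nrow(object@queryScores), "query samples\n")
  cat("  cumulative variance explained:",
      paste(signif(cumsum(object@varExplained), 3), collapse = " "), "\n")
})
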