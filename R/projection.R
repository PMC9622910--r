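# Projection of disease expression profiles onto normal differentiation
# trajectories: rank normalisation, reference-anchored PCA, Manhattan
# distance profiles, distance-SAM and cell-type enrichment.

#' Rank-normalise expression profiles per sample
#'
#' Within each sample (column), values are replaced by their ranks with the
#' highest expression ranked highest; ties receive average ranks.  Any
#' strictly monotone per-sample transform of the input leaves the output
#' unchanged.
#'
#' @param X Gene-by-sample numeric matrix (or expression
#'   `SummarizedExperiment`).
#' @return Rank matrix of the same dimensions.
#' @export
rankNormalize <- function(X) {
  if (is(X, "SummarizedExperiment"))
    X <- SummarizedExperiment::assay(X, "expr")
  apply(X, 2, rank)
}

#' Fit PCA on reference samples and project query samples
#'
#' Principal components are fit on the reference samples only (centering by
#' reference gene means); query samples are then projected with the fitted
#' loadings.  Reference scores reproduce the fit exactly and loadings are
#' orthonormal.
#'
#' @param reference,query Gene-by-sample matrices over the same gene rows
#'   (rank-normalised).
#' @param nComponents Number of components; default: enough to explain 80%
#'   of the reference variance.
#' @return A [ProjectionResult-class].
#' @export
fitAndProject <- function(reference, query, nComponents = NULL) {
  if (!identical(nrow(reference), nrow(query)))
    stop("reference and query need identical gene rows")
  maxComp <- min(dim(reference))
  if (!is.null(nComponents) && nComponents > maxComp)
    stop("nComponents exceeds the matrix rank bound")
  ctr <- rowMeans(reference)
  Rc <- t(reference - ctr)            # samples x genes
  sv <- svd(Rc)
  varExp <- sv$d^2 / sum(sv$d^2)
  k <- if (is.null(nComponents))
    max(1L, which(cumsum(varExp) >= 0.8)[1L])
  else as.integer(nComponents)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- rownames(reference)
  colnames(loadings) <- paste0("PC", seq_len(k))
  refScores <- Rc %*% loadings
  queryScores <- t(query - ctr) %*% loadings
  rownames(refScores) <- colnames(reference)
  rownames(queryScores) <- colnames(query)
  new("ProjectionResult", loadings = loadings, center = ctr,
      refScores = refScores, queryScores = queryScores,
      varExplained = varExp[seq_len(k)])
}

#' Manhattan distance profiles between query and reference samples
#'
#' Computes the reference-by-query matrix of Manhattan distances on the
#' supplied (rank-normalised) matrices, plus a centred variant in which
#' each query column has median zero across references.
#'
#' @param reference,query Gene-by-sample matrices over identical gene rows.
#' @return `list(raw =, centered =)`, both reference-by-query matrices.
#' @export
distanceProfile <- function(reference, query) {
  if (!identical(nrow(reference), nrow(query)))
    stop("reference and query need identical gene rows")
  raw <- matrix(vapply(seq_len(ncol(query)), function(j)
    colSums(abs(reference - query[, j])), numeric(ncol(reference))),
    nrow = ncol(reference),
    dimnames = list(colnames(reference), colnames(query)))
  centered <- sweep(raw, 2, apply(raw, 2, median))
  list(raw = raw, centered = centered)
}

#' Distance-SAM between query groups with cell-type enrichment
#'
#' Treats reference samples as features and query samples as observations
#' of the centred distance profile, finds reference samples whose distance
#' differs significantly between the two query groups (SAM, direction
#' `closer` = smaller distance to the second group), and tests each
#' reference cell type for enrichment within each direction by one-sided
#' hypergeometric tests over all reference samples, BH-corrected.
#'
#' @param profile Output of [distanceProfile()] (the `centered` matrix is
#'   used).
#' @param queryGroups Character vector, one label per query sample; exactly
#'   two distinct labels with at least two samples each.  `closer`
#'   direction refers to the second sorted label unless `contrast` fixes
#'   the order.
#' @param cellTypes Character vector, one cell-type label per reference
#'   sample.
#' @param contrast Optional length-2 character fixing (class1, class2).
#' @param nPerm,fdrTarget,seed Passed to [samTwoClass()].
#' @return `list(sam =, closer =, further =, enrichment = data.frame)`.
#' @export
distanceSamAndEnrichment <- function(profile, queryGroups, cellTypes,
                                     contrast = NULL, nPerm = 1000L,
                                     fdrTarget = 0.05, seed = 1L) {
  D <- profile$centered
  if (length(queryGroups) != ncol(D))
    stop("one query-group label per query sample is required")
  lv <- if (is.null(contrast)) sort(unique(queryGroups)) else contrast
  if (length(lv) != 2) stop("exactly two query groups are required")
  if (any(table(factor(queryGroups, levels = lv)) < 2))
    stop("each query group needs at least 2 samples")
  sam <- samTwoClass(D, factor(queryGroups, levels = lv), nPerm = nPerm,
                     fdrTarget = fdrTarget, seed = seed)
  sig <- sam@significant
  # d > 0: larger distance to group 2 => further from it
  further <- sig$feature[sig$direction == "up"]
  closer <- sig$feature[sig$direction == "down"]
  ct <- setNames(cellTypes, rownames(D))
  enr <- NULL
  for (dir in c("closer", "further")) {
    set <- if (dir == "closer") closer else further
    if (length(set) < 1) next
    if (length(unique(ct[set])) < 2 && length(unique(ct)) > 1) {
      enr <- rbind(enr, data.frame(
        direction = dir, cell_type = unique(ct[set]),
        observed = length(set), expected = NA_real_, fold = NA_real_,
        p = NA_real_, flagged = TRUE, stringsAsFactors = FALSE))
      next
    }
    for (tp in unique(cellTypes)) {
      he <- hyperEnrichment(sum(ct[set] == tp), sum(cellTypes == tp),
                            length(set), length(cellTypes))
      enr <- rbind(enr, data.frame(
        direction = dir, cell_type = tp, observed = he$observed,
        expected = he$expected, fold = he$fold, p = he$p,
        flagged = FALSE, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(enr)) enr$q <- ifelse(is.na(enr$p), NA, bhFdr(enr$p))
  list(sam = sam, closer = closer, further = further, enrichment = enr)
}
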