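# Cohort generator: planted within-TAD expression-methylation modules with
# genotype-group-specific methylation distributions, plus the hematopoietic
# differentiation series.

#' Default cohort design
#'
#' Group sizes follow the discovery cohort layout (16 DNMT3A, 9 IDH1/2, 11
#' double-mutant samples; WT samples are added only for the cohort-comparison
#' analysis).  Driver-site methylation is drawn per genotype group
#' (DNMT3A low `Beta(2,8)`, IDH high `Beta(8,2)`, double-mutant intermediate
#' `Beta(5,5)`, WT intermediate with doubled dispersion `Beta(2.25,2.25)`);
#' regulated-gene log2 expression follows
#' \eqn{\alpha + \beta m + \epsilon} with the noise SD calibrated so planted
#' pairs reach the target Spearman magnitude (default 0.8).  The planted
#' effect sign is negative for 98.5% of regulated genes.
#'
#' @return Named list of design settings for [generateCohort()].
#' @export
defaultCohortDesign <- function() {
  list(
    groupSizes = c(DNMT3A = 16L, IDH = 9L, DOUBLE = 11L, WT = 0L),
    groupBeta = list(DNMT3A = c(2, 8), IDH = c(8, 2), DOUBLE = c(5, 5),
                     WT = c(2.25, 2.25)),
    plantedPairFraction = 0.10,
    plantedRho = 0.8,
    positiveBetaFraction = 0.015,
    betaMagnitude = 3,
    wtBeta = 0,
    alphaMean = 5, alphaSd = 1, noiseSdNull = 1,
    siteJitterSd = 0.05,
    driverEnhancerMirFraction = 0.2,
    siteConcentration = 30,
    coverageFloor = 10L, coverageLambda = 40,
    dropoutFraction = 0.03)
}

# First-TAD assignment for planting (features fully inside one TAD map to
# it; boundary-spanning features use their 5'-most TAD).
.firstTad <- function(gr, part) {
  h <- GenomicRanges::findOverlaps(gr, part)
  keep <- !duplicated(S4Vectors::queryHits(h))
  out <- rep(NA_character_, length(gr))
  out[S4Vectors::queryHits(h)[keep]] <-
    part$tad_id[S4Vectors::subjectHits(h)[keep]]
  out
}

#' Generate a synthetic methylation + expression cohort with ground truth
#'
#' One regulatory module is planted per TAD: a per-sample latent methylation
#' level drawn from the genotype-group Beta distributions drives both the
#' module's driver CpG sites (latent plus small jitter) and the regulated
#' genes' log2 expression.  Every (regulated gene, driver site) combination
#' within the TAD is a planted pair; selecting
#' \eqn{\sqrt{f}} of the genes and of the sites per TAD yields a planted
#' fraction \eqn{f} of within-TAD pairs.  All other sites and genes are
#' mutually independent noise.
#'
#' @param genome A [SyntheticGenome-class].
#' @param design List from [defaultCohortDesign()], possibly modified.
#' @param seed Integer RNG seed.
#' @return A [SyntheticCohort-class]; `groundTruth(x)$pairs` lists every
#'   planted pair with its effect coefficient and sign.
#' @export
generateCohort <- function(genome, design = defaultCohortDesign(),
                           seed = 1L) {
  stopifnot(is(genome, "SyntheticGenome"))
  des <- design
  f <- des$plantedPairFraction
  if (f < 0 || f > 1)
    stop("design error: planted-pair fraction must lie in [0,1]")
  withSeed(seed, {
    gs <- des$groupSizes[des$groupSizes > 0]
    groups <- rep(names(gs), gs)
    n <- length(groups)
    samples <- sprintf("S%02d", seq_len(n))
    part <- tadRanges(genome@tads)
    sites <- genome@sites
    bodies <- geneBodies(genome@genes)
    ids <- bodies$gene_id
    siteTad <- .firstTad(sites, part)
    geneTad <- .firstTad(bodies, part)

    meth <- matrix(NA_real_, length(sites), n,
                   dimnames = list(sites$site_id, samples))
    logexpr <- matrix(NA_real_, length(ids), n,
                      dimnames = list(ids, samples))
    alpha <- rnorm(length(ids), des$alphaMean, des$alphaSd)
    isWt <- groups == "WT"

    gFrac <- sqrt(f)
    pairList <- list()
    regulated <- character(0)
    drivers <- character(0)
    for (tid in if (f > 0) unique(geneTad) else character(0)) {
      gIdx <- which(geneTad == tid)
      sIdx <- which(siteTad == tid)
      nGsel <- round(gFrac * length(gIdx))
      nSsel <- round(gFrac * length(sIdx))
      if (nGsel < 1 || nSsel < 1) next
      # regulated genes: prefer the regulatable protein-coding class
      w <- ifelse(genome@geneClass[ids[gIdx]] == "regulatable", 10, 1) *
        ifelse(bodies$biotype[gIdx] == "protein-coding", 1, 0.2)
      gSel <- gIdx[sample.int(length(gIdx), nGsel, prob = w)]
      # driver sites: a configured share from MIR-overlapping enhancers
      elig <- sites$on_mir[sIdx] & sites$on_enhancer[sIdx]
      nElig <- min(sum(elig), round(nSsel * des$driverEnhancerMirFraction))
      sSel <- integer(0)
      if (nElig > 0)
        sSel <- sIdx[elig][sample.int(sum(elig), nElig)]
      rest <- setdiff(sIdx, sSel)
      sSel <- c(sSel, rest[sample.int(length(rest), nSsel - nElig)])

      # latent methylation level per sample
      u <- numeric(n)
      for (g in unique(groups)) {
        p <- des$groupBeta[[g]]
        u[groups == g] <- rbeta(sum(groups == g), p[1], p[2])
      }
      # driver sites track the latent with small jitter
      meth[sSel, ] <- pmin(1 - 1e-3, pmax(1e-3,
        rep(u, each = length(sSel)) +
          rnorm(length(sSel) * n, 0, des$siteJitterSd)))
      # regulated genes: noise calibrated to the target pair |rho|
      su <- sd(u)
      rhoSite <- su / sqrt(su^2 + des$siteJitterSd^2)
      rhoGene <- min(0.98, des$plantedRho / rhoSite)
      noiseSd <- if (des$betaMagnitude == 0) des$noiseSdNull
                 else des$betaMagnitude * su * sqrt(1 / rhoGene^2 - 1)
      sign_ <- ifelse(runif(length(gSel)) < des$positiveBetaFraction,
                      1, -1)
      beta <- sign_ * des$betaMagnitude
      betaEff <- outer(beta, rep(1, n))
      if (any(isWt)) betaEff[, isWt] <- des$wtBeta * sign_
      # centre the methylation term so a gene's mean expression (and hence
      # its survival of the top-expression filter) is independent of the
      # effect sign
      logexpr[gSel, ] <- alpha[gSel] + betaEff *
        rep(u - mean(u), each = length(gSel)) +
        rnorm(length(gSel) * n, 0, noiseSd)

      pairList[[tid]] <- data.table::CJ(gene_id = ids[gSel],
                                        site_id = sites$site_id[sSel])
      pairList[[tid]]$tad_id <- tid
      pairList[[tid]]$beta <- rep(beta[order(ids[gSel])],
                                  each = length(sSel))
      regulated <- c(regulated, ids[gSel])
      drivers <- c(drivers, sites$site_id[sSel])
    }
    if (f > 0 && !length(pairList))
      stop("design error: no within-TAD pairs available for planting")

    # null sites: site-specific level, independent across sites
    nullSites <- which(!sites$site_id %in% drivers)
    m0 <- rbeta(length(nullSites), 2, 2)
    k <- des$siteConcentration
    meth[nullSites, ] <- rbeta(length(nullSites) * n,
                               rep(m0 * k, n), rep((1 - m0) * k, n))
    # null genes
    nullGenes <- which(!ids %in% regulated)
    logexpr[nullGenes, ] <- alpha[nullGenes] +
      rnorm(length(nullGenes) * n, 0, des$noiseSdNull)

    cov <- matrix(des$coverageFloor +
                    rpois(length(sites) * n, des$coverageLambda),
                  length(sites), n, dimnames = dimnames(meth))
    dropout <- which(runif(length(sites)) < des$dropoutFraction)
    if (length(dropout))
      cov[cbind(dropout, sample.int(n, length(dropout),
                                    replace = TRUE))] <-
        rpois(length(dropout), des$coverageFloor - 2)

    pairs <- if (length(pairList))
      as.data.frame(data.table::rbindlist(pairList))
    else data.frame(gene_id = character(0), site_id = character(0),
                    tad_id = character(0), beta = numeric(0))
    pairs$sign <- ifelse(pairs$beta > 0, "positive", "negative")
    truth <- list(pairs = pairs,
                  regulated = unique(regulated),
                  driverSites = unique(drivers),
                  bridgePairs = data.frame(
                    protein_a = genome@config$bridgePair[1],
                    protein_b = genome@config$bridgePair[2],
                    stringsAsFactors = FALSE),
                  dbpTargets = genome@config$dbpTargets,
                  design = des, seed = seed)

    methSet <- MethylationSet(sites, meth, cov, group = groups)
    exprSe <- ExpressionMatrix(2^logexpr, group = groups,
                               biotype = bodies$biotype)
    new("SyntheticCohort", meth = methSet, expr = exprSe, truth = truth)
  })
}

#' Cell types and lineage grouping of the differentiation series
#'
#' @return `data.frame` with columns `cell_type` and `lineage`
#'   (HSC / progenitor / myeloid / erythroid / lymphoid).
#' @export
lineageMap <- function() {
  data.frame(
    cell_type = c("HSC", "CMP", "GMP", "MEP", "Mega", "Ery", "Gran",
                  "Mono", "Eosin", "Baso", "Dendritic", "B", "T", "NK",
                  "NKT"),
    lineage = c("HSC", "progenitor", "progenitor", "progenitor",
                "erythroid", "erythroid", "myeloid", "myeloid", "myeloid",
                "myeloid", "myeloid", "lymphoid", "lymphoid", "lymphoid",
                "lymphoid"),
    stringsAsFactors = FALSE)
}

#' Default configuration for the differentiation series
#'
#' 211 samples over 15 hematopoietic cell types (the HSC root gets the odd
#' sample), 10% of genes differentially expressed per non-root type, with
#' upregulated genes drawn from the regulatable architecture class at a
#' configurable odds ratio.
#'
#' @return Named list of settings for [generateDifferentiationSeries()].
#' @export
defaultSeriesConfig <- function() {
  list(cellTypes = lineageMap()$cell_type,
       nSamples = 211L,
       deFraction = 0.10,
       regOddsRatio = 4,
       shift = 2,
       noiseSd = 0.7,
       baseMean = 6, baseSd = 1)
}

#' Generate a cell-type-labelled differentiation expression series
#'
#' Emulates a sorted-population hematopoiesis compendium: each non-root
#' cell type shifts a fraction of genes up or down relative to the HSC root
#' profile, with upregulated genes preferentially drawn from the
#' regulatable (MIR-dense) class at `regOddsRatio`.
#'
#' @param genome A [SyntheticGenome-class].
#' @param config List from [defaultSeriesConfig()].
#' @param seed Integer RNG seed.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay `expr`,
#'   `colData(x)$group` = cell type, and
#'   `metadata(x)$deSets` = per-type ground-truth up/down gene sets.
#' @export
generateDifferentiationSeries <- function(genome,
                                          config = defaultSeriesConfig(),
                                          seed = 1L) {
  cfg <- config
  if (length(cfg$cellTypes) < 2)
    stop("design error: need at least 2 cell types")
  withSeed(seed, {
    ids <- geneBodies(genome@genes)$gene_id
    nG <- length(ids)
    nT <- length(cfg$cellTypes)
    base <- cfg$nSamples %/% nT
    sizes <- rep(base, nT)
    sizes[seq_len(cfg$nSamples - base * nT)] <-
      sizes[seq_len(cfg$nSamples - base * nT)] + 1L
    types <- rep(cfg$cellTypes, sizes)
    root <- cfg$cellTypes[1]
    baseProfile <- rnorm(nG, cfg$baseMean, cfg$baseSd)
    regW <- ifelse(genome@geneClass[ids] == "regulatable",
                   cfg$regOddsRatio, 1)
    deSets <- list()
    shiftMat <- matrix(0, nG, nT, dimnames = list(ids, cfg$cellTypes))
    nDE <- round(cfg$deFraction * nG)
    for (tp in cfg$cellTypes[-1]) {
      if (nDE > 0) {
        up <- sample.int(nG, ceiling(nDE / 2), prob = regW)
        down <- sample(setdiff(seq_len(nG), up), floor(nDE / 2),
                       prob = (1 / regW)[setdiff(seq_len(nG), up)])
        shiftMat[up, tp] <- cfg$shift
        shiftMat[down, tp] <- -cfg$shift
        deSets[[tp]] <- list(up = ids[up], down = ids[down])
      } else {
        deSets[[tp]] <- list(up = character(0), down = character(0))
      }
    }
    log2e <- shiftMat[, types] + baseProfile +
      rnorm(nG * length(types), 0, cfg$noiseSd)
    colnames(log2e) <- sprintf("N%03d", seq_along(types))
    se <- ExpressionMatrix(2^log2e, group = types)
    S4Vectors::metadata(se)$deSets <- deSets
    S4Vectors::metadata(se)$lineage <- lineageMap()
    S4Vectors::metadata(se)$seed <- seed
    se
  })
}
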