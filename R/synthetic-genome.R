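# Synthetic genome generator: TADs, gene models with architecture classes,
# repeat elements, CpG sites/islands, enhancers, GC and conservation tracks,
# DBP peak sets, a PPI edge list, and sequence under repeat footprints.

#' Default configuration for the synthetic genome
#'
#' Values emulate the study conditions the pipeline targets: called domains
#' with a 1.4 Mb mean, genes split into a `regulatable` class (GC-rich,
#' evolutionarily neutral, MIR-dense introns) and an `independent` class
#' with the opposite architecture, CpG sites partly on MIR elements and
#' enhancers, and a DBP roster containing one planted site-binding /
#' gene-binding bridge pair.
#'
#' @return A named list of generator settings; override entries and pass to
#'   [generateGenome()].
#' @export
defaultGenomeConfig <- function() {
  list(
    chromSizes = c(chr1 = 10000000L, chr2 = 10000000L),
    tadMeanLength = 1400000, tadShape = 4, calledFraction = 0.9,
    tadGap = c(500, 5000),
    nGenes = 200L, regulatableFraction = 0.5, mirZeroFraction = 0.3,
    codingFraction = 0.85,
    exonsPerGene = c(3L, 8L), exonLength = c(100, 300),
    intronLength = c(2000, 12000),
    mirDensity = c(regulatable = 0.10, independent = 0.02),
    aluDensity = c(regulatable = 0.03, independent = 0.05),
    l1Density = c(regulatable = 0.01, independent = 0.01),
    mirLength = c(130, 260), aluLength = c(280, 320),
    l1Length = c(500, 6000),
    intergenicRepeatsPerMb = 30,
    trackBin = 200L,
    gcExon = 0.52, gcIntron = c(regulatable = 0.55, independent = 0.45),
    gcIntergenic = 0.42, gcSd = 0.02,
    consExon = 1.5, consIntron = c(regulatable = 0.0, independent = 0.8),
    consIntergenic = 0.1, consSd = 0.3,
    nSites = 2000L, siteMirFraction = 0.20, siteEnhancerFraction = 0.15,
    siteEnhancerMirFraction = 0.10,
    nIslands = 40L, islandSites = c(4L, 12L), islandSpan = 2000L,
    nEnhancers = 250L, enhancerLength = c(500, 2000),
    enhancerMirFraction = 0.3,
    dbpCount = 8L, peaksPerDbp = 300L, peakLength = 200L,
    bridgeTadFraction = 0.5, bridgeSiteCoverage = 0.8,
    bridgeGeneCoverage = 0.8, backgroundBindFraction = 0.1,
    nPpiEdges = 20L,
    mirBboxFraction = 0.3)
}

.randomSeq <- function(n) {
  vapply(n, function(len)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

.truncNorm <- function(n, mean, sd, lo = -Inf, hi = Inf)
  pmin(hi, pmax(lo, rnorm(n, mean, sd)))

# Tile one chromosome with domain calls of the configured mean length,
# separated by small gaps; a fraction of tiles is dropped so the partition
# also contains complement-origin TADs.
.drawDomains <- function(chromLen, cfg) {
  starts <- integer(0); ends <- integer(0)
  pos <- 1
  while (pos < chromLen - 200000) {
    len <- round(min(3e6, max(2e5,
      rgamma(1, shape = cfg$tadShape,
             scale = cfg$tadMeanLength / cfg$tadShape))))
    end <- min(pos + len - 1, chromLen)
    starts <- c(starts, pos); ends <- c(ends, end)
    pos <- end + 1 + round(runif(1, cfg$tadGap[1], cfg$tadGap[2]))
  }
  keep <- runif(length(starts)) < cfg$calledFraction
  list(start = starts[keep], end = ends[keep])
}

# Place nGenes non-overlapping gene spans strictly inside called TADs.
.placeGenes <- function(part, cfg) {
  called <- part[part$origin == "called-domain"]
  spans <- list()
  occupied <- GenomicRanges::GRanges()
  meanSpan <- mean(cfg$exonsPerGene) * mean(cfg$exonLength) +
    (mean(cfg$exonsPerGene) - 1) * mean(cfg$intronLength)
  if (cfg$nGenes * meanSpan > 0.8 * sum(as.numeric(BiocGenerics::width(called))))
    stop("capacity error: requested gene count infeasible for genome size")
  for (i in seq_len(cfg$nGenes)) {
    placed <- FALSE
    for (try in 1:50) {
      nEx <- sample(cfg$exonsPerGene[1]:cfg$exonsPerGene[2], 1)
      exLen <- round(runif(nEx, cfg$exonLength[1], cfg$exonLength[2]))
      inLen <- if (nEx > 1)
        round(runif(nEx - 1, cfg$intronLength[1], cfg$intronLength[2]))
      else integer(0)
      span <- sum(exLen) + sum(inLen)
      tad <- called[sample.int(length(called), 1,
                               prob = BiocGenerics::width(called))]
      if (BiocGenerics::width(tad) < span + 2) next
      gStart <- BiocGenerics::start(tad) +
        sample.int(BiocGenerics::width(tad) - span, 1) - 1L
      cand <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(tad),
                                     IRanges::IRanges(gStart,
                                                      gStart + span - 1L))
      if (length(occupied) &&
          length(GenomicRanges::findOverlaps(cand, occupied)) > 0) next
      exStart <- gStart + cumsum(c(0L, head(exLen, -1) + inLen))
      spans[[i]] <- list(chrom = as.character(GenomeInfoDb::seqnames(tad)),
                         exStart = exStart, exEnd = exStart + exLen - 1L,
                         strand = sample(c("+", "-"), 1))
      occupied <- c(occupied, cand)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("capacity error: could not place all genes; genome too small")
  }
  spans
}

# Non-overlapping repeats inside one interval, hitting a target density by
# the slot method: the interval is split into equal slots, one element per
# slot at a random offset.
.placeRepeatsIn <- function(chrom, start, end, density, lenRange, family) {
  width <- end - start + 1
  meanLen <- mean(lenRange)
  nElem <- round(width * density / meanLen)
  if (nElem < 1) return(NULL)
  slot <- width / nElem
  len <- pmin(round(runif(nElem, lenRange[1], lenRange[2])),
              floor(slot) - 1)
  len <- pmax(len, 10L)
  off <- floor(runif(nElem, 0, slot - len))
  s <- start + round((seq_len(nElem) - 1) * slot) + off
  data.table(chrom = chrom, start = s, end = s + len - 1L, family = family)
}

.repeatSubfamily <- function(family, n) {
  pool <- switch(family,
                 MIR = c("MIR", "MIRb", "MIRc", "MIR3"),
                 Alu = c("AluJb", "AluSx", "AluY"),
                 L1 = c("L1M", "L1PA", "L1HS"),
                 "other")
  sample(pool, n, replace = TRUE)
}

.repeatDivergence <- function(family, n) {
  mean <- switch(family, MIR = 30, Alu = 12, L1 = 20, 15)
  .truncNorm(n, mean, mean / 5, lo = 0.5)
}

# Category track over fixed-width bins: exon / intron-by-class / intergenic
# means with Gaussian jitter.
.makeTrack <- function(chromSizes, bin, exons, intronsReg, intronsInd,
                       means, sd) {
  tiles <- GenomicRanges::tileGenome(chromSizes, tilewidth = bin,
                                     cut.last.tile.in.chrom = TRUE)
  cat_ <- rep("intergenic", length(tiles))
  cat_[S4Vectors::queryHits(
    GenomicRanges::findOverlaps(tiles, intronsInd))] <- "intronInd"
  cat_[S4Vectors::queryHits(
    GenomicRanges::findOverlaps(tiles, intronsReg))] <- "intronReg"
  cat_[S4Vectors::queryHits(
    GenomicRanges::findOverlaps(tiles, exons))] <- "exon"
  tiles$score <- rnorm(length(tiles), means[cat_], sd)
  tiles
}

#' Generate a synthetic genome with planted regulatory architecture
#'
#' Deterministic for a fixed `(config, seed)` pair.  Regulatable-class genes
#' receive MIR-dense, GC-rich, evolutionarily neutral introns; independent
#' genes the opposite, with a configurable fraction carrying no MIR at all
#' (the MIR-zero pool).  CpG sites are placed partly on MIR elements and on
#' enhancers; enhancers partly overlap MIRs.  Two roster proteins (`DBP_A`,
#' `DBP_B`) form a planted bridge: in a random half of the TADs `DBP_A`
#' covers driver-eligible CpG sites and `DBP_B` the intronic MIRs of
#' regulatable genes.
#'
#' @param config List from [defaultGenomeConfig()], possibly modified.
#' @param seed Integer RNG seed.
#' @return A [SyntheticGenome-class].
#' @export
generateGenome <- function(config = defaultGenomeConfig(), seed = 1L) {
  cfg <- config
  withSeed(seed, {
    chromSizes <- setNames(as.integer(cfg$chromSizes),
                           names(cfg$chromSizes))
    doms <- lapply(names(chromSizes), function(ch) {
      d <- .drawDomains(chromSizes[[ch]], cfg)
      if (!length(d$start)) return(NULL)
      data.table(chrom = ch, start = d$start, end = d$end)
    })
    doms <- data.table::rbindlist(doms)
    domains <- grangesOn(doms$chrom, doms$start, doms$end, chromSizes)
    tads <- buildTadPartition(domains, chromSizes)

    ## gene models
    spans <- .placeGenes(tadRanges(tads), cfg)
    ids <- sprintf("gene_%03d", seq_along(spans))
    exDt <- data.table::rbindlist(lapply(seq_along(spans), function(i)
      data.table(chrom = spans[[i]]$chrom, start = spans[[i]]$exStart,
                 end = spans[[i]]$exEnd, strand = spans[[i]]$strand,
                 gene_id = ids[i])))
    exGr <- grangesOn(exDt$chrom, exDt$start, exDt$end, chromSizes,
                      strand = exDt$strand, gene_id = exDt$gene_id)
    nReg <- round(cfg$nGenes * cfg$regulatableFraction)
    geneClass <- setNames(
      sample(c(rep("regulatable", nReg),
               rep("independent", cfg$nGenes - nReg))), ids)
    mirZero <- names(geneClass)[geneClass == "independent"]
    mirZero <- sample(mirZero, round(length(mirZero) * cfg$mirZeroFraction))
    biotype <- setNames(ifelse(runif(cfg$nGenes) < cfg$codingFraction,
                               "protein-coding", "non-coding"), ids)
    genes <- GeneModels(exGr, biotype = unname(biotype[ids]))

    ## repeats: intronic per class target + intergenic background
    introns <- intronsByGene(genes)
    intronDt <- as.data.table(BiocGenerics::unlist(introns))
    intronDt$gene_id <- rep(names(introns),
                            S4Vectors::elementNROWS(introns))
    repList <- list()
    famCfg <- list(MIR = list(d = cfg$mirDensity, l = cfg$mirLength),
                   Alu = list(d = cfg$aluDensity, l = cfg$aluLength),
                   L1 = list(d = cfg$l1Density, l = cfg$l1Length))
    for (i in seq_len(nrow(intronDt))) {
      g <- intronDt$gene_id[i]
      cls <- geneClass[[g]]
      for (fam in names(famCfg)) {
        dens <- famCfg[[fam]]$d[[cls]]
        if (fam == "MIR" && g %in% mirZero) dens <- 0
        r <- .placeRepeatsIn(as.character(intronDt$seqnames[i]),
                             intronDt$start[i], intronDt$end[i],
                             dens, famCfg[[fam]]$l, fam)
        if (!is.null(r)) repList[[length(repList) + 1L]] <- r
      }
    }
    ## intergenic repeats, kept off gene bodies (and off MIR-zero genes)
    for (ch in names(chromSizes)) {
      n <- round(cfg$intergenicRepeatsPerMb * chromSizes[[ch]] / 1e6)
      fam <- sample(c("MIR", "Alu", "L1"), n, replace = TRUE,
                    prob = c(0.4, 0.4, 0.2))
      len <- numeric(n)
      for (f in c("MIR", "Alu", "L1"))
        len[fam == f] <- round(runif(sum(fam == f), famCfg[[f]]$l[1],
                                     famCfg[[f]]$l[2]))
      s <- round(runif(n, 1, chromSizes[[ch]] - max(len)))
      cand <- data.table(chrom = ch, start = s, end = s + len - 1L,
                         family = fam)
      gr <- grangesOn(cand$chrom, cand$start, cand$end, chromSizes)
      drop <- S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr, geneBodies(genes)))
      if (length(drop)) cand <- cand[-unique(drop)]
      repList[[length(repList) + 1L]] <- cand
    }
    repDt <- data.table::rbindlist(repList)
    repeats <- grangesOn(repDt$chrom, repDt$start, repDt$end, chromSizes,
                         strand = sample(c("+", "-"), nrow(repDt),
                                         replace = TRUE))
    repeats$family <- repDt$family
    repeats$repeat_id <- sprintf("rep_%05d", seq_along(repeats))
    repeats$subfamily <- repeats$family
    repeats$divergence <- NA_real_
    for (f in unique(repeats$family)) {
      idx <- which(repeats$family == f)
      repeats$subfamily[idx] <- .repeatSubfamily(f, length(idx))
      repeats$divergence[idx] <- .repeatDivergence(f, length(idx))
    }

    ## enhancers: a fraction centred on MIR elements
    nEnhMir <- round(cfg$nEnhancers * cfg$enhancerMirFraction)
    mirs <- repeats[repeats$family == "MIR"]
    eLen <- round(runif(cfg$nEnhancers, cfg$enhancerLength[1],
                        cfg$enhancerLength[2]))
    anchorsMir <- mirs[sample.int(length(mirs), nEnhMir)]
    eChrom <- c(as.character(GenomeInfoDb::seqnames(anchorsMir)),
                sample(names(chromSizes), cfg$nEnhancers - nEnhMir,
                       replace = TRUE))
    eMid <- c(round((BiocGenerics::start(anchorsMir) +
                       BiocGenerics::end(anchorsMir)) / 2),
              round(runif(cfg$nEnhancers - nEnhMir, max(eLen),
                          chromSizes[eChrom[-seq_len(nEnhMir)]] -
                            max(eLen))))
    eStart <- pmax(1L, eMid - round(eLen / 2))
    eEnd <- pmin(unname(chromSizes[eChrom]), eStart + eLen - 1L)
    enhancers <- GenomicRanges::sort(
      grangesOn(eChrom, eStart, eEnd, chromSizes))
    enhancers$enhancer_id <- sprintf("enh_%04d", seq_along(enhancers))

    ## CpG sites: islands + MIR-resident + enhancer-resident + uniform
    islandK <- sample(cfg$islandSites[1]:cfg$islandSites[2], cfg$nIslands,
                      replace = TRUE)
    islChrom <- sample(names(chromSizes), cfg$nIslands, replace = TRUE)
    islStart <- round(runif(cfg$nIslands, 1,
                            chromSizes[islChrom] - cfg$islandSpan))
    islands <- grangesOn(islChrom, islStart,
                         islStart + cfg$islandSpan - 1L, chromSizes)
    islands$island_id <- sprintf("cgi_%03d", seq_along(islands))
    posIsl <- data.table(
      chrom = rep(islChrom, islandK),
      pos = unlist(lapply(seq_len(cfg$nIslands), function(i)
        islStart[i] + sort(sample.int(cfg$islandSpan, islandK[i])) - 1L)))
    nFree <- cfg$nSites - nrow(posIsl)
    nMir <- round(cfg$nSites * cfg$siteMirFraction)
    nEnh <- round(cfg$nSites * cfg$siteEnhancerFraction)
    pickWithin <- function(gr, n) {
      idx <- sample.int(length(gr), n, replace = TRUE,
                        prob = BiocGenerics::width(gr))
      data.table(
        chrom = as.character(GenomeInfoDb::seqnames(gr))[idx],
        pos = BiocGenerics::start(gr)[idx] +
          floor(runif(n) * BiocGenerics::width(gr)[idx]))
    }
    posMir <- pickWithin(mirs, nMir)
    posEnh <- pickWithin(enhancers, nEnh)
    # driver-eligible sites: placed directly on enhancer/MIR intersections
    emInt <- GenomicRanges::intersect(enhancers, mirs,
                                      ignore.strand = TRUE)
    nEM <- if (length(emInt))
      round(cfg$nSites * cfg$siteEnhancerMirFraction) else 0L
    posEM <- if (nEM > 0) pickWithin(emInt, nEM) else NULL
    nUnif <- max(0L, nFree - nMir - nEnh - nEM)
    uChrom <- sample(names(chromSizes), nUnif, replace = TRUE)
    posUnif <- data.table(chrom = uChrom,
                          pos = 1L + floor(runif(nUnif) *
                                             (chromSizes[uChrom] - 1)))
    pos <- unique(data.table::rbindlist(
      list(posIsl, posMir, posEnh, posEM, posUnif)))
    sites <- GenomicRanges::sort(
      grangesOn(pos$chrom, pos$pos, pos$pos, chromSizes))
    sites$site_id <- sprintf("site_%05d", seq_along(sites))
    sites$on_mir <- GenomicRanges::countOverlaps(sites, mirs) > 0
    sites$on_enhancer <- GenomicRanges::countOverlaps(sites, enhancers) > 0

    ## tracks
    exAll <- BiocGenerics::unlist(exonsByGene(genes))
    intAll <- BiocGenerics::unlist(introns)
    intGene <- rep(names(introns), S4Vectors::elementNROWS(introns))
    intReg <- intAll[geneClass[intGene] == "regulatable"]
    intInd <- intAll[geneClass[intGene] == "independent"]
    gcTrack <- .makeTrack(chromSizes, cfg$trackBin, exAll, intReg, intInd,
                          c(exon = cfg$gcExon,
                            intronReg = cfg$gcIntron[["regulatable"]],
                            intronInd = cfg$gcIntron[["independent"]],
                            intergenic = cfg$gcIntergenic), cfg$gcSd)
    gcTrack$score <- pmin(0.95, pmax(0.05, gcTrack$score))
    consTrack <- .makeTrack(chromSizes, cfg$trackBin, exAll, intReg, intInd,
                            c(exon = cfg$consExon,
                              intronReg = cfg$consIntron[["regulatable"]],
                              intronInd = cfg$consIntron[["independent"]],
                              intergenic = cfg$consIntergenic), cfg$consSd)

    ## DBP peaks with one planted bridge pair
    part <- tadRanges(tads)
    called <- part[part$origin == "called-domain"]
    bridgeTads <- sample(called$tad_id,
                         round(length(called) * cfg$bridgeTadFraction))
    bridgeRanges <- part[part$tad_id %in% bridgeTads]
    siteTad <- part$tad_id[S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(sites, part))]
    eligible <- sites$on_mir & sites$on_enhancer
    inBridge <- siteTad %in% bridgeTads
    pw <- cfg$peakLength
    peakOn <- function(gr, frac) {
      pick <- which(runif(length(gr)) < frac)
      if (!length(pick)) return(GenomicRanges::GRanges())
      mid <- round((BiocGenerics::start(gr)[pick] +
                      BiocGenerics::end(gr)[pick]) / 2)
      chr <- as.character(GenomeInfoDb::seqnames(gr))[pick]
      s <- pmax(1L, mid - pw %/% 2)
      grangesOn(chr, s, pmin(unname(chromSizes[chr]), s + pw - 1L),
                chromSizes)
    }
    uniformPeaks <- function(n) {
      chr <- sample(names(chromSizes), n, replace = TRUE)
      s <- 1L + floor(runif(n) * (chromSizes[chr] - pw))
      grangesOn(chr, s, s + pw - 1L, chromSizes)
    }
    # DBP_A binds driver-eligible sites inside bridge TADs
    peakA <- c(peakOn(sites[eligible & inBridge], cfg$bridgeSiteCoverage),
               peakOn(sites[eligible & !inBridge],
                      cfg$backgroundBindFraction),
               uniformPeaks(cfg$peaksPerDbp %/% 3))
    # DBP_B binds intronic MIRs of regulatable genes in bridge TADs
    gh <- GenomicRanges::findOverlaps(geneBodies(genes), part)
    firstHit <- !duplicated(S4Vectors::queryHits(gh))
    geneTad <- rep(NA_character_, length(ids))
    geneTad[S4Vectors::queryHits(gh)[firstHit]] <-
      part$tad_id[S4Vectors::subjectHits(gh)[firstHit]]
    regGenes <- ids[geneClass == "regulatable"]
    intMirHits <- GenomicRanges::findOverlaps(mirs, intAll)
    mirGene <- intGene[S4Vectors::subjectHits(intMirHits)]
    mirIdx <- S4Vectors::queryHits(intMirHits)
    bridgeGenes <- intersect(regGenes,
                             ids[geneTad %in% bridgeTads])
    # gene-level coverage: one peak on a random intronic MIR of each
    # covered gene (per-element coverage would saturate MIR-rich genes)
    coverGenes <- function(geneIds, frac) {
      pick <- geneIds[runif(length(geneIds)) < frac]
      hit <- unlist(lapply(pick, function(gg) {
        cand <- which(mirGene == gg)
        if (!length(cand)) integer(0) else cand[sample.int(length(cand), 1)]
      }))
      if (!length(hit)) GenomicRanges::GRanges()
      else peakOn(mirs[mirIdx[hit]], 1)
    }
    peakB <- c(coverGenes(bridgeGenes, cfg$bridgeGeneCoverage),
               coverGenes(setdiff(unique(mirGene), bridgeGenes),
                          cfg$backgroundBindFraction),
               uniformPeaks(cfg$peaksPerDbp %/% 3))
    roster <- c("DBP_A", "DBP_B",
                sprintf("DBP_%02d", seq_len(max(0, cfg$dbpCount - 2)) + 2))
    peaks <- list(DBP_A = GenomicRanges::sort(peakA),
                  DBP_B = GenomicRanges::sort(peakB))
    for (nm in roster[-(1:2)])
      peaks[[nm]] <- GenomicRanges::sort(uniformPeaks(cfg$peaksPerDbp))
    peaks <- GenomicRanges::GRangesList(peaks)

    ## PPI: planted bridge edge + random edges among the rest
    others <- roster[-(1:2)]
    ppi <- data.frame(protein_a = "DBP_A", protein_b = "DBP_B",
                      stringsAsFactors = FALSE)
    if (length(others) >= 2) {
      extra <- unique(t(replicate(cfg$nPpiEdges,
                                  sample(others, 2))))
      ppi <- rbind(ppi, data.frame(protein_a = extra[, 1],
                                   protein_b = extra[, 2],
                                   stringsAsFactors = FALSE))
    }

    ## sequence under repeat footprints; a fraction of MIRs carries a B-box
    seqs <- .randomSeq(BiocGenerics::width(repeats))
    isMir <- repeats$family == "MIR"
    withBox <- which(isMir & runif(length(repeats)) < cfg$mirBboxFraction)
    for (i in withBox) {
      box <- paste0("GTTC", sample(c("A", "C", "G", "T"), 1), "A",
                    paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE),
                          collapse = ""), "C")
      if (runif(1) < 0.5)
        box <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(box)))
      at <- sample.int(nchar(seqs[i]) - 9L, 1)
      substr(seqs[i], at, at + 8L) <- box
    }
    repeatSeqs <- Biostrings::DNAStringSet(setNames(seqs,
                                                    repeats$repeat_id))

    new("SyntheticGenome",
        chromSizes = chromSizes, tads = tads, genes = genes,
        geneClass = geneClass, repeats = repeats, sites = sites,
        islands = islands, enhancers = enhancers,
        conservation = consTrack, gcTrack = gcTrack, peaks = peaks,
        ppi = ppi, repeatSeqs = repeatSeqs,
        config = c(cfg, list(
          seed = seed, mirZeroGenes = mirZero,
          bridgeTads = bridgeTads, bridgeGenes = bridgeGenes,
          bridgePair = c("DBP_A", "DBP_B"),
          dbpTargets = list(DBP_A = character(0), DBP_B = bridgeGenes))))
  })
}
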