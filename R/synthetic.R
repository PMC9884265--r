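## Synthetic heat-stress chromatin dataset with planted ground truth.
## Every input the pipeline consumes is generated from one master seed;
## the planted truth is returned alongside so recovery can be scored.

#' Default parameters of the synthetic dataset
#'
#' The preset emulates the study conditions: two 5-Mb chromosomes at 20-kb
#' bins with a central gene-poor pericentromere (bins 101-150) and
#' chromosome arms of alternating A/B compartment blocks (25 bins each, A
#' and B balanced and translation-symmetric on the arms); power-law
#' distance decay with exponent `gamma`; a checkerboard of amplitude
#' `amplitude`; 10^6 valid pairs per chromosome at 0h with
#' condition-dependent library size proportional to total contact
#' intensity; at 1h the A-A contacts are boosted x1.3, arm B-B contacts
#' damped x0.7 and pericentromeric contacts damped x0.5, fully reverting at
#' 6h; 20 planted promoter-RE loops of fold 3 in A-compartment arm bins
#' (10 transient heat-gained at 1h, HSFA1a-bound; 10 stable); HiChIP
#' matrices re-weight RNAPII-anchored loop pixels x4. Tracks, peaks,
#' expression, the TF cascade (HSF-like wave at 1h, WRKY-like wave at 6h)
#' and the validation assays (3C-qPCR WT fold 2.5 / knock-down 0.6,
#' luciferase folds 2.5 and 3.5) follow the same planted truth.
#'
#' @param ... Named overrides of any default.
#' @return A parameter list.
#' @export
syntheticParams <- function(...) {
  p <- list(
    nChrom = 2L, chromLength = 5e6, binSize = 2e4,
    periFrac = c(0.4, 0.6), blockBins = 25L,
    depth = 1e6, gamma = 1.0, amplitude = 0.4,
    conditions = c("0h", "1h", "6h"),
    aaBoost = 1.3, bbDamp = 0.7, periDamp = 0.5,
    nGainedLoops = 10L, nStableLoops = 10L, loopFold = 3,
    loopDistRange = c(12L, 35L), hichipLoopFold = 4,
    trackBinSize = 200L, gammaShape = 4, activityFold = 3,
    promoterMarkFold = 4, enhancerFold = 6, enhancerK4Depletion = 0.05,
    nGenes = 1000L, geneLength = 1000L, geneSpacing = 8000L,
    nProximalPeaks = 200L, nDistalPeaks = 300L, nEnhancerPeaks = 30L,
    peakWidth = 300L, accBase = 1, accHigh = 5, accNoiseSd = 0.2,
    accThreshold = 2,
    nArchetypeIDistal = 60L, nHsfPlanted = 50L,
    nHsfTargets = 20L, nWrkyTargets = 15L,
    hsfConsensus = "TCTAGAANNTTCT", wrkyConsensus = "TTGACCGGTCAA",
    exprBaseMeanLog = log(100), exprBaseMeanSd = 1,
    dispersion = 0.05, reps = 2L, nDE1h = 100L, deLfc = 2,
    latentLfcSd = 1.5, accCoupling = 0.8,
    qpcrFoldWT = 2.5, qpcrFoldMut = 0.6, ctNoiseSd = 0.15,
    qpcrBio = 3L, qpcrTech = 3L,
    lucFolds = c("RE-A" = 2.5, "RE-B" = 3.5), lucNoiseSd = 0.1, lucReps = 3L,
    genSequence = TRUE)
  over <- list(...)
  p[names(over)] <- over
  p
}

.lnoise <- function(n, sdlog) rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)

## compartment sign vector per chromosome: +1 = A, -1 = B
.compVector <- function(layout, chrom, blockBins) {
  n <- nBins(layout)[chrom]
  peri <- periBins(layout, chrom)
  comp <- rep(-1, n)
  for (armIdx in list(seq_len(min(peri) - 1L),
                      seq(max(peri) + 1L, n))) {
    blk <- (seq_along(armIdx) - 1L) %/% blockBins
    comp[armIdx] <- ifelse(blk %% 2 == 0, 1, -1)
  }
  comp
}

## per-pixel condition factor matrix
.conditionFactor <- function(comp, inPeri, cond, p) {
  n <- length(comp)
  f <- matrix(1, n, n)
  if (cond != "1h") return(f)
  A <- comp == 1
  B <- comp == -1
  bothA <- outer(A, A, "&"); bothB <- outer(B, B, "&")
  bothPeri <- outer(inPeri, inPeri, "&")
  f[bothA] <- p$aaBoost
  f[bothB] <- p$bbDamp
  f[bothPeri] <- p$periDamp
  f
}

.loopFoldAt <- function(loop, cond, p) {
  if (loop$type == "stable") return(p$loopFold)
  if (cond == "1h") p$loopFold else 1
}

## intensity matrix for one chromosome / condition / assay
.intensity <- function(layout, chrom, comp, cond, assay, loops, p) {
  n <- nBins(layout)[chrom]
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  w <- pmax(d, 0.5)^(-p$gamma)
  chk <- outer(comp, comp)
  inPeri <- seq_len(n) %in% periBins(layout, chrom)
  lam <- w * (1 + p$amplitude * chk) * .conditionFactor(comp, inPeri, cond, p)
  for (i in seq_len(nrow(loops))) {
    if (loops$chrom[i] != chrom) next
    f <- .loopFoldAt(loops[i, ], cond, p)
    if (assay == "HiChIP" && f > 1) f <- f * p$hichipLoopFold
    b1 <- loops$bin1[i]; b2 <- loops$bin2[i]
    lam[b1, b2] <- lam[b1, b2] * f
    lam[b2, b1] <- lam[b1, b2]
  }
  lam
}

## multinomial draw of a symmetric count matrix from an intensity matrix
.drawCounts <- function(lam, size) {
  n <- nrow(lam)
  ut <- upper.tri(lam, diag = TRUE)
  pvec <- lam[ut]
  cnt <- as.numeric(rmultinom(1, size = size, prob = pvec))
  m <- matrix(0, n, n)
  m[ut] <- cnt
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  m
}

## sample loop anchor bin pairs within A-compartment arm bins; anchor bins
## are kept distinct across loops and restricted to bins that can host a
## promoter (promoterBins) or a distal-RE slot (slotBins)
.sampleLoops <- function(layout, comps, p, promoterBins, slotBins) {
  nLoops <- p$nGainedLoops + p$nStableLoops
  if (nLoops == 0L)
    return(data.frame(chrom = character(0), bin1 = integer(0),
                      bin2 = integer(0), type = character(0),
                      hsfa1aBound = logical(0), fold = numeric(0)))
  perChrom <- ceiling(nLoops / p$nChrom)
  loops <- NULL
  for (chr in chromNames(layout)) {
    comp <- comps[[chr]]
    n <- length(comp)
    abins <- which(comp == 1)
    abins <- abins[abins >= 8 & abins <= n - 7]
    cand <- expand.grid(bin1 = intersect(abins, promoterBins[[chr]]),
                        d = seq(p$loopDistRange[1], p$loopDistRange[2]))
    cand$bin2 <- cand$bin1 + cand$d
    cand <- cand[cand$bin2 %in% intersect(abins, slotBins[[chr]]),
                 c("bin1", "bin2")]
    cand <- cand[sample.int(nrow(cand)), ]
    placed <- 0L; usedBins <- integer(0)
    for (r in seq_len(nrow(cand))) {
      if (placed >= perChrom) break
      pA <- cand$bin1[r]; pB <- cand$bin2[r]
      if (pA %in% usedBins || pB %in% usedBins) next
      if (!is.null(loops)) {
        same <- loops[loops$chrom == chr, , drop = FALSE]
        if (nrow(same) &&
            any(abs(same$bin1 - pA) <= 4 & abs(same$bin2 - pB) <= 4)) next
      }
      loops <- rbind(loops, data.frame(chrom = chr, bin1 = pA, bin2 = pB))
      usedBins <- c(usedBins, pA, pB)
      placed <- placed + 1L
    }
    if (placed < perChrom)
      stop("infeasible loop placement on ", chr,
           ": only ", placed, " of ", perChrom, " loops fit")
  }
  loops <- loops[seq_len(nLoops), ]
  ## interleave so both chromosomes carry gained and stable loops
  types <- c(rep(c("gained", "stable"), min(p$nGainedLoops, p$nStableLoops)),
             rep(if (p$nGainedLoops > p$nStableLoops) "gained" else "stable",
                 abs(p$nGainedLoops - p$nStableLoops)))
  loops$type <- types
  loops$hsfa1aBound <- loops$type == "gained"
  loops$fold <- p$loopFold
  rownames(loops) <- NULL
  loops
}

#' Generate the full synthetic heat-stress dataset
#'
#' Draws every input of the pipeline from one master seed (expanded into
#' per-component substreams, see [substreamSeed()]): genome layout and
#' gene annotation, Hi-C and RNAPII-HiChIP contact matrices per condition
#' (multinomial over bin pairs with probability proportional to
#' `s^-gamma x (1 + amplitude x checkerboard) x loop folds x condition
#' modifiers`), histone-mark/ATAC/RNAPII signal tracks (planted signatures
#' with multiplicative Gamma noise), classified peak truth with per-time
#' accessibility, an expression matrix tied to the planted DE plan, DAP
#' peaks of the HSF-like factor with a Halo-tag control, the TF cascade,
#' and the 3C-qPCR / luciferase tables. Identical seeds give byte-identical
#' output.
#'
#' @param params Parameter list from [syntheticParams()].
#' @param seed Master seed.
#' @return A list: `layout`, `genes`, `contacts` (nested
#'   `[[assay]][[condition]]` of [ContactMatrix-class]), `tracks` (named
#'   list of [SignalTrack-class]), `peaks`, `dapPeaks`, `haloPeaks`,
#'   `genome` (named character sequences; `NULL` unless `genSequence`),
#'   `expr`, `tfs`, `de` (planted-truth DE tables per time), `qpcr`,
#'   `luc`, and `truth` (every planted quantity).
#' @export
generateDataset <- function(params = syntheticParams(), seed = 1L) {
  p <- params
  chromNamesV <- paste0("chr", seq_len(p$nChrom))
  lens <- setNames(rep(p$chromLength, p$nChrom), chromNamesV)
  peri <- lapply(chromNamesV, function(x)
    c(floor(p$chromLength * p$periFrac[1]) + 1, floor(p$chromLength * p$periFrac[2])))
  names(peri) <- chromNamesV
  layout <- GenomeLayout(lens, peri, p$binSize)
  comps <- lapply(chromNamesV, function(chr) .compVector(layout, chr, p$blockBins))
  names(comps) <- chromNamesV

  ## ---- genes --------------------------------------------------------------
  set.seed(substreamSeed(seed, "genes"))
  perChrom <- p$nGenes / p$nChrom
  geneRows <- NULL
  for (chr in chromNamesV) {
    pc <- layout@pericentromere[chr, ]
    arms <- list(c(1, pc[1] - 1), c(pc[2] + 1, p$chromLength))
    perArm <- perChrom / 2
    for (a in 1:2) {
      starts <- arms[[a]][1] + (seq_len(perArm) - 1) * p$geneSpacing + 3000
      geneRows <- rbind(geneRows, data.frame(
        chrom = chr, start = starts, end = starts + p$geneLength - 1,
        strand = sample(c("+", "-"), perArm, replace = TRUE)))
    }
  }
  geneRows$gene_id <- sprintf("gene%04d", seq_len(nrow(geneRows)))
  genes <- GenomicRanges::GRanges(geneRows$chrom,
    IRanges::IRanges(geneRows$start, geneRows$end),
    strand = geneRows$strand, gene_id = geneRows$gene_id)
  GenomeInfoDb::seqlengths(genes) <- lens
  tss <- geneTSS(genes)
  tssPos <- BiocGenerics::start(tss)
  tssBin <- binIndex(layout, geneRows$chrom, tssPos)
  slotStart <- geneRows$start + 3500
  slotBin <- binIndex(layout, geneRows$chrom, slotStart)

  ## ---- loops --------------------------------------------------------------
  set.seed(substreamSeed(seed, "loops"))
  ## bins able to host a promoter / distal-RE slot (TF genes 1:2 reserved)
  hostable <- function(bins) {
    out <- lapply(chromNamesV, function(chr)
      sort(unique(bins[geneRows$chrom == chr &
                         !(seq_len(nrow(geneRows)) %in% 1:2)])))
    names(out) <- chromNamesV
    out
  }
  loops <- .sampleLoops(layout, comps, p, hostable(tssBin), hostable(slotBin))
  pickGene <- function(chr, bin, pool, by) {
    cand <- which(geneRows$chrom == chr & by == bin & !(seq_len(nrow(geneRows)) %in% pool))
    if (!length(cand)) stop("no free gene in anchor bin ", chr, ":", bin)
    cand[1]
  }
  used <- integer(0)
  loops$promoterGene <- rep(NA_character_, nrow(loops))
  loops$reGene <- rep(NA_integer_, nrow(loops)) # gene row hosting the RE peak
  for (i in seq_len(nrow(loops))) {
    gi <- pickGene(loops$chrom[i], loops$bin1[i], used, tssBin)
    used <- c(used, gi)
    loops$promoterGene[i] <- geneRows$gene_id[gi]
    ri <- pickGene(loops$chrom[i], loops$bin2[i], used, slotBin)
    used <- c(used, ri)
    loops$reGene[i] <- ri
  }

  ## ---- peaks --------------------------------------------------------------
  set.seed(substreamSeed(seed, "peaks"))
  gained <- which(loops$type == "gained")
  stable <- which(loops$type == "stable")
  hsfTargetGenes <- loops$promoterGene[gained]
  extraHsfIdx <- sample(setdiff(seq_len(nrow(geneRows)),
                                c(used, 1:2)), p$nHsfTargets - length(gained) +
                          p$nWrkyTargets + p$nProximalPeaks)
  hsfExtra <- extraHsfIdx[seq_len(p$nHsfTargets - length(gained))]
  wrkyIdx <- extraHsfIdx[p$nHsfTargets - length(gained) + seq_len(p$nWrkyTargets)]
  restProx <- extraHsfIdx[(p$nHsfTargets - length(gained) + p$nWrkyTargets + 1):
                            length(extraHsfIdx)]
  hsfTargetGenes <- c(hsfTargetGenes, geneRows$gene_id[hsfExtra])
  wrkyTargetGenes <- geneRows$gene_id[wrkyIdx]

  nConstit <- min(5L, length(stable))
  stableProm <- match(loops$promoterGene[head(stable, nConstit)],
                      geneRows$gene_id)
  proxGeneIdx <- c(match(hsfTargetGenes, geneRows$gene_id), wrkyIdx,
                   stableProm,
                   restProx[seq_len(p$nProximalPeaks - p$nHsfTargets -
                                      p$nWrkyTargets - nConstit)])
  proxKind <- c(rep("hsf", p$nHsfTargets), rep("wrky", p$nWrkyTargets),
                rep("constitutive", nConstit),
                rep("coupled", length(proxGeneIdx) - p$nHsfTargets -
                      p$nWrkyTargets - nConstit))
  upstream <- ifelse(geneRows$strand[proxGeneIdx] == "+",
                     tssPos[proxGeneIdx] - 700, tssPos[proxGeneIdx] + 401)
  proxDF <- data.frame(chrom = geneRows$chrom[proxGeneIdx],
                       start = upstream, end = upstream + p$peakWidth - 1,
                       class0 = "proximal", kind = proxKind,
                       gene = geneRows$gene_id[proxGeneIdx])

  ## distal peaks: gained-loop REs + stable-loop REs + the rest in free slots
  reRows <- loops$reGene
  freeSlots <- setdiff(seq_len(nrow(geneRows)), c(used, proxGeneIdx, 1:2))
  distGeneIdx <- c(reRows, sample(freeSlots, p$nDistalPeaks - length(reRows)))
  distKind <- rep("other", p$nDistalPeaks)
  distKind[seq_len(nrow(loops))] <-
    ifelse(loops$type == "gained", "gainedRE", "stableRE")
  nOtherI <- p$nArchetypeIDistal - length(gained)
  otherPool <- which(distKind == "other")
  archIidx <- c(which(distKind == "gainedRE"), sample(otherPool, nOtherI))
  distDF <- data.frame(chrom = geneRows$chrom[distGeneIdx],
                       start = geneRows$start[distGeneIdx] + 3500,
                       end = geneRows$start[distGeneIdx] + 3500 + p$peakWidth - 1,
                       class0 = "distal", kind = distKind,
                       gene = NA_character_)
  hsfPlantedDist <- archIidx[seq_len(min(p$nHsfPlanted, length(archIidx)))]
  enhancerIdx <- sample(seq_len(p$nDistalPeaks), p$nEnhancerPeaks)

  peaksDF <- rbind(proxDF, distDF)
  nProx <- nrow(proxDF)
  isDistArchI <- rep(FALSE, nrow(peaksDF))
  isDistArchI[nProx + archIidx] <- TRUE
  isEnhancer <- rep(FALSE, nrow(peaksDF))
  isEnhancer[nProx + enhancerIdx] <- TRUE
  isHsfPlantedPeak <- rep(FALSE, nrow(peaksDF))
  isHsfPlantedPeak[nProx + hsfPlantedDist] <- TRUE
  isHsfPlantedPeak[which(proxKind == "hsf")] <- TRUE
  isWrkyPlantedPeak <- rep(FALSE, nrow(peaksDF))
  isWrkyPlantedPeak[which(proxKind == "wrky")] <- TRUE

  ## ---- expression plan ----------------------------------------------------
  set.seed(substreamSeed(seed, "deplan"))
  tfGenes <- geneRows$gene_id[1:2]   # reserved: HSF-like, WRKY-like TF genes
  lfc <- matrix(0, p$nGenes, 3, dimnames = list(geneRows$gene_id, p$conditions))
  lfc[hsfTargetGenes, "1h"] <- p$deLfc
  lfc[wrkyTargetGenes, "6h"] <- p$deLfc
  lfc[tfGenes[1], "1h"] <- p$deLfc
  lfc[tfGenes[2], "6h"] <- p$deLfc
  nonSpecial <- setdiff(geneRows$gene_id,
                        c(hsfTargetGenes, wrkyTargetGenes, tfGenes,
                          loops$promoterGene))
  nExtraDE <- p$nDE1h - length(hsfTargetGenes) - 1L
  extraDE <- sample(nonSpecial, nExtraDE)
  upExtra <- extraDE[seq_len(ceiling(nExtraDE * 0.6))]
  downExtra <- setdiff(extraDE, upExtra)
  lfc[upExtra, "1h"] <- p$deLfc
  lfc[downExtra, "1h"] <- -p$deLfc
  ## latent time-course variation for the remaining genes: they fluctuate
  ## with heat (the coupling target for accessibility) but are not part of
  ## the planted DE design
  designed <- rownames(lfc)[rowSums(lfc != 0) > 0]
  flat <- setdiff(geneRows$gene_id, designed)
  lfc[flat, "1h"] <- rnorm(length(flat), 0, p$latentLfcSd)
  lfc[flat, "6h"] <- rnorm(length(flat), 0, p$latentLfcSd)
  deTruth <- lapply(c("1h", "6h"), function(tt) {
    dirv <- ifelse(rownames(lfc) %in% designed & abs(lfc[, tt]) >= 1,
                   ifelse(lfc[, tt] > 0, "up", "down"), "unchanged")
    data.frame(gene = rownames(lfc), lfc = lfc[, tt], direction = dirv)
  })
  names(deTruth) <- c("1h", "6h")

  ## ---- peak accessibility -------------------------------------------------
  set.seed(substreamSeed(seed, "access"))
  arch <- rbind(I = c(1, 5, 1), II = c(1, 4, 4), III = c(4, 1, 1),
                IV = c(4, 4, 1), V = c(1, 1, 4))
  colnames(arch) <- p$conditions
  nPk <- nrow(peaksDF)
  accMean <- matrix(p$accBase, nPk, 3, dimnames = list(NULL, p$conditions))
  archLabel <- rep(NA_character_, nPk)
  for (i in seq_len(nPk)) {
    if (i <= nProx) {
      kind <- peaksDF$kind[i]
      if (kind == "hsf") { accMean[i, ] <- arch["I", ]; archLabel[i] <- "I" }
      else if (kind == "wrky") { accMean[i, ] <- arch["V", ]; archLabel[i] <- "V" }
      else if (kind == "constitutive") accMean[i, ] <- c(4, 4, 4)
      else {
        g <- peaksDF$gene[i]
        accMean[i, ] <- p$accBase * 2^(p$accCoupling * lfc[g, ])
      }
    } else {
      if (isDistArchI[i]) { accMean[i, ] <- arch["I", ]; archLabel[i] <- "I" }
      else if (peaksDF$kind[i] == "stableRE") accMean[i, ] <- c(1, 1, 1)
      else if (runif(1) < 0.5) {
        aa <- sample(rownames(arch), 1)
        accMean[i, ] <- arch[aa, ]; archLabel[i] <- aa
      }
    }
  }
  acc <- accMean * matrix(.lnoise(nPk * 3, p$accNoiseSd), nPk, 3)
  peaks <- GenomicRanges::GRanges(peaksDF$chrom,
    IRanges::IRanges(peaksDF$start, peaksDF$end))
  GenomeInfoDb::seqlevels(peaks) <- chromNamesV
  GenomeInfoDb::seqlengths(peaks) <- lens
  peaks$summit <- (peaksDF$start + peaksDF$end) %/% 2
  for (j in 1:3) S4Vectors::mcols(peaks)[[paste0("acc_", p$conditions[j])]] <- acc[, j]

  ## ---- genome sequence with planted motifs --------------------------------
  genome <- NULL
  if (p$genSequence) {
    set.seed(substreamSeed(seed, "sequence"))
    chars <- lapply(chromNamesV, function(chr)
      sample(c("A", "C", "G", "T"), p$chromLength, replace = TRUE))
    names(chars) <- chromNamesV
    plant <- function(i, consensus, offset) {
      lets <- strsplit(consensus, "")[[1]]
      lets[lets == "N"] <- sample(c("A", "C", "G", "T"),
                                  sum(lets == "N"), replace = TRUE)
      at <- peaks$summit[i] - offset
      chars[[peaksDF$chrom[i]]][at:(at + length(lets) - 1L)] <<- lets
      invisible(NULL)
    }
    for (i in which(isHsfPlantedPeak)) plant(i, p$hsfConsensus, 6L)
    for (i in which(isWrkyPlantedPeak)) plant(i, p$wrkyConsensus, 5L)
    genome <- lapply(chars, paste, collapse = "")
  }

  ## ---- contact matrices ---------------------------------------------------
  set.seed(substreamSeed(seed, "contacts"))
  contacts <- list()
  for (assay in c("HiC", "HiChIP")) {
    contacts[[assay]] <- list()
    for (cond in p$conditions) {
      mats <- list(); sizes <- numeric(0)
      for (chr in chromNamesV) {
        lam <- .intensity(layout, chr, comps[[chr]], cond, assay, loops, p)
        lam0 <- .intensity(layout, chr, comps[[chr]], "0h", assay, loops, p)
        size <- round(p$depth * sum(lam) / sum(lam0))
        mats[[chr]] <- .drawCounts(lam, size)
        sizes <- c(sizes, size)
      }
      contacts[[assay]][[cond]] <- ContactMatrix(
        mats, layout, assay = assay, condition = cond,
        balanced = FALSE, totalPairs = sum(sizes))
    }
  }

  ## ---- signal tracks ------------------------------------------------------
  set.seed(substreamSeed(seed, "tracks"))
  tb <- p$trackBinSize
  nTB <- ceiling(lens / tb)
  addRegion <- function(meanList, chrom, start, end, factor) {
    b1 <- max(1L, as.integer((start - 1) %/% tb) + 1L)
    b2 <- min(nTB[chrom], as.integer((end - 1) %/% tb) + 1L)
    meanList[[chrom]][b1:b2] <- meanList[[chrom]][b1:b2] * factor
    meanList
  }
  baseMeans <- function() {
    out <- lapply(chromNamesV, function(chr) rep(1, nTB[chr]))
    names(out) <- chromNamesV
    out
  }
  activityMeans <- function() {
    out <- baseMeans()
    for (chr in chromNamesV) {
      abins <- which(comps[[chr]] == 1)
      for (b in abins)
        out <- addRegion(out, chr, (b - 1) * p$binSize + 1, b * p$binSize,
                         p$activityFold)
    }
    out
  }
  promWin <- genePromoters(genes, upstream = 1000L)
  elevAtPromoters <- function(m, factor) {
    for (i in seq_along(promWin))
      m <- addRegion(m, as.character(GenomeInfoDb::seqnames(promWin))[i],
                     BiocGenerics::start(promWin)[i],
                     BiocGenerics::end(promWin)[i], factor)
    m
  }
  flankElev <- function(m, i, factor) {
    m <- addRegion(m, peaksDF$chrom[i], peaksDF$start[i] - 500,
                   peaksDF$start[i] - 1, factor)
    addRegion(m, peaksDF$chrom[i], peaksDF$end[i] + 1,
              peaksDF$end[i] + 500, factor)
  }
  mk <- list()
  mk$H3K9ac <- elevAtPromoters(activityMeans(), p$promoterMarkFold)
  mk$H3K18ac <- elevAtPromoters(baseMeans(), p$promoterMarkFold)
  mk$H3K4me3 <- elevAtPromoters(baseMeans(), p$promoterMarkFold)
  for (i in which(isEnhancer)) {
    mk$H3K9ac <- flankElev(mk$H3K9ac, i, p$enhancerFold)
    mk$H3K18ac <- flankElev(mk$H3K18ac, i, p$enhancerFold)
    mk$H3K4me3 <- flankElev(mk$H3K4me3, i, p$enhancerK4Depletion)
  }
  mk$RNAPII <- elevAtPromoters(baseMeans(), p$promoterMarkFold)
  for (i in which(peaksDF$kind %in% c("gainedRE", "stableRE")))
    mk$RNAPII <- addRegion(mk$RNAPII, peaksDF$chrom[i], peaksDF$start[i],
                           peaksDF$end[i], 3)
  drawTrack <- function(meanList, name, cond = "all") {
    vals <- lapply(chromNamesV, function(chr) {
      mu <- meanList[[chr]]
      mu * rgamma(length(mu), shape = p$gammaShape) / p$gammaShape
    })
    names(vals) <- chromNamesV
    SignalTrack(name, vals, layout, tb, cond)
  }
  tracks <- list()
  for (nm in names(mk)) tracks[[nm]] <- drawTrack(mk[[nm]], nm)
  for (j in seq_along(p$conditions)) {
    cond <- p$conditions[j]
    m <- activityMeans()
    for (i in seq_len(nPk))
      m <- addRegion(m, peaksDF$chrom[i], peaksDF$start[i], peaksDF$end[i],
                     pmax(1, 2 * acc[i, j]))
    tracks[[paste0("ATAC_", cond)]] <- drawTrack(m, "ATAC", cond)
  }

  ## ---- expression ---------------------------------------------------------
  truthCore <- list(lfc = lfc, geneIds = geneRows$gene_id,
                    conditions = p$conditions)
  expr <- generateExpression(truthCore, dispersion = p$dispersion,
                             reps = p$reps, seed = substreamSeed(seed, "expr"),
                             baseMeanLog = p$exprBaseMeanLog,
                             baseMeanSd = p$exprBaseMeanSd)

  ## ---- DAP peaks (HSF-like factor) with Halo-tag control ------------------
  set.seed(substreamSeed(seed, "dap"))
  dapIdx <- which(isHsfPlantedPeak)
  dapPeaks <- GenomicRanges::GRanges(peaksDF$chrom[dapIdx],
    IRanges::IRanges(peaks$summit[dapIdx] - 100L, peaks$summit[dapIdx] + 100L),
    summit = peaks$summit[dapIdx])
  nHalo <- 10L
  haloChrom <- sample(chromNamesV, nHalo, replace = TRUE)
  haloPos <- sapply(haloChrom, function(ch) sample.int(p$chromLength - 300L, 1))
  haloPeaks <- GenomicRanges::GRanges(haloChrom,
    IRanges::IRanges(haloPos, haloPos + 200L), summit = haloPos + 100L)

  ## ---- TF table -----------------------------------------------------------
  tfs <- data.frame(
    name = c("HSF-like", "WRKY-like"),
    gene = tfGenes,
    family = c("HSF", "WRKY"),
    motif = c(p$hsfConsensus, p$wrkyConsensus),
    wave = c("1h", "6h"))

  ## ---- validation assays --------------------------------------------------
  set.seed(substreamSeed(seed, "qpcr"))
  qpcr <- NULL
  relEff <- function(genotype, cond) {
    if (cond == "0h") return(1)
    if (genotype == "WT") p$qpcrFoldWT else p$qpcrFoldMut
  }
  for (loopId in c("A", "B")) for (gt in c("WT", "hsfa1a-1", "hsfa1a-2"))
    for (cond in c("0h", "1h")) for (b in seq_len(p$qpcrBio)) {
      bioEff <- .lnoise(1, 0.05)
      for (tc in seq_len(p$qpcrTech)) {
        ctn <- rnorm(1, 20, 0.3)
        rif <- 2^-5 * relEff(gt, cond) * bioEff
        qpcr <- rbind(qpcr, data.frame(
          genotype = gt, condition = cond, loop = loopId,
          bioRep = b, techRep = tc,
          Ct_target = ctn - log2(rif) + rnorm(1, 0, p$ctNoiseSd),
          Ct_norm = ctn))
      }
    }

  set.seed(substreamSeed(seed, "luc"))
  luc <- NULL
  for (cons in c("mini35S", names(p$lucFolds))) for (r in seq_len(p$lucReps)) {
    ren <- rlnorm(1, log(1000), 0.3)
    fold <- if (cons == "mini35S") 1 else p$lucFolds[[cons]]
    luc <- rbind(luc, data.frame(
      construct = cons, replicate = r, REN = ren,
      LUC = ren * 0.5 * fold * .lnoise(1, p$lucNoiseSd)))
  }

  truth <- list(
    comps = comps, amplitude = p$amplitude, gamma = p$gamma,
    aaBoost = p$aaBoost, bbDamp = p$bbDamp, periDamp = p$periDamp,
    loops = loops, lfc = lfc, deTruth = deTruth,
    hsfTargets = hsfTargetGenes, wrkyTargets = wrkyTargetGenes,
    tfGenes = tfGenes,
    peakKind = peaksDF$kind, peakClass0 = peaksDF$class0,
    peakGene = peaksDF$gene, archetype = archLabel,
    enhancerPeaks = which(isEnhancer),
    hsfPlantedPeaks = which(isHsfPlantedPeak),
    wrkyPlantedPeaks = which(isWrkyPlantedPeak),
    distalArchIPeaks = which(isDistArchI),
    accMean = accMean, accThreshold = p$accThreshold,
    qpcrFoldWT = p$qpcrFoldWT, qpcrFoldMut = p$qpcrFoldMut,
    lucFolds = p$lucFolds, seed = seed)

  list(layout = layout, genes = genes, contacts = contacts, tracks = tracks,
       peaks = peaks, dapPeaks = dapPeaks, haloPeaks = haloPeaks,
       genome = genome, expr = expr, tfs = tfs, de = deTruth,
       qpcr = qpcr, luc = luc, truth = truth, params = p, seed = seed)
}

#' Generate a negative-binomial expression matrix from a planted DE plan
#'
#' Counts are NB with gene base means (log-normal) shifted by the planted
#' log2 fold changes per condition; transient genes revert at 6h because
#' their planted fold change at 6h is 0.
#'
#' @param truth A list with `lfc` (gene x condition log2FC matrix, 0h
#'   reference), `geneIds` and `conditions` (e.g. from
#'   [generateDataset()]'s truth, or built directly).
#' @param dispersion NB dispersion (default 0.05).
#' @param reps Replicates per condition (default 2, the study's design).
#' @param seed Integer seed.
#' @param baseMeanLog,baseMeanSd Log-normal parameters of gene base means.
#' @return A list with `counts` (gene x sample integer matrix) and
#'   `samples` (data.frame `sample`, `condition`, `replicate`).
#' @export
generateExpression <- function(truth, dispersion = 0.05, reps = 2L, seed = 1L,
                               baseMeanLog = log(100), baseMeanSd = 1) {
  set.seed(seed)
  genes <- truth$geneIds
  conds <- truth$conditions
  base <- rlnorm(length(genes), baseMeanLog, baseMeanSd)
  samples <- expand.grid(replicate = seq_len(reps), condition = conds,
                         stringsAsFactors = FALSE)[, 2:1]
  samples$sample <- paste0(samples$condition, "_r", samples$replicate)
  counts <- matrix(0L, length(genes), nrow(samples),
                   dimnames = list(genes, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- base * 2^(truth$lfc[, samples$condition[j]])
    counts[, j] <- rnbinom(length(genes), mu = mu, size = 1 / dispersion)
  }
  list(counts = counts, samples = samples)
}

#' Simple differential-expression caller
#'
#' Median-of-ratios size factors, log2 fold change of normalized group
#' means, a two-sample t-test on `log2(normalized + 1)`, BH adjustment, and
#' direction labels (`up`/`down` at `padj <= 0.05` and `|log2FC| >= 1`).
#' All-zero genes are excluded and counted.
#'
#' @param expr Expression list (`counts`, `samples`).
#' @param contrast Length-2 character: (treatment, reference) condition.
#' @param alpha BH threshold (default 0.05).
#' @param lfcMin Minimum |log2FC| for a call (default 1).
#' @return A data.frame `gene`, `lfc`, `p`, `padj`, `direction`, with the
#'   number of excluded all-zero genes in attribute `"nZero"`.
#' @export
simpleDE <- function(expr, contrast = c("1h", "0h"), alpha = 0.05, lfcMin = 1) {
  counts <- expr$counts
  nz <- rowSums(counts) > 0
  nZero <- sum(!nz)
  counts <- counts[nz, , drop = FALSE]
  ## median-of-ratios size factors
  logGeo <- rowMeans(log(counts + 0.5))
  sf <- apply(counts, 2, function(col) {
    r <- log(col + 0.5) - logGeo
    exp(median(r))
  })
  norm <- sweep(counts, 2, sf, "/")
  gA <- expr$samples$condition == contrast[1]
  gB <- expr$samples$condition == contrast[2]
  mA <- rowMeans(norm[, gA, drop = FALSE])
  mB <- rowMeans(norm[, gB, drop = FALSE])
  lfc <- log2((mA + 0.5) / (mB + 0.5))
  lg <- log2(norm + 1)
  pv <- vapply(seq_len(nrow(lg)), function(i) {
    a <- lg[i, gA]; b <- lg[i, gB]
    if (sd(a) == 0 && sd(b) == 0) return(if (mean(a) == mean(b)) 1 else 0)
    twoSampleT(a, b)$p
  }, numeric(1))
  padj <- p.adjust(pv, method = "BH")
  dirv <- ifelse(padj <= alpha & abs(lfc) >= lfcMin,
                 ifelse(lfc > 0, "up", "down"), "unchanged")
  out <- data.frame(gene = rownames(counts), lfc = lfc, p = pv,
                    padj = padj, direction = dirv)
  rownames(out) <- NULL
  attr(out, "nZero") <- nZero
  out
}

#' Planted time-course archetype profiles for clustering benchmarks
#'
#' Five archetype shapes over the heat-stress time course (transient up,
#' sustained up, transient/immediate down, sustained down-late, late up),
#' standardized, with additive Gaussian noise.
#'
#' @param nPer Items per archetype (default 40).
#' @param k Number of archetypes used (default 5, in order).
#' @param noiseSd Additive noise standard deviation (default 0.2).
#' @param seed Integer seed.
#' @return A list with `profiles` (matrix), `truth` (integer archetype
#'   labels) and `archetypes`.
#' @export
generateTimecourseProfiles <- function(nPer = 40L, k = 5L, noiseSd = 0.2,
                                       seed = 1L) {
  arch <- rbind(I = c(1, 5, 1), II = c(1, 4, 4), III = c(4, 1, 1),
                IV = c(4, 4, 1), V = c(1, 1, 4))[seq_len(k), , drop = FALSE]
  colnames(arch) <- c("0h", "1h", "6h")
  archStd <- standardizeProfiles(arch)
  set.seed(seed)
  profiles <- archStd[rep(seq_len(k), each = nPer), , drop = FALSE] +
    matrix(rnorm(k * nPer * ncol(arch), 0, noiseSd), k * nPer)
  rownames(profiles) <- paste0("item", seq_len(nrow(profiles)))
  list(profiles = profiles, truth = rep(seq_len(k), each = nPer),
       archetypes = archStd)
}

#' Synthetic interactions with strength coupled to anchor accessibility
#'
#' A single-chromosome contact matrix with planted loops whose fold grows
#' with the number of accessible anchors (category 0/1/2), plus the
#' matching accessible-peak set — the coupled construction used to test
#' accessibility stratification.
#'
#' @param nPerCat Loops per accessibility category (default 30).
#' @param folds Loop folds for categories 0, 1, 2 (default 1.5, 2.5, 4).
#' @param depth Valid pairs (default 5e5).
#' @param gamma Distance-decay exponent.
#' @param seed Integer seed.
#' @return A list with `cm` ([ContactMatrix-class]), `atacPeaks`
#'   (accessible peaks), `loops` (data.frame with `category`) and `layout`.
#' @export
generateCoupledInteractions <- function(nPerCat = 30L, folds = c(1.5, 2.5, 4),
                                        depth = 5e5, gamma = 1.0, seed = 1L) {
  set.seed(seed)
  n <- 300L; bs <- 2e4
  L <- n * bs
  layout <- GenomeLayout(c(chr1 = L), list(chr1 = c(L / 2 - 1e4, L / 2 + 1e4)),
                         bs)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- pmax(d, 0.5)^(-gamma)
  loops <- NULL
  usedBins <- integer(0)   # anchors kept distinct so categories stay pure
  for (cat in 0:2) for (k in seq_len(nPerCat)) {
    repeat {
      b1 <- sample(10:(n - 70), 1)
      b2 <- b1 + sample(15:55, 1)
      if (!(b1 %in% usedBins) && !(b2 %in% usedBins) &&
          (is.null(loops) ||
           !any(abs(loops$bin1 - b1) <= 3 & abs(loops$bin2 - b2) <= 3))) break
    }
    usedBins <- c(usedBins, b1, b2)
    loops <- rbind(loops, data.frame(chrom = "chr1", bin1 = b1, bin2 = b2,
                                     category = cat))
  }
  loops$fold <- folds[loops$category + 1]
  for (i in seq_len(nrow(loops))) {
    lam[loops$bin1[i], loops$bin2[i]] <- lam[loops$bin1[i], loops$bin2[i]] * loops$fold[i]
    lam[loops$bin2[i], loops$bin1[i]] <- lam[loops$bin1[i], loops$bin2[i]]
  }
  m <- .drawCounts(lam, depth)
  cm <- ContactMatrix(list(chr1 = m), layout, assay = "CHiC", condition = "1h",
                      totalPairs = depth)
  ## accessible peaks: both anchors for cat 2, the first anchor for cat 1
  accBins <- c(loops$bin1[loops$category >= 1], loops$bin2[loops$category == 2])
  starts <- (accBins - 1) * bs + 5000
  atacPeaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, starts + 299))
  list(cm = cm, atacPeaks = atacPeaks, loops = loops, layout = layout)
}

#' Random non-loop anchor pairs matched to the planted loop geometry
#'
#' Samples arm A-compartment bin pairs in the planted distance range that
#' are at least 3 bins away from every planted loop pixel — the null set
#' for APA and precision benchmarks.
#'
#' @param dataset A [generateDataset()] result.
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @return data.frame `chrom`, `bin1`, `bin2`.
#' @export
randomAnchorPairs <- function(dataset, n = 200L, seed = 1L) {
  set.seed(seed)
  layout <- dataset$layout
  loops <- dataset$truth$loops
  p <- dataset$params
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    chr <- sample(chromNames(layout), 1)
    abins <- which(dataset$truth$comps[[chr]] == 1)
    abins <- abins[abins >= 8 & abins <= nBins(layout)[chr] - 7]
    b1 <- sample(abins, 1)
    b2 <- b1 + sample(seq(p$loopDistRange[1], p$loopDistRange[2]), 1)
    if (b2 > nBins(layout)[chr] - 7) next
    if (!(b2 %in% abins)) next
    same <- loops[loops$chrom == chr, , drop = FALSE]
    if (nrow(same) && any(abs(same$bin1 - b1) <= 3 & abs(same$bin2 - b2) <= 3)) next
    out <- rbind(out, data.frame(chrom = chr, bin1 = b1, bin2 = b2))
  }
  out[seq_len(n), ]
}
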