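#' Classify peaks as TSS-proximal, TSS-distal or genic-other
#'
#' Proximal: the peak overlaps the strand-aware upstream window
#' `[TSS - proxBp, TSS)` of some gene (linked to the nearest such TSS).
#' Distal: at least `proxBp` away from every gene body and every promoter
#' window. Everything else (gene-body overlap or the in-between margin) is
#' `genic-other`, keeping both named categories pure;
#' `allowGenicDistal = TRUE` relaxes the distal rule to ignore gene bodies.
#'
#' @param peaks Peak GRanges.
#' @param genes Gene GRanges with strand and `gene_id`.
#' @param proxBp Upstream window size in bp (default 1000).
#' @param allowGenicDistal Let peaks inside gene bodies count as distal.
#' @return `peaks` with `class` and `linkedGene` metadata columns; every
#'   peak receives exactly one class.
#' @export
classifyPeaks <- function(peaks, genes, proxBp = 1000L, allowGenicDistal = FALSE) {
  upstream <- genePromoters(genes, upstream = proxBp)
  cls <- rep("genic-other", length(peaks))
  linked <- rep(NA_character_, length(peaks))

  hits <- GenomicRanges::findOverlaps(peaks, upstream)
  if (length(hits)) {
    tss <- geneTSS(genes)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    dd <- GenomicRanges::distance(peaks[qh], tss[sh])
    best <- tapply(seq_along(qh), qh, function(ii) ii[which.min(dd[ii])])
    bi <- unlist(best)
    cls[qh[bi]] <- "proximal"
    linked[qh[bi]] <- genes$gene_id[sh[bi]]
  }

  geneSpace <- if (allowGenicDistal) GenomicRanges::granges(upstream) else
    c(GenomicRanges::granges(genes), GenomicRanges::granges(upstream))
  dn <- GenomicRanges::distanceToNearest(peaks, geneSpace)
  distOK <- rep(TRUE, length(peaks))
  distOK[S4Vectors::queryHits(dn)] <- S4Vectors::mcols(dn)$distance >= proxBp
  cls[cls != "proximal" & distOK] <- "distal"

  peaks$class <- cls
  peaks$linkedGene <- linked
  peaks
}

#' Label distal peaks with the enhancer chromatin signature
#'
#' A distal peak is enhancer-like when its nucleosome flanks (± `flankBp`
#' around the peak, excluding the accessible interval itself) carry high
#' H3K9ac AND high H3K18ac (each at or above the `hiQ` quantile of the
#' distal-peak flank distribution) AND are devoid of H3K4me3 (at or below
#' its `loQ` quantile). Proximal peaks are never labeled: their flanks are
#' H3K4me3-high, the promoter signature.
#'
#' @param peaks Classified peak GRanges (see [classifyPeaks()]).
#' @param marks Named list of [SignalTrack-class] objects; must contain
#'   `H3K9ac`, `H3K18ac` and `H3K4me3`.
#' @param flankBp Flank width in bp (default 500).
#' @param hiQ,loQ Cohort quantile thresholds (defaults 0.75 / 0.25).
#' @return `peaks` with a `signature` column (`"enhancer-like"` / `"none"`)
#'   and per-mark `flank_<mark>` columns on distal peaks.
#' @export
enhancerSignature <- function(peaks, marks, flankBp = 500L,
                              hiQ = 0.75, loQ = 0.25) {
  need <- c("H3K9ac", "H3K18ac", "H3K4me3")
  for (mk in need)
    if (!mk %in% names(marks)) stop("missing required mark track: ", mk)
  if (is.null(peaks$class)) stop("peaks must be classified first (classifyPeaks)")
  sig <- rep("none", length(peaks))
  distal <- which(peaks$class == "distal")
  flankVals <- matrix(NA_real_, length(peaks), length(need),
                      dimnames = list(NULL, need))
  if (length(distal)) {
    left <- GenomicRanges::flank(peaks[distal], flankBp, start = TRUE)
    right <- GenomicRanges::flank(peaks[distal], flankBp, start = FALSE)
    left <- suppressWarnings(GenomicRanges::trim(left))
    right <- suppressWarnings(GenomicRanges::trim(right))
    for (mk in need) {
      lv <- summarizeTrack(marks[[mk]], left, "mean")
      rv <- summarizeTrack(marks[[mk]], right, "mean")
      flankVals[distal, mk] <- rowMeans(cbind(lv, rv), na.rm = TRUE)
    }
    hi9 <- quantile(flankVals[distal, "H3K9ac"], hiQ, na.rm = TRUE)
    hi18 <- quantile(flankVals[distal, "H3K18ac"], hiQ, na.rm = TRUE)
    lo4 <- quantile(flankVals[distal, "H3K4me3"], loQ, na.rm = TRUE)
    hit <- flankVals[distal, "H3K9ac"] >= hi9 &
      flankVals[distal, "H3K18ac"] >= hi18 &
      flankVals[distal, "H3K4me3"] <= lo4
    sig[distal[which(hit)]] <- "enhancer-like"
  }
  peaks$signature <- sig
  for (mk in need)
    S4Vectors::mcols(peaks)[[paste0("flank_", mk)]] <- flankVals[, mk]
  peaks
}

## k-means++ seeding (Arthur & Vassilvitskii): first center uniform, the
## rest sampled with probability proportional to squared distance to the
## nearest chosen center.
.kmeansPPInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' Standardize time-course profiles row-wise
#'
#' Each row gets mean 0 and unit standard deviation (constant rows become
#' all-zero), so clustering portrays profile shape rather than magnitude.
#'
#' @param profiles Numeric matrix, items x time points.
#' @return The standardized matrix.
#' @export
standardizeProfiles <- function(profiles) {
  m <- rowMeans(profiles)
  s <- apply(profiles, 1, sd)
  s[s == 0 | is.na(s)] <- 1
  (profiles - m) / s
}

#' k-means clustering of time-course profiles
#'
#' Rows are standardized, seeded k-means++ centers are refined by Lloyd
#' iterations (converged when the relative inertia change drops below 1e-6,
#' at most 300 iterations), and cluster ids are relabeled by descending
#' cluster size. Fully reproducible given `seed`; permuting the input row
#' order only relabels clusters.
#'
#' @param profiles Numeric matrix, items x time points (row names carried
#'   into the result).
#' @param k Number of clusters (default 5).
#' @param seed Integer seed.
#' @param nstart Number of seeded k-means++ restarts; the solution with
#'   the lowest inertia is kept (default 10).
#' @return A list with `cluster` (named integer vector), `centers`,
#'   `inertia`, `k`, `method = "kmeans"`, `seed`.
#' @export
kmeansTimecourse <- function(profiles, k = 5L, seed = 1L, nstart = 10L) {
  if (k > nrow(profiles)) stop("k exceeds the number of items")
  x <- standardizeProfiles(profiles)
  set.seed(seed)
  if (k == 1L) {
    ctr <- matrix(colMeans(x), 1)
    cl <- rep(1L, nrow(x))
    inertia <- sum((x - ctr[rep(1, nrow(x)), , drop = FALSE])^2)
  } else {
    best <- NULL
    for (r in seq_len(nstart)) {
      init <- .kmeansPPInit(x, k)
      ## Lloyd refinement; kmeans() stops on assignment fixpoint, which
      ## implies relative inertia change < 1e-6 well before 300 iterations
      fit <- suppressWarnings(kmeans(x, centers = init, iter.max = 300,
                                     algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    cl <- best$cluster
    ctr <- best$centers
    inertia <- best$tot.withinss
  }
  sizes <- tabulate(cl, nbins = k)
  relabel <- order(sizes, decreasing = TRUE)
  map <- integer(k); map[relabel] <- seq_len(k)
  cl <- map[cl]
  ctr <- ctr[relabel, , drop = FALSE]
  rownames(ctr) <- NULL
  names(cl) <- rownames(profiles)
  list(cluster = cl, centers = ctr, inertia = inertia, k = k,
       method = "kmeans", seed = seed)
}

#' Concordance between proximal-peak accessibility and gene expression
#'
#' For every proximal peak with a linked gene present in the expression
#' matrix, the Spearman correlation between its per-time-point accessibility
#' and the linked gene's mean normalized expression across the matched time
#' points.
#'
#' @param peaks Classified peak GRanges with accessibility columns
#'   `acc_<time>` and `linkedGene`.
#' @param expr An expression list as returned by [generateExpression()] /
#'   [simpleDE()] input: `counts` (gene x sample) and `samples`
#'   (data.frame with `condition`).
#' @param times Time-point labels to use (default: all `acc_*` columns).
#' @return A list with `perPeak` (data.frame `peak`, `gene`, `rho`),
#'   `fractionPositive`, `medianRho` and `nUnlinked`.
#' @export
atacExpressionConcordance <- function(peaks, expr, times = NULL) {
  md <- S4Vectors::mcols(peaks)
  accCols <- grep("^acc_", colnames(md), value = TRUE)
  if (is.null(times)) times <- sub("^acc_", "", accCols)
  accCols <- paste0("acc_", times)
  sf <- colSums(expr$counts)
  norm <- sweep(expr$counts, 2, sf / mean(sf), "/")
  exprMeans <- vapply(times, function(tt) {
    rowMeans(norm[, expr$samples$condition == tt, drop = FALSE])
  }, numeric(nrow(norm)))
  prox <- which(peaks$class == "proximal" & !is.na(peaks$linkedGene) &
                  peaks$linkedGene %in% rownames(norm))
  nUnlinked <- sum(peaks$class == "proximal") - length(prox)
  accMat <- as.matrix(as.data.frame(md[, accCols, drop = FALSE]))
  rho <- vapply(prox, function(i) {
    suppressWarnings(cor(accMat[i, ], exprMeans[peaks$linkedGene[i], ],
                         method = "spearman"))
  }, numeric(1))
  perPeak <- data.frame(peak = prox, gene = peaks$linkedGene[prox], rho = rho)
  list(perPeak = perPeak,
       fractionPositive = mean(rho > 0, na.rm = TRUE),
       medianRho = median(rho, na.rm = TRUE),
       nUnlinked = nUnlinked)
}
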