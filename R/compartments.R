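#' Expected contact frequency by genomic distance
#'
#' `expected[d + 1]` is the mean of the unmasked matrix entries at diagonal
#' offset `|i - j| = d` (d = 0 .. n-1). A fully masked diagonal gives `NA`.
#'
#' @param m A symmetric per-chromosome contact matrix (raw or balanced).
#' @return Numeric vector of length `nrow(m)`.
#' @export
expectedByDistance <- function(m) {
  n <- nrow(m)
  d <- col(m) - row(m)
  keep <- d >= 0
  means <- tapply(m[keep], d[keep], .safeMean)
  out <- rep(NA_real_, n)
  out[as.integer(names(means)) + 1L] <- as.numeric(means)
  out
}

#' Observed/expected transformation
#'
#' Divides every entry by the mean of its diagonal, removing the
#' distance-decay trend: each diagonal of the result has mean 1 (within
#' 1e-9) wherever it carries observations. Masked (`NA`) rows propagate.
#' A zero expected value at a distance that carries observations is an
#' inconsistency and raises an error.
#'
#' @param m Symmetric contact matrix.
#' @param expected Optional precomputed [expectedByDistance()] vector.
#' @return The O/E matrix (same dimensions; `NA` where expected is 0 or
#'   masked).
#' @export
oeTransform <- function(m, expected = NULL) {
  if (is.null(expected)) expected <- expectedByDistance(m)
  n <- nrow(m)
  d <- abs(col(m) - row(m))
  e <- matrix(expected[d + 1L], n, n)
  zero <- !is.na(e) & e == 0
  if (any(zero & !is.na(m) & m > 0))
    stop("expected frequency 0 at a distance with observed contacts (inconsistent matrix)")
  e[zero] <- NA_real_
  m / e
}

#' @rdname oeTransform
#' @param cm A [ContactMatrix-class].
#' @return `observedOverExpected`: a named list of per-chromosome O/E
#'   matrices.
#' @export
observedOverExpected <- function(cm) {
  out <- lapply(chromNames(cm), function(chr) oeTransform(cmMatrix(cm, chr)))
  names(out) <- chromNames(cm)
  out
}

#' Pearson correlation map of an O/E matrix
#'
#' `C[i, j]` is the Pearson correlation of rows `i` and `j` of the O/E
#' matrix over pairwise-complete unmasked columns; the diagonal is 1.
#' Zero-variance rows come out `NA` and are masked downstream.
#'
#' @param oe An O/E matrix.
#' @return A symmetric correlation matrix.
#' @export
correlationMap <- function(oe) {
  C <- suppressWarnings(cor(oe, use = "pairwise.complete.obs"))
  ok <- apply(oe, 2, function(x) sum(is.finite(x)) >= 3 && sd(x, na.rm = TRUE) > 0)
  diag(C)[ok] <- 1
  C[!ok, ] <- NA_real_
  C[, !ok] <- NA_real_
  C
}

## PC1 of one centered correlation matrix. Returns list(pc1, note).
.pc1One <- function(corr, degenTol = 1e-8) {
  n <- nrow(corr)
  mask <- apply(corr, 1, function(x) all(is.na(x)))
  pc1 <- rep(NA_real_, n)
  if (sum(!mask) < 3) return(list(pc1 = pc1, note = "too few unmasked bins"))
  Cu <- corr[!mask, !mask, drop = FALSE]
  Cu[is.na(Cu)] <- 0
  Cc <- scale(Cu, center = TRUE, scale = FALSE)
  S <- (Cc + t(Cc)) / 2
  eig <- eigen(S, symmetric = TRUE)
  lam <- eig$values
  if ((lam[1] - lam[2]) < degenTol * max(1, abs(lam[1]))) {
    return(list(pc1 = pc1, note = "degenerate leading eigenvalue"))
  }
  pc1[!mask] <- eig$vectors[, 1]
  list(pc1 = pc1, note = NULL)
}

#' Call A/B compartments from the correlation map
#'
#' PC1 is the leading eigenvector of the centered Pearson correlation map,
#' computed per chromosome. The sign is oriented with an activity track
#' (e.g. H3K9ac): it is flipped if needed so that the mean activity over
#' PC1 > 0 bins is at least the mean over PC1 <= 0 bins; bins with PC1 > 0
#' are then labeled A, the rest B. A degenerate leading eigenvalue (within
#' 1e-8 of the second) masks the chromosome with a warning.
#'
#' @param cm A [ContactMatrix-class] (O/E and correlation computed
#'   internally), or a named list of precomputed correlation matrices.
#' @param activity A [SignalTrack-class] at the matrix bin size, or a named
#'   list of per-chromosome numeric vectors.
#' @param activityName Label recorded as the orientation source.
#' @return A [CompartmentProfile-class].
#' @export
compartmentPC1 <- function(cm, activity, activityName = NULL) {
  if (is(cm, "ContactMatrix")) {
    corrs <- lapply(observedOverExpected(cm), correlationMap)
    bs <- binSize(cm)
  } else {
    corrs <- cm
    bs <- NA_integer_
  }
  if (is(activity, "SignalTrack")) {
    if (is.null(activityName)) activityName <- activity@name
    act <- activity@values
  } else {
    act <- activity
    if (is.null(activityName)) activityName <- "activity"
  }
  pc1 <- list(); labels <- list()
  for (chr in names(corrs)) {
    res <- .pc1One(corrs[[chr]])
    v <- res$pc1
    if (!is.null(res$note)) {
      warning(sprintf("chromosome '%s': %s; all bins masked", chr, res$note))
      pc1[[chr]] <- v
      labels[[chr]] <- rep("masked", length(v))
      next
    }
    a <- act[[chr]]
    hi <- .safeMean(a[!is.na(v) & v > 0])
    lo <- .safeMean(a[!is.na(v) & v <= 0])
    if (is.finite(hi) && is.finite(lo) && hi < lo) v <- -v
    lab <- ifelse(is.na(v), "masked", ifelse(v > 0, "A", "B"))
    pc1[[chr]] <- v
    labels[[chr]] <- lab
  }
  new("CompartmentProfile", pc1 = pc1, labels = labels,
      orientation = activityName,
      binSize = if (is.na(bs)) 0L else as.integer(bs))
}

#' Reorder a matrix by a per-bin feature
#'
#' Rows and columns are permuted by ascending feature value, ties broken by
#' original bin index; `NA` feature bins are placed last and masked. Sorting
#' a correlation map by PC1 turns the checkerboard into a block-diagonal
#' portrait.
#'
#' @param m A square matrix.
#' @param feature Numeric vector, one value per bin.
#' @return A list with `matrix` (reordered, NA-masked trailing bins) and
#'   `permutation` (the bin order applied).
#' @export
sortMatrixByFeature <- function(m, feature) {
  stopifnot(length(feature) == nrow(m))
  ord <- order(feature, seq_along(feature), na.last = TRUE)
  out <- m[ord, ord, drop = FALSE]
  nNA <- sum(is.na(feature))
  if (nNA > 0) {
    tailIdx <- seq(nrow(m) - nNA + 1L, nrow(m))
    out[tailIdx, ] <- NA_real_
    out[, tailIdx] <- NA_real_
  }
  list(matrix = out, permutation = ord)
}

#' SaddleResult: quantile-binned mean O/E and compartment strength
#'
#' @slot S Q x Q matrix of mean O/E between PC1-quantile groups (group 1 =
#'   most-B, group Q = most-A).
#' @slot Q Number of quantile groups.
#' @slot corner Corner size c used for strength.
#' @slot strength Ratio-product strength (AA x BB) / (AB x BA).
#' @slot strengthSum Alternative (AA + BB) / (AB + BA) strength.
#' @slot cornerMeans Named vector of AA, BB, AB, BA corner means.
#' @export
setClass("SaddleResult",
  representation(S = "matrix", Q = "integer", corner = "integer",
                 strength = "numeric", strengthSum = "numeric",
                 cornerMeans = "numeric"))

setMethod("show", "SaddleResult", function(object) {
  cat(sprintf("SaddleResult: Q = %d, corner = %d, strength = %.3f (sum form %.3f)\n",
              object@Q, object@corner, object@strength, object@strengthSum))
  print(round(object@cornerMeans, 3))
})

#' Saddle plot and compartment strength
#'
#' Unmasked bins are ranked by PC1 genome-wide and split into `Q`
#' equal-occupancy groups; `S[q1, q2]` is the mean O/E over intra-chromosomal
#' bin pairs in those groups, excluding near-diagonal pairs (`|i - j| <
#' minSep` bins). Compartment strength is the ratio product
#' `(mean AA corner x mean BB corner) / (mean AB x mean BA)` over the
#' `corner x corner` extreme groups; the sum form is also reported.
#'
#' @param cm A [ContactMatrix-class], a single O/E matrix, or a named list
#'   of per-chromosome O/E matrices.
#' @param profile A [CompartmentProfile-class], or a numeric PC1 vector /
#'   named list of vectors aligned with the matrices.
#' @param Q Number of quantile groups (default 50).
#' @param corner Corner size (default 5).
#' @param minSep Near-diagonal exclusion in bins (default 2).
#' @return A [SaddleResult-class].
#' @export
saddlePlot <- function(cm, profile, Q = 50L, corner = 5L, minSep = 2L) {
  if (is(cm, "ContactMatrix")) {
    oes <- observedOverExpected(cm)
  } else if (is.matrix(cm)) {
    oes <- list(chr = cm)
  } else oes <- cm
  if (is(profile, "CompartmentProfile")) {
    pcs <- profile@pc1[names(oes)]
  } else if (is.numeric(profile)) {
    pcs <- list(chr = profile)
    names(pcs) <- names(oes)
  } else pcs <- profile[names(oes)]
  allPc <- unlist(pcs, use.names = FALSE)
  unm <- sum(is.finite(allPc))
  if (Q > unm) stop(sprintf("Q = %d exceeds the %d unmasked bins", Q, unm))
  ranks <- rank(allPc, ties.method = "first", na.last = "keep")
  groupAll <- ceiling(ranks * Q / unm)
  offs <- c(0, cumsum(vapply(pcs, length, integer(1))))
  sums <- matrix(0, Q, Q); cnts <- matrix(0, Q, Q)
  for (k in seq_along(oes)) {
    oe <- oes[[k]]
    g <- groupAll[(offs[k] + 1):offs[k + 1]]
    n <- nrow(oe)
    d <- abs(col(oe) - row(oe))
    G1 <- matrix(g[row(oe)], n, n)
    G2 <- matrix(g[col(oe)], n, n)
    keep <- d >= minSep & is.finite(oe) & !is.na(G1) & !is.na(G2)
    if (!any(keep)) next
    idx <- cbind(G1[keep], G2[keep])
    val <- oe[keep]
    agg <- tapply(val, list(factor(idx[, 1], levels = 1:Q),
                            factor(idx[, 2], levels = 1:Q)), sum)
    cnt <- tapply(rep(1, length(val)), list(factor(idx[, 1], levels = 1:Q),
                                            factor(idx[, 2], levels = 1:Q)), sum)
    agg[is.na(agg)] <- 0; cnt[is.na(cnt)] <- 0
    sums <- sums + agg; cnts <- cnts + cnt
  }
  S <- sums / cnts
  cc <- as.integer(corner)
  hi <- (Q - cc + 1):Q; lo <- 1:cc
  mAA <- .safeMean(S[hi, hi]); mBB <- .safeMean(S[lo, lo])
  mAB <- .safeMean(S[lo, hi]); mBA <- .safeMean(S[hi, lo])
  new("SaddleResult", S = S, Q = as.integer(Q), corner = cc,
      strength = (mAA * mBB) / (mAB * mBA),
      strengthSum = (mAA + mBB) / (mAB + mBA),
      cornerMeans = c(AA = mAA, BB = mBB, AB = mAB, BA = mBA))
}

#' P(s) scaling curve for arms or pericentromeres
#'
#' Mean raw contact frequency against genomic separation, over bin pairs
#' with both bins inside the region class, pooled across chromosomes into
#' log2-spaced distance bins. Counts are reported raw (not
#' depth-normalized), so condition-dependent library sizes show up as
#' frequency changes. A log-log least-squares slope is fitted over
#' `fitRange` (default 3 bins to a quarter of the region span).
#'
#' @param cm A [ContactMatrix-class] (raw counts).
#' @param regionClass `"arm"` or `"pericentromere"`.
#' @param fitRange Length-2 numeric, distance range in bp for the slope fit.
#' @param logStep Log2 spacing of the distance bins (default 0.5).
#' @return A list with `curve` (data.frame `s`, `freq`, `n`), `slope`,
#'   `regionClass` and `condition`.
#' @export
scalingCurve <- function(cm, regionClass = c("arm", "pericentromere"),
                         fitRange = NULL, logStep = 0.5) {
  regionClass <- match.arg(regionClass)
  layout <- genomeLayout(cm)
  bs <- binSize(cm)
  sums <- list(); spans <- numeric(0)
  acc <- NULL
  for (chr in chromNames(cm)) {
    idx <- if (regionClass == "arm") armBins(layout, chr) else periBins(layout, chr)
    if (length(idx) < 2) {
      warning(sprintf("no %s bins on '%s'; chromosome skipped", regionClass, chr))
      next
    }
    spans <- c(spans, length(idx) * bs)
    m <- cmMatrix(cm, chr)[idx, idx, drop = FALSE]
    d <- abs(outer(idx, idx, "-"))
    keep <- upper.tri(m) & d >= 1 & is.finite(m)
    df <- data.frame(d = d[keep], x = m[keep])
    acc <- if (is.null(acc)) df else rbind(acc, df)
  }
  if (is.null(acc)) stop("no usable region bins on any chromosome")
  maxd <- max(acc$d)
  breaks <- unique(c(2^seq(0, ceiling(log2(maxd)) + logStep, by = logStep)))
  bin <- cut(acc$d, breaks = c(0, breaks), right = TRUE)
  tot <- tapply(acc$x, bin, sum)
  n <- tapply(rep(1, nrow(acc)), bin, sum)
  gm <- tapply(acc$d, bin, function(z) exp(mean(log(z))))
  keep <- !is.na(tot) & n > 0
  curve <- data.frame(s = as.numeric(gm[keep]) * bs,
                      freq = as.numeric(tot[keep] / n[keep]),
                      n = as.numeric(n[keep]))
  curve <- curve[order(curve$s), ]
  if (is.null(fitRange)) fitRange <- c(3 * bs, mean(spans) / 4)
  fitPts <- curve$s >= fitRange[1] & curve$s <= fitRange[2] & curve$freq > 0
  slope <- if (sum(fitPts) >= 3) {
    unname(coef(stats::lm(log(freq) ~ log(s), data = curve[fitPts, ]))[2])
  } else NA_real_
  list(curve = curve, slope = slope, fitRange = fitRange,
       regionClass = regionClass, condition = condition(cm))
}

#' Depth-normalized difference map between two contact matrices
#'
#' Both matrices are scaled to counts per million valid pairs before
#' subtraction; positive entries are enriched in `a` (e.g. RNAPII HiChIP
#' over Hi-C highlights polymerase-anchored contacts).
#'
#' @param a,b [ContactMatrix-class] objects on the same binning.
#' @return Named list of per-chromosome difference matrices (`a - b`, CPM).
#' @export
differenceMap <- function(a, b) {
  if (binSize(a) != binSize(b) ||
      !identical(chromNames(a), chromNames(b)) ||
      !identical(nBins(genomeLayout(a)), nBins(genomeLayout(b))))
    stop("contact matrices are on different binnings")
  fa <- 1e6 / totalPairs(a); fb <- 1e6 / totalPairs(b)
  out <- lapply(chromNames(a), function(chr)
    cmMatrix(a, chr) * fa - cmMatrix(b, chr) * fb)
  names(out) <- chromNames(a)
  out
}
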