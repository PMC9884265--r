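#' Call significant interactions with a cumulative binomial model
#'
#' For every intra-chromosomal bin pair (i, j) with `minDistBins <= j - i <=
#' maxDistBins`, the expected contact probability is the product of the bin
#' marginal frequencies times a distance-decay weight, renormalized so the
#' expected probabilities over all tested pairs sum to 1:
#' `p0 = (cov_i / N) (cov_j / N) f(|i - j|) / Z`. The p-value is the upper
#' binomial tail `P(X >= k)` for `X ~ Binomial(N, p0)` (computed through the
#' regularized incomplete beta function via [stats::pbinom()]). `N` is the
#' total intra-chromosomal pair count. Output is deterministic and invariant
#' to input pair order.
#'
#' @param cm A raw (unbalanced) [ContactMatrix-class].
#' @param minDistBins,maxDistBins Tested distance range in bins.
#' @param alpha Significance threshold (default 0.05, the caller's standard).
#' @param correction `"BH"` (Benjamini-Hochberg on all tested pairs) or
#'   `"none"` (raw p threshold).
#' @param keepAll Return all tested pairs (with a `significant` flag) rather
#'   than only the significant ones.
#' @return A data.frame with columns `chrom`, `bin1`, `bin2`, `count`,
#'   `expected` (expected count `N * p0`), `p0`, `p`, `padj`, `significant`.
#' @export
callInteractions <- function(cm, minDistBins = 2L, maxDistBins = 100L,
                             alpha = 0.05, correction = c("BH", "none"),
                             keepAll = FALSE) {
  correction <- match.arg(correction)
  N <- sum(vapply(chromNames(cm), function(chr) {
    m <- cmMatrix(cm, chr)
    (sum(m, na.rm = TRUE) + sum(diag(m), na.rm = TRUE)) / 2
  }, numeric(1)))
  if (N <= 0) stop("total intrachromosomal pair count is zero")
  Z <- 0
  rows <- lapply(chromNames(cm), function(chr) {
    m <- cmMatrix(cm, chr)
    n <- nrow(m)
    cov <- rowSums(m, na.rm = TRUE)
    ed <- expectedByDistance(m)
    ed[is.na(ed)] <- 0
    ## raw weights over ALL unordered pairs: the renormalization constant
    ## makes the expected probabilities a distribution over the whole matrix
    w <- outer(cov / N, cov / N) * matrix(ed[abs(col(m) - row(m)) + 1L], n, n)
    Z <<- Z + sum(w[upper.tri(w, diag = TRUE)])
    ij <- which(upper.tri(m), arr.ind = TRUE)
    d <- ij[, 2] - ij[, 1]
    keep <- d >= minDistBins & d <= maxDistBins
    ij <- ij[keep, , drop = FALSE]
    if (nrow(ij) == 0L) return(NULL)
    data.frame(chrom = chr, bin1 = ij[, 1], bin2 = ij[, 2],
               count = m[ij], p0raw = w[ij])
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df) || nrow(df) == 0L) stop("no bin pairs in the tested distance range")
  df$p0 <- df$p0raw / Z
  df$p0raw <- NULL
  if (any(df$p0 >= 1)) stop("expected probability >= 1 for a pair (model violation)")
  df$expected <- N * df$p0
  df$p <- pbinom(df$count - 1, size = round(N), prob = df$p0, lower.tail = FALSE)
  df$padj <- p.adjust(df$p, method = "BH")
  df$significant <- if (correction == "BH") df$padj <= alpha else df$p <= alpha
  df <- df[order(df$chrom, df$bin1, df$bin2), ]
  rownames(df) <- NULL
  if (keepAll) df else df[df$significant, , drop = FALSE]
}

#' Annotate interaction anchors and apply the standard filters
#'
#' Each anchor bin is labeled `promoter` if it overlaps a gene promoter,
#' `RE` if it overlaps a distal regulatory-element peak, else `other`.
#' Self-loops (identical anchors) and duplicate unordered pairs are removed,
#' as are interactions without any gene annotation (gene body or promoter)
#' on at least one anchor (`requireBoth = TRUE` demands both anchors).
#'
#' @param ints Interaction data.frame from [callInteractions()].
#' @param layout The [GenomeLayout-class] of the calling resolution.
#' @param genes Gene GRanges with `gene_id`.
#' @param rePeaks GRanges of distal RE peaks (may be empty).
#' @param promoterBp Promoter width used for anchor promoter labels.
#' @param requireBoth Require gene annotation on both anchors.
#' @return The filtered data.frame with `anchor1Class`, `anchor2Class`
#'   columns added.
#' @export
annotateAnchors <- function(ints, layout, genes, rePeaks = NULL,
                            promoterBp = 1500L, requireBoth = FALSE) {
  if (nrow(ints) == 0L) {
    ints$anchor1Class <- character(0); ints$anchor2Class <- character(0)
    return(ints)
  }
  ints <- ints[ints$bin1 != ints$bin2, , drop = FALSE]            # self-loops
  key <- paste(ints$chrom, pmin(ints$bin1, ints$bin2), pmax(ints$bin1, ints$bin2))
  ints <- ints[!duplicated(key), , drop = FALSE]                  # duplicates
  if (nrow(ints) == 0L) {
    ints$anchor1Class <- character(0); ints$anchor2Class <- character(0)
    return(ints)
  }
  bs <- binSize(layout)
  anchorGR <- function(bin) {
    starts <- (bin - 1) * bs + 1
    GenomicRanges::GRanges(ints$chrom,
      IRanges::IRanges(starts, pmin(starts + bs - 1, chromLengths(layout)[ints$chrom])))
  }
  a1 <- anchorGR(ints$bin1); a2 <- anchorGR(ints$bin2)
  prom <- genePromoters(genes, upstream = promoterBp)
  classify <- function(a) {
    cls <- rep("other", length(a))
    if (!is.null(rePeaks) && length(rePeaks))
      cls[IRanges::overlapsAny(a, rePeaks)] <- "RE"
    cls[IRanges::overlapsAny(a, prom)] <- "promoter"
    cls
  }
  ints$anchor1Class <- classify(a1)
  ints$anchor2Class <- classify(a2)
  geneSpace <- c(GenomicRanges::granges(genes), GenomicRanges::granges(prom))
  g1 <- IRanges::overlapsAny(a1, geneSpace)
  g2 <- IRanges::overlapsAny(a2, geneSpace)
  keep <- if (requireBoth) g1 & g2 else g1 | g2
  out <- ints[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratify interactions by anchor accessibility
#'
#' Each interaction is assigned the number of anchors overlapping an
#' accessible peak (category 0, 1 or 2); interaction strength is the O/E
#' value at the pixel. The summary reports per-category counts and
#' mean/median strength.
#'
#' @param ints Interaction data.frame (`chrom`, `bin1`, `bin2`).
#' @param cm The [ContactMatrix-class] the interactions were called on
#'   (used for the O/E strength).
#' @param atacPeaks GRanges of accessible peaks for the matched condition
#'   (may be `NULL`/empty: all interactions fall in category 0).
#' @return A list with `interactions` (input plus `category` and `strength`)
#'   and `summary` (per-category data.frame).
#' @export
accessibilityStrata <- function(ints, cm, atacPeaks = NULL) {
  layout <- genomeLayout(cm)
  bs <- binSize(layout)
  oes <- observedOverExpected(cm)
  n <- nrow(ints)
  cat01 <- function(bin) {
    if (is.null(atacPeaks) || length(atacPeaks) == 0L) return(rep(FALSE, n))
    starts <- (bin - 1) * bs + 1
    a <- GenomicRanges::GRanges(ints$chrom,
      IRanges::IRanges(starts, pmin(starts + bs - 1, chromLengths(layout)[ints$chrom])))
    IRanges::overlapsAny(a, atacPeaks)
  }
  ints$category <- as.integer(cat01(ints$bin1)) + as.integer(cat01(ints$bin2))
  ints$strength <- vapply(seq_len(n), function(i)
    oes[[ints$chrom[i]]][ints$bin1[i], ints$bin2[i]], numeric(1))
  summ <- do.call(rbind, lapply(0:2, function(k) {
    s <- ints$strength[ints$category == k]
    data.frame(category = k, n = length(s),
               meanStrength = .safeMean(s),
               medianStrength = if (length(s)) median(s, na.rm = TRUE) else NA_real_)
  }))
  list(interactions = ints, summary = summ)
}

#' Detect promoter-centric and RE-centric hubs
#'
#' From the bipartite promoter-RE graph of significant annotated
#' interactions: promoters contacting at least `hubMin` distinct REs form
#' promoter-centric hubs; REs contacting at least `hubMin` distinct
#' promoters form RE-centric hubs. Anchors are identified by their bin
#' (`chrom:bin`).
#'
#' @param ints Annotated interaction data.frame (needs `anchor1Class`,
#'   `anchor2Class`).
#' @param hubMin Minimum number of distinct partners (default 2).
#' @return A list with `promoterHubs` and `reHubs`, each a named list
#'   mapping the hub anchor to its partner anchors.
#' @export
detectHubs <- function(ints, hubMin = 2L) {
  stopifnot(hubMin >= 2L)
  id1 <- paste0(ints$chrom, ":", ints$bin1)
  id2 <- paste0(ints$chrom, ":", ints$bin2)
  pr <- c(ifelse(ints$anchor1Class == "promoter" & ints$anchor2Class == "RE", id1, NA),
          ifelse(ints$anchor2Class == "promoter" & ints$anchor1Class == "RE", id2, NA))
  re <- c(ifelse(ints$anchor1Class == "promoter" & ints$anchor2Class == "RE", id2, NA),
          ifelse(ints$anchor2Class == "promoter" & ints$anchor1Class == "RE", id1, NA))
  keep <- !is.na(pr)
  pr <- pr[keep]; re <- re[keep]
  promoterHubs <- lapply(split(re, pr), unique)
  promoterHubs <- promoterHubs[vapply(promoterHubs, length, integer(1)) >= hubMin]
  reHubs <- lapply(split(pr, re), unique)
  reHubs <- reHubs[vapply(reHubs, length, integer(1)) >= hubMin]
  list(promoterHubs = promoterHubs, reHubs = reHubs)
}

#' Differential interactions between two conditions
#'
#' For every unordered bin pair in the union of the two called sets, a 2x2
#' table `(k_a, Na - k_a; k_b, Nb - k_b)` is tested with Fisher's exact test
#' (two-sided), BH-adjusted, and labeled `gained` (enriched in `a`) or
#' `lost`. Swapping the two conditions flips the direction labels and leaves
#' the p-values unchanged.
#'
#' @param a,b Interaction data.frames for the two conditions (typically the
#'   significant calls; `allA`/`allB` supply counts for pairs absent from
#'   the other condition's table).
#' @param Na,Nb Library sizes (total intra-chromosomal pairs).
#' @param alpha BH threshold for the direction call (default 0.05).
#' @param allA,allB Optional full (keepAll) tables used to look up counts.
#' @return A data.frame with `chrom`, `bin1`, `bin2`, `countA`, `countB`,
#'   `p`, `padj`, `direction` (`gained`/`lost`/`ns`).
#' @export
differentialInteractions <- function(a, b, Na, Nb, alpha = 0.05,
                                     allA = NULL, allB = NULL) {
  if (Na <= 0 || Nb <= 0) stop("library sizes must be positive")
  keyOf <- function(df) paste(df$chrom, pmin(df$bin1, df$bin2), pmax(df$bin1, df$bin2))
  keys <- union(keyOf(a), keyOf(b))
  if (length(keys) == 0L)
    return(data.frame(chrom = character(0), bin1 = integer(0),
                      bin2 = integer(0), countA = numeric(0),
                      countB = numeric(0), p = numeric(0),
                      padj = numeric(0), direction = character(0)))
  lookup <- function(df, keys) {
    k <- setNames(df$count, keyOf(df))
    out <- k[keys]
    out[is.na(out)] <- 0
    unname(out)
  }
  kA <- lookup(if (is.null(allA)) a else allA, keys)
  kB <- lookup(if (is.null(allB)) b else allB, keys)
  parts <- do.call(rbind, strsplit(keys, " "))
  res <- data.frame(chrom = parts[, 1],
                    bin1 = as.integer(parts[, 2]),
                    bin2 = as.integer(parts[, 3]),
                    countA = kA, countB = kB)
  res$p <- vapply(seq_len(nrow(res)), function(i) {
    tab <- matrix(c(kA[i], Na - kA[i], kB[i], Nb - kB[i]), 2, 2)
    fisher.test(round(tab))$p.value
  }, numeric(1))
  res$padj <- p.adjust(res$p, method = "BH")
  rateA <- kA / Na; rateB <- kB / Nb
  res$direction <- ifelse(res$padj > alpha, "ns",
                          ifelse(rateA > rateB, "gained", "lost"))
  res <- res[order(res$chrom, res$bin1, res$bin2), ]
  rownames(res) <- NULL
  res
}

#' Aggregate peak analysis (APA)
#'
#' Stacks `(2w+1) x (2w+1)` O/E submatrices centered on each loop pixel and
#' averages them. The center score is the center pixel divided by the mean
#' of the 3x3 lower-left (short-distance) background corner. Loops closer
#' than `w` bins to a matrix edge, or with anchor separation `<= 2w`, are
#' excluded and counted.
#'
#' @param cm A [ContactMatrix-class].
#' @param loops data.frame with `chrom`, `bin1`, `bin2` (bin1 < bin2) at the
#'   matrix binning.
#' @param w Half-window in bins (default 5; must be >= 3).
#' @return A list with `matrix` (the stacked mean O/E), `score`, `nLoops`
#'   (used) and `nExcluded`.
#' @export
apa <- function(cm, loops, w = 5L) {
  stopifnot(w >= 3L)
  oes <- observedOverExpected(cm)
  size <- 2L * w + 1L
  acc <- matrix(0, size, size); cnt <- matrix(0, size, size)
  used <- 0L; excluded <- 0L
  for (i in seq_len(nrow(loops))) {
    chr <- loops$chrom[i]
    b1 <- min(loops$bin1[i], loops$bin2[i])
    b2 <- max(loops$bin1[i], loops$bin2[i])
    n <- nrow(oes[[chr]])
    if (b1 - w < 1 || b2 + w > n || (b2 - b1) <= 2L * w) {
      excluded <- excluded + 1L
      next
    }
    win <- oes[[chr]][(b1 - w):(b1 + w), (b2 - w):(b2 + w)]
    ok <- is.finite(win)
    acc[ok] <- acc[ok] + win[ok]
    cnt[ok] <- cnt[ok] + 1
    used <- used + 1L
  }
  if (used == 0L) stop("no usable loops for APA")
  S <- acc / cnt
  ctr <- S[w + 1L, w + 1L]
  bg <- .safeMean(S[(size - 2L):size, 1:3])
  list(matrix = S, score = ctr / bg, nLoops = used, nExcluded = excluded)
}
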