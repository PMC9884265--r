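#' Bin valid pairs into a contact matrix
#'
#' Each valid pair increments exactly one unordered bin pair; both triangles
#' of the per-chromosome matrices are kept consistent and the total pair
#' count is conserved. Inter-chromosomal pairs are counted in `totalPairs`
#' but do not enter the (intra-chromosomal) matrices.
#'
#' @param pairs Valid-pairs data.frame (`chromA`, `posA`, `chromB`, `posB`).
#' @param layout A [GenomeLayout-class].
#' @param assay,condition Metadata for the returned matrix.
#' @return A raw [ContactMatrix-class].
#' @export
binPairs <- function(pairs, layout, assay = "HiC", condition = "0h") {
  nb <- nBins(layout)
  known <- chromNames(layout)
  bad <- which(!(pairs$chromA %in% known) | !(pairs$chromB %in% known))
  if (length(bad))
    stop("pair(s) on unknown chromosome at record ",
         paste(head(bad, 5), collapse = ", "))
  mats <- lapply(known, function(chr) matrix(0, nb[chr], nb[chr]))
  names(mats) <- known
  cis <- pairs$chromA == pairs$chromB
  if (any(cis)) {
    sub <- pairs[cis, , drop = FALSE]
    bi <- binIndex(layout, sub$chromA, sub$posA)
    bj <- binIndex(layout, sub$chromB, sub$posB)
    lo <- pmin(bi, bj); hi <- pmax(bi, bj)
    for (chr in unique(sub$chromA)) {
      sel <- sub$chromA == chr
      tab <- table(paste(lo[sel], hi[sel]))
      ij <- do.call(rbind, strsplit(names(tab), " "))
      i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
      m <- mats[[chr]]
      m[cbind(i, j)] <- m[cbind(i, j)] + as.numeric(tab)
      m[cbind(j, i)] <- m[cbind(i, j)]
      mats[[chr]] <- m
    }
  }
  ContactMatrix(mats, layout, assay = assay, condition = condition,
                balanced = FALSE, totalPairs = nrow(pairs))
}

## Iterative proportional fitting of one symmetric matrix.
## Bins with marginal < maskFrac * median(positive marginals) are masked (NA).
.balanceOne <- function(m, maxIter, tol, maskFrac) {
  marg <- rowSums(m, na.rm = TRUE)
  medm <- median(marg[marg > 0])
  mask <- marg < maskFrac * medm | marg == 0
  if (all(mask)) return(list(m = m * NA_real_, converged = TRUE, mask = mask))
  w <- m
  w[mask, ] <- NA; w[, mask] <- NA
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    rs <- rowSums(w, na.rm = TRUE)
    rs[mask] <- NA
    b <- rs / mean(rs, na.rm = TRUE)
    dev <- max(abs(b - 1), na.rm = TRUE)
    if (dev < tol) { converged <- TRUE; break }
    b[mask | b == 0] <- 1
    w <- w / outer(b, b)
  }
  ## normalize so unmasked row sums average 1
  s <- mean(rowSums(w, na.rm = TRUE)[!mask])
  if (is.finite(s) && s > 0) w <- w / s
  list(m = w, converged = converged, mask = mask)
}

#' Balance a contact matrix by iterative correction
#'
#' Iterative proportional fitting (ICE-style) per chromosome: rows and
#' columns are repeatedly divided by their marginals until unmasked row sums
#' agree within `tol` (relative). Bins whose raw marginal falls below
#' `maskFrac` of the median positive marginal are masked (`NA`). Balancing is
#' idempotent and invariant to global scaling of the input. On
#' non-convergence the best iterate is returned with a warning.
#'
#' @param cm A raw [ContactMatrix-class].
#' @param maxIter Maximum iterations (default 200).
#' @param tol Relative tolerance on row-sum equality (default 1e-3).
#' @param maskFrac Marginal-to-median ratio below which a bin is masked.
#' @return A balanced [ContactMatrix-class] (`balanced` flag set).
#' @export
balanceMatrix <- function(cm, maxIter = 200L, tol = 1e-3, maskFrac = 0.05) {
  mats <- lapply(chromNames(cm), function(chr) {
    res <- .balanceOne(cmMatrix(cm, chr), maxIter, tol, maskFrac)
    if (!res$converged)
      warning(sprintf("balancing did not converge on '%s' in %d iterations; best iterate returned",
                      chr, maxIter))
    res$m
  })
  names(mats) <- chromNames(cm)
  ContactMatrix(mats, genomeLayout(cm), assay = cm@assay,
                condition = cm@condition, balanced = TRUE,
                totalPairs = totalPairs(cm))
}

#' Design capture baits tiling gene promoters
#'
#' Promoters (1.5 kb upstream of the strand-aware TSS by default) are tiled
#' left to right with probes of `probeLen` bp at stride `step`; a final probe
#' is right-aligned so the promoter end is always covered. Promoters shorter
#' than one probe get a single centered probe. Probes are clipped to
#' chromosome bounds and deduplicated by coordinate.
#'
#' @param genes Gene GRanges with strand and `gene_id`.
#' @param probeLen Probe length in bp (default 120).
#' @param step Tiling stride in bp (default `probeLen`, non-overlapping).
#' @param promoterBp Promoter length upstream of the TSS (default 1500).
#' @return A GRanges of unique bait intervals.
#' @export
designCaptureBaits <- function(genes, probeLen = 120L, step = probeLen,
                               promoterBp = 1500L) {
  prom <- genePromoters(genes, upstream = promoterBp)
  baits <- lapply(seq_along(prom), function(i) {
    s <- BiocGenerics::start(prom)[i]
    e <- BiocGenerics::end(prom)[i]
    w <- e - s + 1
    if (w < probeLen) {
      mid <- (s + e) %/% 2
      st <- max(1L, mid - probeLen %/% 2)
      return(IRanges::IRanges(st, st + probeLen - 1L))
    }
    starts <- seq(s, e - probeLen + 1, by = step)
    last <- e - probeLen + 1
    if (tail(starts, 1) != last) starts <- c(starts, last)
    IRanges::IRanges(starts, starts + probeLen - 1L)
  })
  chroms <- rep(as.character(GenomeInfoDb::seqnames(prom)),
                vapply(baits, length, integer(1)))
  gr <- GenomicRanges::GRanges(chroms, do.call(c, baits))
  if (!is.null(GenomeInfoDb::seqlengths(genes)) &&
      !all(is.na(GenomeInfoDb::seqlengths(genes)))) {
    GenomeInfoDb::seqlengths(gr) <-
      GenomeInfoDb::seqlengths(genes)[GenomeInfoDb::seqlevels(gr)]
    gr <- suppressWarnings(GenomicRanges::trim(gr))
  }
  unique(sort(gr))
}

#' Summarize a signal track over regions
#'
#' One value per region: the `stat` of the track bins overlapping the region,
#' ignoring `NA` (unmappable) bins. Regions lying entirely in `NA` bins give
#' `NA`.
#'
#' @param track A [SignalTrack-class].
#' @param regions A GRanges of regions.
#' @param stat `"mean"`, `"max"` or `"sum"`.
#' @return Numeric vector, one value per region.
#' @export
summarizeTrack <- function(track, regions, stat = c("mean", "max", "sum")) {
  stat <- match.arg(stat)
  f <- switch(stat, mean = mean, max = max, sum = sum)
  if (length(regions) == 0L) return(numeric(0))
  bs <- track@binSize
  vapply(seq_along(regions), function(i) {
    chr <- as.character(GenomeInfoDb::seqnames(regions))[i]
    v <- trackValues(track, chr)
    if (is.null(v)) stop("region on chromosome absent from track: ", chr)
    b1 <- as.integer((BiocGenerics::start(regions)[i] - 1) %/% bs) + 1L
    b2 <- as.integer((BiocGenerics::end(regions)[i] - 1) %/% bs) + 1L
    b2 <- min(b2, length(v))
    x <- v[b1:b2]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_real_)
    f(x)
  }, numeric(1))
}

#' Re-bin a signal track to a coarser resolution
#'
#' Bin values are averaged (ignoring `NA`) into bins of `newBinSize`, which
#' must be a multiple of the track's bin size.
#'
#' @param track A [SignalTrack-class].
#' @param newBinSize Target bin size (bp).
#' @return A [SignalTrack-class] at the new resolution.
#' @export
rebinTrack <- function(track, newBinSize) {
  k <- newBinSize / track@binSize
  if (abs(k - round(k)) > 1e-9)
    stop("newBinSize must be a multiple of the track bin size")
  k <- as.integer(round(k))
  layout <- track@layout
  nbNew <- ceiling(chromLengths(layout) / newBinSize)
  vals <- lapply(chromNames(layout), function(chr) {
    v <- trackValues(track, chr)
    grp <- (seq_along(v) - 1L) %/% k + 1L
    out <- as.numeric(tapply(v, grp, .safeMean))
    length(out) <- nbNew[chr]
    out
  })
  names(vals) <- chromNames(layout)
  SignalTrack(track@name, vals, layout, newBinSize, track@condition)
}
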