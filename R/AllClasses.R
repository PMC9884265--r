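#' @import methods
#' @importFrom stats cor fisher.test kmeans p.adjust pbinom prcomp pt
#'   quantile rgamma rlnorm rmultinom rnbinom rnorm runif sd setNames
#'   t.test median aggregate var dist coef lm
#' @importFrom utils read.table write.table head tail
NULL

## ---------------------------------------------------------------------------
## GenomeLayout
## ---------------------------------------------------------------------------

#' GenomeLayout: chromosomes, pericentromeres and a bin grid
#'
#' Holds an ordered set of chromosomes with lengths, one pericentromeric
#' interval per chromosome (1-based, closed), and a bin size. Bins tile each
#' chromosome left to right; the last bin may be short. Chromosome arms are
#' everything outside the pericentromere.
#'
#' @slot chromLengths Named numeric vector of chromosome lengths (bp), in
#'   file/definition order.
#' @slot pericentromere Two-column matrix (`start`, `end`, bp, 1-based closed)
#'   with one row per chromosome, rownames matching `chromLengths`.
#' @slot binSize Integer bin size in bp.
#' @export
setClass("GenomeLayout",
  representation(
    chromLengths = "numeric",
    pericentromere = "matrix",
    binSize = "integer"
  )
)

setValidity("GenomeLayout", function(object) {
  msgs <- character()
  len <- object@chromLengths
  if (is.null(names(len)) || anyDuplicated(names(len)))
    msgs <- c(msgs, "chromosome names must be unique and non-empty")
  if (any(len <= 0)) msgs <- c(msgs, "chromosome lengths must be > 0")
  if (object@binSize < 1L) msgs <- c(msgs, "bin size must be >= 1")
  pc <- object@pericentromere
  if (!identical(rownames(pc), names(len)) || ncol(pc) != 2L) {
    msgs <- c(msgs, "pericentromere must have one (start,end) row per chromosome")
  } else {
    for (chr in names(len)) {
      s <- pc[chr, 1]; e <- pc[chr, 2]
      if (s < 1 || e > len[chr] || s >= e)
        msgs <- c(msgs, sprintf(
          "pericentromere of '%s' [%s,%s] not strictly inside chromosome (length %s)",
          chr, s, e, len[chr]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeLayout
#'
#' @param chromLengths Named numeric vector of chromosome lengths in bp.
#' @param pericentromere Named list (or 2-column matrix) of `c(start, end)`
#'   1-based closed pericentromeric intervals, one per chromosome.
#' @param binSize Bin size in bp.
#' @return A [GenomeLayout-class] object.
#' @examples
#' gl <- GenomeLayout(c(chr1 = 1e6), list(chr1 = c(4e5, 6e5)), binSize = 1e4)
#' nBins(gl)
#' @export
GenomeLayout <- function(chromLengths, pericentromere, binSize) {
  if (is.list(pericentromere)) {
    pericentromere <- do.call(rbind, pericentromere[names(chromLengths)])
  }
  pericentromere <- as.matrix(pericentromere)
  rownames(pericentromere) <- names(chromLengths)
  colnames(pericentromere) <- c("start", "end")
  new("GenomeLayout",
      chromLengths = chromLengths,
      pericentromere = pericentromere,
      binSize = as.integer(binSize))
}

#' @rdname GenomeLayout
#' @param object,x A GenomeLayout.
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname GenomeLayout
#' @export
setMethod("chromNames", "GenomeLayout", function(x) names(x@chromLengths))

#' @rdname GenomeLayout
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeLayout
#' @export
setMethod("chromLengths", "GenomeLayout", function(x) x@chromLengths)

#' @rdname GenomeLayout
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname GenomeLayout
#' @export
setMethod("binSize", "GenomeLayout", function(x) x@binSize)

#' Number of bins per chromosome
#'
#' @param x A GenomeLayout.
#' @return Named integer vector of per-chromosome bin counts.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname nBins
#' @export
setMethod("nBins", "GenomeLayout", function(x) {
  setNames(as.integer(ceiling(x@chromLengths / x@binSize)),
           names(x@chromLengths))
})

setMethod("show", "GenomeLayout", function(object) {
  cat(sprintf("GenomeLayout: %d chromosome(s), bin size %d bp, %d bins total\n",
              length(object@chromLengths), object@binSize, sum(nBins(object))))
  for (chr in chromNames(object)) {
    cat(sprintf("  %s: %s bp, pericentromere [%s, %s]\n", chr,
                format(object@chromLengths[chr], big.mark = ","),
                format(object@pericentromere[chr, 1], big.mark = ","),
                format(object@pericentromere[chr, 2], big.mark = ",")))
  }
})

#' Bin coordinates of a layout as GRanges
#'
#' One range per bin, tiling each chromosome; metadata column `bin` holds the
#' per-chromosome 1-based bin index.
#'
#' @param layout A GenomeLayout.
#' @param chrom Optional chromosome name to restrict to.
#' @return A [GenomicRanges::GRanges] of bins.
#' @export
binRanges <- function(layout, chrom = NULL) {
  chroms <- if (is.null(chrom)) chromNames(layout) else chrom
  grl <- lapply(chroms, function(chr) {
    n <- nBins(layout)[chr]
    starts <- (seq_len(n) - 1L) * layout@binSize + 1L
    ends <- pmin(starts + layout@binSize - 1L, chromLengths(layout)[chr])
    GenomicRanges::GRanges(factor(rep(chr, n), levels = chroms),
                           IRanges::IRanges(starts, ends), bin = seq_len(n))
  })
  gr <- do.call(c, grl)
  GenomeInfoDb::seqlengths(gr) <- chromLengths(layout)[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Map a genomic position to its bin index
#'
#' @param layout A GenomeLayout.
#' @param chrom Chromosome name(s).
#' @param pos 1-based positions (bp).
#' @return Integer bin indices (per chromosome, 1-based).
#' @export
binIndex <- function(layout, chrom, pos) {
  bad <- !(chrom %in% chromNames(layout))
  if (any(bad)) stop("unknown chromosome(s): ", paste(unique(chrom[bad]), collapse = ", "))
  oob <- pos < 1 | pos > chromLengths(layout)[chrom]
  if (any(oob)) stop("position(s) outside chromosome bounds at record ",
                     paste(which(oob), collapse = ", "))
  as.integer((pos - 1) %/% layout@binSize) + 1L
}

#' Pericentromeric and arm bins of a chromosome
#'
#' A bin belongs to the pericentromere when its midpoint lies inside the
#' pericentromeric interval; all other bins are arm bins.
#'
#' @param layout A GenomeLayout.
#' @param chrom Chromosome name.
#' @return Integer vector of bin indices.
#' @export
periBins <- function(layout, chrom) {
  n <- nBins(layout)[chrom]
  starts <- (seq_len(n) - 1) * layout@binSize + 1
  ends <- pmin(starts + layout@binSize - 1, chromLengths(layout)[chrom])
  mid <- (starts + ends) / 2
  pc <- layout@pericentromere[chrom, ]
  which(mid >= pc[1] & mid <= pc[2])
}

#' @rdname periBins
#' @export
armBins <- function(layout, chrom) {
  setdiff(seq_len(nBins(layout)[chrom]), periBins(layout, chrom))
}

## ---------------------------------------------------------------------------
## ContactMatrix
## ---------------------------------------------------------------------------

#' ContactMatrix: per-chromosome symmetric binned contact counts
#'
#' Intra-chromosomal contact matrices at a stated bin size with assay and
#' condition metadata. `totalPairs` is the total valid-pair count the
#' matrices were built from (including any inter-chromosomal pairs dropped
#' during binning). After balancing, masked bins are `NA`.
#'
#' @slot matrices Named list of symmetric numeric matrices, one per chromosome.
#' @slot layout The [GenomeLayout-class] the matrices are binned on.
#' @slot assay One of `"HiC"`, `"CHiC"`, `"HiChIP"`.
#' @slot condition Condition/time label, e.g. `"0h"`, `"1h"`, `"6h"`.
#' @slot balanced Logical; `TRUE` after iterative correction.
#' @slot totalPairs Total valid-pair count.
#' @export
setClass("ContactMatrix",
  representation(
    matrices = "list",
    layout = "GenomeLayout",
    assay = "character",
    condition = "character",
    balanced = "logical",
    totalPairs = "numeric"
  )
)

setValidity("ContactMatrix", function(object) {
  msgs <- character()
  nb <- nBins(object@layout)
  if (!identical(names(object@matrices), chromNames(object@layout)))
    msgs <- c(msgs, "matrix names must match layout chromosomes")
  for (chr in names(object@matrices)) {
    m <- object@matrices[[chr]]
    if (!is.matrix(m) || nrow(m) != nb[chr] || ncol(m) != nb[chr]) {
      msgs <- c(msgs, sprintf("matrix '%s' must be %d x %d", chr, nb[chr], nb[chr]))
      next
    }
    if (any(m < 0, na.rm = TRUE))
      msgs <- c(msgs, sprintf("matrix '%s' has negative entries", chr))
    d <- abs(m - t(m))
    if (any(d > 1e-8 * (1 + abs(m)), na.rm = TRUE))
      msgs <- c(msgs, sprintf("matrix '%s' is not symmetric", chr))
  }
  if (!object@assay %in% c("HiC", "CHiC", "HiChIP"))
    msgs <- c(msgs, "assay must be HiC, CHiC or HiChIP")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ContactMatrix
#'
#' @param matrices Named list of symmetric per-chromosome matrices.
#' @param layout A [GenomeLayout-class].
#' @param assay Assay type (`"HiC"`, `"CHiC"`, `"HiChIP"`).
#' @param condition Condition label.
#' @param balanced Whether the matrices are balanced.
#' @param totalPairs Total valid-pair count; defaults to the sum of the
#'   (unordered) matrix entries.
#' @return A [ContactMatrix-class].
#' @export
ContactMatrix <- function(matrices, layout, assay = "HiC", condition = "0h",
                          balanced = FALSE, totalPairs = NULL) {
  matrices <- matrices[chromNames(layout)]
  if (is.null(totalPairs)) {
    totalPairs <- sum(vapply(matrices, function(m) {
      (sum(m, na.rm = TRUE) + sum(diag(m), na.rm = TRUE)) / 2
    }, numeric(1)))
  }
  new("ContactMatrix", matrices = matrices, layout = layout, assay = assay,
      condition = condition, balanced = balanced, totalPairs = totalPairs)
}

#' @rdname ContactMatrix
#' @param x A ContactMatrix.
#' @param chrom Chromosome name.
#' @export
cmMatrix <- function(x, chrom) x@matrices[[chrom]]

#' @rdname ContactMatrix
#' @export
genomeLayout <- function(x) x@layout

#' @rdname ContactMatrix
#' @export
setMethod("binSize", "ContactMatrix", function(x) x@layout@binSize)

#' @rdname ContactMatrix
#' @export
setMethod("chromNames", "ContactMatrix", function(x) chromNames(x@layout))

#' @rdname ContactMatrix
#' @export
isBalanced <- function(x) x@balanced

#' @rdname ContactMatrix
#' @export
totalPairs <- function(x) x@totalPairs

#' @rdname ContactMatrix
#' @export
condition <- function(x) x@condition

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf("ContactMatrix [%s, %s]: %d chromosome(s), bin %d bp, %s pairs%s\n",
              object@assay, object@condition, length(object@matrices),
              binSize(object), format(round(object@totalPairs), big.mark = ","),
              if (object@balanced) ", balanced" else ""))
})

## ---------------------------------------------------------------------------
## SignalTrack
## ---------------------------------------------------------------------------

#' SignalTrack: a binned genome-wide signal
#'
#' One non-negative value per genomic bin at its own resolution (independent
#' of any contact-matrix binning); `NA` marks unmappable bins.
#'
#' @slot name Track name (e.g. `"H3K9ac"`, `"ATAC"`).
#' @slot values Named list of per-chromosome numeric vectors.
#' @slot layout The [GenomeLayout-class] giving chromosome lengths.
#' @slot binSize Track bin size in bp.
#' @slot condition Condition label (`"all"` for condition-invariant tracks).
#' @export
setClass("SignalTrack",
  representation(
    name = "character",
    values = "list",
    layout = "GenomeLayout",
    binSize = "integer",
    condition = "character"
  )
)

setValidity("SignalTrack", function(object) {
  msgs <- character()
  nb <- ceiling(chromLengths(object@layout) / object@binSize)
  if (!identical(names(object@values), chromNames(object@layout)))
    msgs <- c(msgs, "value names must match layout chromosomes")
  for (chr in names(object@values)) {
    v <- object@values[[chr]]
    if (length(v) != nb[chr])
      msgs <- c(msgs, sprintf("'%s': expected %d values, got %d", chr, nb[chr], length(v)))
    if (any(v < 0, na.rm = TRUE))
      msgs <- c(msgs, sprintf("'%s': negative signal values", chr))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SignalTrack
#'
#' @param name Track name.
#' @param values Named list of per-chromosome numeric vectors.
#' @param layout A [GenomeLayout-class].
#' @param binSize Track bin size (bp).
#' @param condition Condition label.
#' @return A [SignalTrack-class].
#' @export
SignalTrack <- function(name, values, layout, binSize, condition = "all") {
  new("SignalTrack", name = name, values = values[chromNames(layout)],
      layout = layout, binSize = as.integer(binSize), condition = condition)
}

#' @rdname SignalTrack
#' @param x A SignalTrack.
#' @export
setMethod("binSize", "SignalTrack", function(x) x@binSize)

#' @rdname SignalTrack
#' @param chrom Chromosome name.
#' @export
trackValues <- function(x, chrom) x@values[[chrom]]

setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack '%s' [%s]: bin %d bp, %d chromosome(s)\n",
              object@name, object@condition, object@binSize,
              length(object@values)))
})

## ---------------------------------------------------------------------------
## CompartmentProfile
## ---------------------------------------------------------------------------

#' CompartmentProfile: per-bin PC1 values and A/B labels
#'
#' Leading-eigenvector loadings of the centered contact correlation map, one
#' per bin, oriented so that A (PC1 > 0) has the higher mean activity-track
#' signal; labels are `"A"`, `"B"` or `"masked"`.
#'
#' @slot pc1 Named list of per-chromosome numeric PC1 vectors (NA = masked).
#' @slot labels Named list of per-chromosome character labels.
#' @slot orientation Name of the activity track that fixed the sign.
#' @slot binSize Bin size (bp) of the underlying matrix.
#' @export
setClass("CompartmentProfile",
  representation(
    pc1 = "list",
    labels = "list",
    orientation = "character",
    binSize = "integer"
  )
)

setValidity("CompartmentProfile", function(object) {
  for (chr in names(object@pc1)) {
    p <- object@pc1[[chr]]; l <- object@labels[[chr]]
    if (length(p) != length(l)) return(sprintf("'%s': pc1/label length mismatch", chr))
    if (!all(l %in% c("A", "B", "masked"))) return("labels must be A, B or masked")
    if (any(l == "A" & !(p > 0), na.rm = TRUE)) return("label A requires PC1 > 0")
  }
  TRUE
})

#' @rdname CompartmentProfile-class
#' @param x A CompartmentProfile.
#' @param chrom Chromosome name.
#' @export
pc1Values <- function(x, chrom) x@pc1[[chrom]]

#' @rdname CompartmentProfile-class
#' @export
compartmentLabels <- function(x, chrom) x@labels[[chrom]]

setMethod("show", "CompartmentProfile", function(object) {
  nA <- sum(unlist(object@labels) == "A")
  nB <- sum(unlist(object@labels) == "B")
  nM <- sum(unlist(object@labels) == "masked")
  cat(sprintf("CompartmentProfile: %d A / %d B / %d masked bins (oriented by %s)\n",
              nA, nB, nM, object@orientation))
})
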