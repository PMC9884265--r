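#' Read a genome layout from a YAML config
#'
#' The config lists chromosome names and lengths, pericentromeric intervals
#' (1-based closed, bp) and the bin size:
#' \preformatted{
#' bin_size: 20000
#' chromosomes:
#'   - name: chr1
#'     length: 5000000
#'     pericentromere: [2000001, 3000000]
#' }
#' Bin indexing is deterministic in file order.
#'
#' @param path Path to the YAML file.
#' @return A validated [GenomeLayout-class].
#' @export
readLayout <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$bin_size) || is.null(cfg$chromosomes))
    stop("layout config must contain 'bin_size' and 'chromosomes'")
  lens <- setNames(
    vapply(cfg$chromosomes, function(x) as.numeric(x$length), numeric(1)),
    vapply(cfg$chromosomes, function(x) as.character(x$name), character(1)))
  peri <- lapply(cfg$chromosomes, function(x) as.numeric(x$pericentromere))
  names(peri) <- names(lens)
  GenomeLayout(lens, peri, cfg$bin_size)
}

#' Write a genome layout to YAML
#'
#' @param layout A [GenomeLayout-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLayout <- function(layout, path) {
  cfg <- list(
    bin_size = binSize(layout),
    chromosomes = lapply(chromNames(layout), function(chr) {
      list(name = chr, length = unname(chromLengths(layout)[chr]),
           pericentromere = as.numeric(layout@pericentromere[chr, ]))
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read / write valid-pairs text
#'
#' Four tab-separated columns `chromA posA chromB posB` (1-based bp), one
#' ligation pair per line, with a header. Pair order within a record is not
#' meaningful: (A,B) and (B,A) denote the same unordered pair.
#'
#' @param path File path.
#' @return `readPairs`: a data.frame with columns `chromA`, `posA`,
#'   `chromB`, `posB`.
#' @export
readPairs <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(identical(colnames(df), c("chromA", "posA", "chromB", "posB")))
  df
}

#' @rdname readPairs
#' @param pairs A valid-pairs data.frame.
#' @export
writePairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a contact matrix as sparse upper-triangle text
#'
#' The interchange format is a tab-separated table
#' `chrom bin_i bin_j count` keeping `bin_i <= bin_j` (1-based bin indices),
#' with a sidecar bin table `chrom start end bin` written next to it
#' (`<file>.bins.tsv`). Counts survive a round trip to 6 significant digits;
#' integer counts exactly.
#'
#' @param cm A [ContactMatrix-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeContactMatrix <- function(cm, file) {
  rows <- lapply(chromNames(cm), function(chr) {
    m <- cmMatrix(cm, chr)
    idx <- which(upper.tri(m, diag = TRUE) & !is.na(m) & m != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    data.frame(chrom = chr, bin_i = idx[, 1], bin_j = idx[, 2],
               count = signif(m[idx], 7))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(), bin_i = integer(),
                                    bin_j = integer(), count = numeric())
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  br <- binRanges(genomeLayout(cm))
  bins <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(br)),
                     start = BiocGenerics::start(br), end = BiocGenerics::end(br),
                     bin = br$bin)
  write.table(bins, paste0(file, ".bins.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname writeContactMatrix
#' @param layout The [GenomeLayout-class] the matrix is binned on.
#' @param assay,condition,balanced,totalPairs Metadata for the returned object.
#' @export
readContactMatrix <- function(file, layout, assay = "HiC", condition = "0h",
                              balanced = FALSE, totalPairs = NULL) {
  df <- read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  nb <- nBins(layout)
  mats <- lapply(chromNames(layout), function(chr) {
    m <- matrix(0, nb[chr], nb[chr])
    sub <- df[df$chrom == chr, , drop = FALSE]
    if (nrow(sub)) {
      m[cbind(sub$bin_i, sub$bin_j)] <- sub$count
      m[cbind(sub$bin_j, sub$bin_i)] <- sub$count
    }
    m
  })
  names(mats) <- chromNames(layout)
  ContactMatrix(mats, layout, assay = assay, condition = condition,
                balanced = balanced, totalPairs = totalPairs)
}

#' Read a dense contact matrix from TSV
#'
#' A plain numeric table (no header, no row names), one row per bin.
#'
#' @param file Path to a dense TSV matrix.
#' @return A symmetric numeric matrix.
#' @export
readDenseMatrix <- function(file) {
  m <- as.matrix(read.table(file, header = FALSE, sep = "\t"))
  dimnames(m) <- NULL
  m
}

#' Read gene annotation from 6-column BED
#'
#' BED columns: chrom, start, end, name (gene id), score, strand. GFF-style
#' 1-based input can be converted upstream; BED half-open coordinates are
#' converted to the 1-based closed GRanges convention on read.
#'
#' @param path BED file path.
#' @param layout Optional [GenomeLayout-class] used to set sequence lengths.
#' @return A [GenomicRanges::GRanges] with a `gene_id` metadata column.
#' @export
readGenesBed <- function(path, layout = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  gr$gene_id <- gr$name
  gr$name <- NULL
  gr$score <- NULL
  if (anyDuplicated(gr$gene_id)) stop("gene_id values must be unique")
  if (!is.null(layout))
    GenomeInfoDb::seqlengths(gr) <- chromLengths(layout)[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' @rdname readGenesBed
#' @param genes A gene GRanges with `gene_id`.
#' @export
writeGenesBed <- function(genes, path) {
  out <- genes
  out$name <- out$gene_id
  out$gene_id <- NULL
  out$score <- 0L
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Strand-aware transcription start sites and promoters
#'
#' The TSS of a `+` gene is its start, of a `-` gene its end. The promoter
#' extends `upstream` bp upstream of the TSS in strand direction (1.5 kb by
#' default, the width used for capture-bait design) and is clipped to the
#' chromosome bounds.
#'
#' @param genes Gene GRanges with strand.
#' @param upstream Promoter length in bp.
#' @return `geneTSS`: GRanges of width-1 TSS positions. `genePromoters`:
#'   promoter GRanges (clipped).
#' @export
geneTSS <- function(genes) {
  GenomicRanges::resize(genes, width = 1L, fix = "start")
}

#' @rdname geneTSS
#' @export
genePromoters <- function(genes, upstream = 1500L) {
  p <- GenomicRanges::promoters(genes, upstream = upstream, downstream = 0L)
  suppressWarnings(GenomicRanges::trim(p))
}

#' Read / write a binned signal track as bedGraph
#'
#' @param path bedGraph path.
#' @param layout A [GenomeLayout-class].
#' @param trackBinSize Bin size (bp) of the track.
#' @param name,condition Track metadata.
#' @return `readBedGraph`: a [SignalTrack-class].
#' @export
readBedGraph <- function(path, layout, trackBinSize, name = "signal",
                         condition = "all") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  nb <- ceiling(chromLengths(layout) / trackBinSize)
  vals <- lapply(chromNames(layout), function(chr) {
    v <- rep(NA_real_, nb[chr])
    sub <- gr[GenomeInfoDb::seqnames(gr) == chr]
    if (length(sub)) {
      idx <- as.integer((BiocGenerics::start(sub) - 1) %/% trackBinSize) + 1L
      v[idx] <- sub$score
    }
    v
  })
  names(vals) <- chromNames(layout)
  SignalTrack(name, vals, layout, trackBinSize, condition)
}

#' @rdname readBedGraph
#' @param track A [SignalTrack-class].
#' @export
writeBedGraph <- function(track, path) {
  layout <- track@layout
  rows <- lapply(chromNames(layout), function(chr) {
    v <- trackValues(track, chr)
    keep <- !is.na(v)
    if (!any(keep)) return(NULL)
    starts <- (which(keep) - 1) * track@binSize + 1
    ends <- pmin(starts + track@binSize - 1, chromLengths(layout)[chr])
    GenomicRanges::GRanges(factor(rep(chr, sum(keep)), levels = chromNames(layout)),
                           IRanges::IRanges(starts, ends),
                           score = signif(v[keep], 7))
  })
  gr <- do.call(c, rows[!vapply(rows, is.null, logical(1))])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write peak sets with analysis columns
#'
#' A tab-separated table with header: `chrom start end` (1-based closed)
#' plus any metadata columns (`summit`, `class`, `signature`, per-time-point
#' accessibility scores, `cluster`, ...). This is the package's native peak
#' interchange format; plain BED peaks can be imported with
#' [rtracklayer::import()].
#'
#' @param path File path.
#' @param layout Optional [GenomeLayout-class] for sequence lengths.
#' @return `readPeaks`: a GRanges with all metadata columns.
#' @export
readPeaks <- function(path, layout = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  for (colname in setdiff(colnames(df), c("chrom", "start", "end")))
    S4Vectors::mcols(gr)[[colname]] <- df[[colname]]
  if (!is.null(layout))
    GenomeInfoDb::seqlengths(gr) <- chromLengths(layout)[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' @rdname readPeaks
#' @param peaks A peak GRanges.
#' @export
writePeaks <- function(peaks, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(peaks)),
                   start = BiocGenerics::start(peaks),
                   end = BiocGenerics::end(peaks))
  md <- as.data.frame(S4Vectors::mcols(peaks))
  if (ncol(md)) df <- cbind(df, md)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write interactions as BEDPE-like TSV
#'
#' Columns: chrom1 start1 end1 chrom2 start2 end2 plus all statistics columns
#' (`count`, `expected`, `p`, `padj`, ...).
#'
#' @param ints Interaction data.frame (see [callInteractions()]).
#' @param layout The [GenomeLayout-class] used for bin coordinates.
#' @param path Output path.
#' @export
writeInteractions <- function(ints, layout, path) {
  bs <- binSize(layout)
  lens <- chromLengths(layout)[ints$chrom]
  df <- data.frame(
    chrom1 = ints$chrom,
    start1 = (ints$bin1 - 1) * bs + 1,
    end1 = pmin(ints$bin1 * bs, lens),
    chrom2 = ints$chrom,
    start2 = (ints$bin2 - 1) * bs + 1,
    end2 = pmin(ints$bin2 * bs, lens))
  keep <- setdiff(colnames(ints), c("chrom", "bin1", "bin2"))
  df <- cbind(df, ints[, keep, drop = FALSE])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeInteractions
#' @export
readInteractions <- function(path, layout) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  bs <- binSize(layout)
  out <- data.frame(chrom = df$chrom1,
                    bin1 = as.integer((df$start1 - 1) %/% bs) + 1L,
                    bin2 = as.integer((df$start2 - 1) %/% bs) + 1L)
  keep <- setdiff(colnames(df), c("chrom1", "start1", "end1",
                                  "chrom2", "start2", "end2"))
  cbind(out, df[, keep, drop = FALSE])
}
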