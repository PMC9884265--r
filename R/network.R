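#' Associate TF binding peaks with target genes near the TSS
#'
#' Each peak is assigned to every gene whose `[TSS - windowBp, TSS +
#' windowBp]` window contains the peak summit (equidistant peaks go to all
#' such genes); peaks with no gene in range keep an empty target set.
#' Control (e.g. Halo-tag) peaks should be subtracted upstream by removing
#' peaks that overlap them (see `controlPeaks`).
#'
#' @param dapPeaks Peak GRanges with a `summit` metadata column (absolute
#'   bp position; defaults to the interval midpoint when absent).
#' @param genes Gene GRanges with strand and `gene_id`.
#' @param windowBp Half-window around the TSS in bp (default 1000).
#' @param controlPeaks Optional GRanges; dapPeaks overlapping any control
#'   peak are dropped before association.
#' @return A list with `targets` (named list: peak index -> character
#'   vector of gene ids) and `targetGenes` (unique gene ids hit).
#' @export
associateDapTargets <- function(dapPeaks, genes, windowBp = 1000L,
                                controlPeaks = NULL) {
  if (!is.null(controlPeaks) && length(controlPeaks))
    dapPeaks <- dapPeaks[!IRanges::overlapsAny(dapPeaks, controlPeaks)]
  summit <- dapPeaks$summit
  if (is.null(summit))
    summit <- (BiocGenerics::start(dapPeaks) + BiocGenerics::end(dapPeaks)) %/% 2
  sgr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(dapPeaks),
                                IRanges::IRanges(summit, summit))
  tss <- geneTSS(genes)
  win <- suppressWarnings(GenomicRanges::trim(
    GenomicRanges::resize(tss, width = 2L * windowBp + 1L, fix = "center")))
  hits <- GenomicRanges::findOverlaps(sgr, win, ignore.strand = TRUE)
  targets <- vector("list", length(dapPeaks))
  for (i in seq_along(targets)) targets[[i]] <- character(0)
  if (length(hits)) {
    sp <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (nm in names(sp)) targets[[as.integer(nm)]] <- unname(sp[[nm]])
  }
  list(targets = targets,
       targetGenes = unique(unlist(targets)))
}

#' Split target genes by regulation direction
#'
#' Counts and percentages (one decimal, rounded half away from zero) of
#' target genes called up- or down-regulated at the stated contrast. Target
#' genes absent from the DE table count as unchanged and are excluded from
#' the percentage denominator; with no up/down calls the percentages are
#' `NA`.
#'
#' @param targets Character vector of target gene ids.
#' @param de DE table data.frame with columns `gene` and `direction`
#'   (`"up"`, `"down"`, `"unchanged"`).
#' @return A list with `nUp`, `nDown`, `pctUp`, `pctDown`.
#' @export
targetRegulationSplit <- function(targets, de) {
  dir <- setNames(de$direction, de$gene)[targets]
  dir[is.na(dir)] <- "unchanged"
  nUp <- sum(dir == "up"); nDown <- sum(dir == "down")
  denom <- nUp + nDown
  if (denom == 0)
    return(list(nUp = nUp, nDown = nDown, pctUp = NA_real_, pctDown = NA_real_))
  list(nUp = nUp, nDown = nDown,
       pctUp = roundHalfUp(100 * nUp / denom, 1),
       pctDown = roundHalfUp(100 * nDown / denom, 1))
}

#' Build the time-resolved TF -> gene network
#'
#' A directed edge TF -> gene exists at time `t` iff (a) a motif hit for the
#' TF lies inside a peak overlapping the gene's promoter, (b) that peak is
#' accessible at `t` (accessibility score above `accThreshold`), and (c)
#' the gene is differentially expressed at `t`. TF nodes carry their own DE
#' direction per time point. Output is independent of input record order.
#'
#' @param tfs data.frame with columns `name`, `family` and `motif` (IUPAC
#'   consensus; `NA` keeps the node without edges, with a warning).
#' @param peaks Peak GRanges with per-time accessibility columns
#'   `acc_<time>`.
#' @param de Named list of DE tables per time point (each with `gene`,
#'   `direction`).
#' @param genes Gene GRanges with `gene_id`.
#' @param genome Named [Biostrings::DNAStringSet] / character sequences.
#' @param times Time points (default: names of `de`).
#' @param accThreshold Accessibility threshold (default 1).
#' @param promoterBp Promoter width for peak-gene pairing (default 1500).
#' @param motifThresholdP Per-position background probability used to set
#'   the motif score threshold; network edges demand high-confidence
#'   matches, so this is stricter (1e-6) than the scanning default.
#' @return A list with `edges` (data.frame `tf`, `gene`, `time`, `peak`),
#'   `nodes` (data.frame `name`, `type`, `family`, per-time direction) and
#'   `times`.
#' @export
buildTFNetwork <- function(tfs, peaks, de, genes, genome, times = names(de),
                           accThreshold = 1, promoterBp = 1500L,
                           motifThresholdP = 1e-6) {
  prom <- genePromoters(genes, upstream = promoterBp)
  pk2gene <- GenomicRanges::findOverlaps(peaks, prom)
  md <- S4Vectors::mcols(peaks)
  seqs <- getPeakSeqs(peaks, genome)
  edges <- list()
  for (r in seq_len(nrow(tfs))) {
    tf <- tfs$name[r]
    if (is.na(tfs$motif[r]) || tfs$motif[r] == "") {
      warning("TF without motif: ", tf, " (node retained, no edges)")
      next
    }
    motif <- consensusPWM(tfs$motif[r], name = tf, thresholdP = motifThresholdP)
    pkHit <- which(vapply(seqs, function(s) nrow(pwmScan(s, motif)) > 0,
                          logical(1)))
    for (tt in times) {
      accessible <- md[[paste0("acc_", tt)]] > accThreshold
      deGenes <- de[[tt]]$gene[de[[tt]]$direction %in% c("up", "down")]
      cand <- intersect(pkHit, which(accessible))
      h <- pk2gene[S4Vectors::queryHits(pk2gene) %in% cand]
      gg <- genes$gene_id[S4Vectors::subjectHits(h)]
      pp <- S4Vectors::queryHits(h)
      keep <- gg %in% deGenes
      if (any(keep))
        edges[[length(edges) + 1L]] <- data.frame(
          tf = tf, gene = gg[keep], time = tt, peak = pp[keep])
    }
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(tf = character(0), gene = character(0),
               time = character(0), peak = integer(0))
  edges <- edges[order(edges$tf, edges$time, edges$gene, edges$peak), ]
  rownames(edges) <- NULL
  nodeNames <- c(tfs$name, setdiff(unique(edges$gene), tfs$name))
  nodes <- data.frame(
    name = nodeNames,
    type = c(rep("TF", nrow(tfs)),
             rep("gene", length(nodeNames) - nrow(tfs))),
    family = c(tfs$family, rep(NA_character_, length(nodeNames) - nrow(tfs))))
  for (tt in times) {
    dd <- setNames(de[[tt]]$direction, de[[tt]]$gene)[nodes$name]
    dd[is.na(dd)] <- "unchanged"
    nodes[[paste0("direction_", tt)]] <- unname(dd)
  }
  list(edges = edges, nodes = nodes, times = times)
}

#' Write a TF network as edge-list TSV and GraphML
#'
#' @param network Network list from [buildTFNetwork()].
#' @param prefix Output path prefix; writes `<prefix>.edges.tsv` and
#'   `<prefix>.graphml`.
#' @export
writeNetwork <- function(network, prefix) {
  write.table(network$edges, paste0(prefix, ".edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  con <- file(paste0(prefix, ".graphml"), "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="type" for="node" attr.name="type" attr.type="string"/>',
    '  <key id="time" for="edge" attr.name="time" attr.type="string"/>',
    '  <graph edgedefault="directed">'), con)
  for (i in seq_len(nrow(network$nodes)))
    writeLines(sprintf('    <node id="%s"><data key="type">%s</data></node>',
                       network$nodes$name[i], network$nodes$type[i]), con)
  for (i in seq_len(nrow(network$edges)))
    writeLines(sprintf('    <edge source="%s" target="%s"><data key="time">%s</data></edge>',
                       network$edges$tf[i], network$edges$gene[i],
                       network$edges$time[i]), con)
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(prefix)
}
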