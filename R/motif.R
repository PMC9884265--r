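IUPAC_PROB <- list(
  A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
  R = c(.5, 0, .5, 0), Y = c(0, .5, 0, .5), S = c(0, .5, .5, 0),
  W = c(.5, 0, 0, .5), K = c(0, 0, .5, .5), M = c(.5, .5, 0, 0),
  B = c(0, 1, 1, 1) / 3, D = c(1, 0, 1, 1) / 3, H = c(1, 1, 0, 1) / 3,
  V = c(1, 1, 1, 0) / 3, N = c(.25, .25, .25, .25))

#' Build a position weight matrix from an IUPAC consensus
#'
#' Each consensus letter becomes a probability column (IUPAC ambiguity
#' codes split the mass; `N` is the background), a pseudocount is mixed in,
#' and log2-odds scores against the background composition are derived.
#' The default score threshold is calibrated so that the per-position hit
#' probability on background sequence is at most `thresholdP` (computed
#' exactly by dynamic programming over the column score distributions).
#'
#' @param consensus IUPAC consensus string, e.g. the heat-shock-element
#'   consensus `"TCTAGAANNTTCT"`.
#' @param name Motif name.
#' @param pseudocount Pseudocount mixed into each column (default 0.01).
#' @param background Background base composition (A, C, G, T).
#' @param thresholdP Per-position background hit probability used to set
#'   the score threshold (default 1e-4).
#' @return A `MotifModel` list: `name`, `pwm` (4 x L probabilities),
#'   `logodds` (4 x L, log2), `background`, `threshold`, `maxScore`.
#' @export
consensusPWM <- function(consensus, name = consensus, pseudocount = 0.01,
                         background = c(A = .25, C = .25, G = .25, T = .25),
                         thresholdP = 1e-4) {
  stopifnot(pseudocount > 0, nchar(consensus) >= 4)
  letters <- strsplit(toupper(consensus), "")[[1]]
  if (!all(letters %in% names(IUPAC_PROB)))
    stop("invalid IUPAC letter(s) in consensus")
  pwm <- vapply(letters, function(ch) {
    p <- IUPAC_PROB[[ch]] + pseudocount
    p / sum(p)
  }, numeric(4))
  rownames(pwm) <- c("A", "C", "G", "T")
  lo <- log2(pwm / background)
  model <- list(name = name, pwm = pwm, logodds = lo,
                background = background, maxScore = sum(apply(lo, 2, max)))
  model$threshold <- pwmScoreThreshold(model, thresholdP)
  model
}

#' Exact score threshold for a background hit probability
#'
#' Dynamic-programming convolution of the per-column log-odds score
#' distributions under the background composition (scores discretized to a
#' 1e-3 grid); returns the smallest score `t` with
#' `P(score >= t) <= p` for a random background window.
#'
#' @param motif A `MotifModel`.
#' @param p Target per-position background hit probability.
#' @return The score threshold.
#' @export
pwmScoreThreshold <- function(motif, p = 1e-4) {
  res <- 1e-3
  L <- ncol(motif$logodds)
  dist <- c(`0` = 1)  # named by integer score units
  for (j in seq_len(L)) {
    sc <- round(motif$logodds[, j] / res)
    newDist <- list()
    for (b in 1:4) {
      shifted <- setNames(dist * motif$background[b],
                          as.character(as.numeric(names(dist)) + sc[b]))
      newDist[[b]] <- shifted
    }
    all <- unlist(newDist)
    dist <- tapply(all, names(all), sum)
  }
  scores <- as.numeric(names(dist))
  ord <- order(scores, decreasing = TRUE)
  cum <- cumsum(as.numeric(dist)[ord])
  ok <- which(cum <= p + 1e-12)
  if (length(ok) == 0L) return(motif$maxScore + res)
  ## small margin absorbs the per-column discretization of the DP grid
  min(scores[ord][ok]) * res - res * L
}

#' Read a motif from JASPAR-style PFM text or a consensus line
#'
#' Accepts either a JASPAR-style position frequency matrix (a `>` header
#' followed by four `A/C/G/T [ counts ]` rows) or a plain file whose first
#' non-empty line is an IUPAC consensus. Counts are converted to column
#' probabilities with the pseudocount; a packaged example is the
#' heat-shock-element consensus
#' (`system.file("extdata", "hse_motif.jaspar", package = "heatloop")`).
#'
#' @param path Motif file path.
#' @param pseudocount,background,thresholdP Passed to the model builder
#'   (see [consensusPWM()]).
#' @return A `MotifModel` list.
#' @export
readMotif <- function(path, pseudocount = 0.01,
                      background = c(A = .25, C = .25, G = .25, T = .25),
                      thresholdP = 1e-4) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  name <- if (startsWith(lines[1], ">")) sub("^>\\s*", "", lines[1]) else
    basename(path)
  body <- lines[!startsWith(lines, ">")]
  rowRe <- "^[ACGT]\\s*\\["
  if (all(grepl(rowRe, body[1:min(4, length(body))]))) {
    counts <- t(vapply(body[1:4], function(l) {
      nums <- regmatches(l, gregexpr("[0-9.]+", l))[[1]]
      as.numeric(nums)
    }, numeric(length(regmatches(body[1], gregexpr("[0-9.]+", body[1]))[[1]]))))
    rownames(counts) <- substr(body[1:4], 1, 1)
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    pwm <- apply(counts, 2, function(col) {
      p <- col / sum(col) + pseudocount
      p / sum(p)
    })
    rownames(pwm) <- c("A", "C", "G", "T")
    lo <- log2(pwm / background)
    model <- list(name = name, pwm = pwm, logodds = lo,
                  background = background,
                  maxScore = sum(apply(lo, 2, max)))
    model$threshold <- pwmScoreThreshold(model, thresholdP)
    model
  } else {
    consensusPWM(body[1], name = name, pseudocount = pseudocount,
                 background = background, thresholdP = thresholdP)
  }
}

.DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

.encodeSeq <- function(seq) {
  ch <- strsplit(toupper(as.character(seq)), "")[[1]]
  code <- .DNA_CODE[ch]
  code[is.na(code)] <- 5L
  unname(code)
}

## score every window start of an encoded sequence against a 5 x L matrix
## (row 5 = N = 0 contribution); returns numeric vector length n - L + 1
.scanScores <- function(code, lo5) {
  L <- ncol(lo5)
  n <- length(code)
  if (n < L) return(numeric(0))
  sc <- numeric(n - L + 1L)
  for (j in seq_len(L)) {
    sc <- sc + lo5[cbind(code[j:(n - L + j)], j)]
  }
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Log2-odds scores are computed at every window on the forward and
#' reverse-complement strand; `N` bases contribute the background score
#' (log-odds 0). Hits are windows scoring at or above the motif threshold.
#' Positions are 1-based starts on the forward strand for both strands.
#'
#' @param seq A character string or [Biostrings::DNAString] over A/C/G/T/N.
#' @param motif A `MotifModel` from [consensusPWM()].
#' @param threshold Score threshold (defaults to `motif$threshold`).
#' @return A data.frame with `position`, `strand`, `score`, sorted by
#'   position; empty when the sequence is shorter than the motif.
#' @export
pwmScan <- function(seq, motif, threshold = motif$threshold) {
  lo5 <- rbind(motif$logodds, N = 0)
  L <- ncol(lo5)
  code <- .encodeSeq(seq)
  n <- length(code)
  if (n < L)
    return(data.frame(position = integer(0), strand = character(0),
                      score = numeric(0)))
  fwd <- .scanScores(code, lo5)
  rcCode <- rev(c(4L, 3L, 2L, 1L, 5L)[code])
  rvs <- .scanScores(rcCode, lo5)
  hitsF <- which(fwd >= threshold)
  hitsR <- which(rvs >= threshold)
  out <- data.frame(
    position = c(hitsF, n - L + 2L - hitsR),
    strand = c(rep("+", length(hitsF)), rep("-", length(hitsR))),
    score = c(fwd[hitsF], rvs[hitsR]))
  out <- out[order(out$position, out$strand), ]
  rownames(out) <- NULL
  out
}

.seqLen <- function(s) if (is.character(s)) nchar(s) else length(s)

.seqSub <- function(s, from, to) {
  if (is.character(s)) substr(s, from, to)
  else as.character(Biostrings::subseq(s, from, to))
}

## fast any-hit test on both strands, avoiding the data.frame path
.anyHit <- function(seq, motif, threshold = motif$threshold) {
  lo5 <- rbind(motif$logodds, N = 0)
  code <- .encodeSeq(seq)
  if (length(code) < ncol(lo5)) return(FALSE)
  if (any(.scanScores(code, lo5) >= threshold)) return(TRUE)
  any(.scanScores(rev(c(4L, 3L, 2L, 1L, 5L)[code]), lo5) >= threshold)
}

#' Extract peak sequences from a genome
#'
#' @param peaks Peak GRanges.
#' @param genome Named list of per-chromosome sequences
#'   ([Biostrings::DNAString] objects or plain character strings).
#' @return Character vector of peak sequences.
#' @export
getPeakSeqs <- function(peaks, genome) {
  vapply(seq_along(peaks), function(i) {
    chr <- as.character(GenomeInfoDb::seqnames(peaks))[i]
    .seqSub(genome[[chr]], BiocGenerics::start(peaks)[i],
            BiocGenerics::end(peaks)[i])
  }, character(1))
}

#' Motif enrichment in a peak set by binomial test
#'
#' `m` peaks of `n` contain at least one motif hit; the background rate `q`
#' is the fraction of `bgDraws` seeded, length-matched random genomic
#' windows (excluding the peak regions themselves) with at least one hit.
#' The p-value is the upper binomial tail `P(X >= m)`, `X ~ Binomial(n, q)`;
#' fold is `(m/n) / q`.
#'
#' @param peaks Peak GRanges.
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param motif A `MotifModel`.
#' @param bgDraws Number of background windows (default 10000).
#' @param seed Integer seed for the background draw.
#' @return A list with `fold`, `p`, `m`, `n`, `q`, and `flag`
#'   (`"q_zero"` when no background window had a hit but peaks did, in
#'   which case `p` is reported as `1/bgDraws`).
#' @export
motifEnrichment <- function(peaks, genome, motif, bgDraws = 10000L, seed = 1L) {
  seqs <- getPeakSeqs(peaks, genome)
  hasHit <- vapply(seqs, function(s) .anyHit(s, motif), logical(1))
  m <- sum(hasHit); n <- length(peaks)
  widths <- BiocGenerics::width(peaks)
  chroms <- names(genome)
  chrLens <- vapply(chroms, function(ch) .seqLen(genome[[ch]]), numeric(1))
  set.seed(seed)
  bgHit <- logical(0)
  while (length(bgHit) < bgDraws) {
    nb <- 2L * (bgDraws - length(bgHit))
    w <- sample(widths, nb, replace = TRUE)
    chr <- sample(chroms, nb, replace = TRUE, prob = chrLens)
    st <- floor(runif(nb) * (chrLens[chr] - w)) + 1
    wins <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, st + w - 1))
    ok <- which(!IRanges::overlapsAny(wins, peaks, ignore.strand = TRUE))
    ok <- head(ok, bgDraws - length(bgHit))
    if (!length(ok)) next
    hits <- vapply(ok, function(i)
      .anyHit(.seqSub(genome[[chr[i]]], st[i], st[i] + w[i] - 1), motif),
      logical(1))
    bgHit <- c(bgHit, hits)
  }
  q <- mean(bgHit)
  flag <- NULL
  if (q == 0 && m > 0) {
    p <- 1 / bgDraws
    flag <- "q_zero"
    fold <- Inf
  } else {
    p <- pbinom(m - 1, n, q, lower.tail = FALSE)
    fold <- (m / n) / q
  }
  list(fold = fold, p = p, m = m, n = n, q = q, flag = flag)
}
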