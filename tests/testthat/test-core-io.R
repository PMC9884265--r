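test_that("bin grid tiles chromosomes exactly, with a short last bin", {
  gl <- GenomeLayout(c(c1 = 1e6), list(c1 = c(4e5, 6e5)), 1e4)
  expect_equal(unname(nBins(gl)["c1"]), 100L)

  gl2 <- GenomeLayout(c(c1 = 1005000), list(c1 = c(4e5, 6e5)), 1e4)
  expect_equal(unname(nBins(gl2)["c1"]), 101L)
  br <- binRanges(gl2)
  expect_equal(BiocGenerics::width(br)[101], 5000L)

  ## bin index <-> coordinate mapping is a bijection over bin starts
  expect_equal(binIndex(gl, "c1", BiocGenerics::start(binRanges(gl))),
               seq_len(100))
})

test_that("invalid pericentromeres are rejected with the chromosome named", {
  expect_error(
    validObject(GenomeLayout(c(bad = 8e5), list(bad = c(2e5, 9e5)), 1e4)),
    "bad")
  expect_error(
    validObject(GenomeLayout(c(c1 = 8e5), list(c1 = c(6e5, 2e5)), 1e4)),
    "c1")
})

test_that("layout YAML round-trips", {
  gl <- GenomeLayout(c(chr1 = 5e6, chr2 = 4e6),
                     list(chr1 = c(2e6, 3e6), chr2 = c(1.5e6, 2.5e6)), 2e4)
  f <- tempfile(fileext = ".yaml")
  writeLayout(gl, f)
  gl2 <- readLayout(f)
  expect_equal(chromLengths(gl2), chromLengths(gl))
  expect_equal(gl2@pericentromere, gl@pericentromere)
  expect_equal(binSize(gl2), binSize(gl))
})

test_that("binPairs bins unordered pairs and conserves totals", {
  gl <- GenomeLayout(c(c1 = 100), list(c1 = c(40, 60)), 10)
  pairs <- data.frame(chromA = "c1", posA = c(5, 5, 25),
                      chromB = "c1", posB = c(15, 5, 5))
  cm <- binPairs(pairs, gl)
  m <- cmMatrix(cm, "c1")
  expect_equal(m[1, 2], 1); expect_equal(m[2, 1], 1)
  expect_equal(m[1, 1], 1)
  expect_equal(m[1, 3], 1); expect_equal(m[3, 1], 1)
  expect_identical(m, t(m))

  empty <- binPairs(pairs[0, ], gl)
  expect_true(all(cmMatrix(empty, "c1") == 0))

  set.seed(11)
  rnd <- data.frame(chromA = "c1", posA = sample(100, 1000, TRUE),
                    chromB = "c1", posB = sample(100, 1000, TRUE))
  cmr <- binPairs(rnd, gl)
  mr <- cmMatrix(cmr, "c1")
  expect_equal(sum(mr[upper.tri(mr)]) + sum(diag(mr)), 1000)
  expect_equal(totalPairs(cmr), 1000)

  bad <- data.frame(chromA = "cX", posA = 1, chromB = "c1", posB = 1)
  expect_error(binPairs(bad, gl), "record 1")
})

test_that("balancing equalizes row sums, masks empty bins and is stable", {
  gl <- GenomeLayout(c(c1 = 40), list(c1 = c(15, 25)), 10)
  ## already doubly stochastic: fixed point
  ds <- matrix(c(.5, .3, .2, .3, .4, .3, .2, .3, .5), 3, 3)
  gl3 <- GenomeLayout(c(c1 = 30), list(c1 = c(12, 18)), 10)
  cm <- ContactMatrix(list(c1 = ds), gl3)
  bal <- balanceMatrix(cm)
  scaled <- cmMatrix(bal, "c1") / cmMatrix(bal, "c1")[1, 1] * ds[1, 1]
  expect_equal(scaled, ds, tolerance = 1e-2)

  ## diag-dominant with a zero row: the zero row is masked, others equalized;
  ## result agrees with an independent IPF oracle run to convergence
  m <- matrix(c(10, 2, 1, 0,
                2, 8, 2, 0,
                1, 2, 12, 0,
                0, 0, 0, 0), 4, 4)
  cm4 <- ContactMatrix(list(c1 = m), gl)
  bal4 <- balanceMatrix(cm4)
  b <- cmMatrix(bal4, "c1")
  expect_true(all(is.na(b[4, ])))
  rs <- rowSums(b[1:3, 1:3])
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-3)
  oracle <- bruteIPF(m[1:3, 1:3], 100)
  oracle <- oracle / mean(rowSums(oracle))
  expect_equal(b[1:3, 1:3], oracle, tolerance = 1e-3)

  ## global scale invariance
  bal7 <- balanceMatrix(ContactMatrix(list(c1 = 7 * m), gl))
  expect_equal(cmMatrix(bal7, "c1"), b, tolerance = 1e-6)

  ## idempotence
  balb <- balanceMatrix(bal4)
  expect_equal(cmMatrix(balb, "c1"), b, tolerance = 1e-3)
})

test_that("capture baits tile promoters with a right-aligned final probe", {
  genes <- tinyGenes()
  baits <- designCaptureBaits(genes[1], probeLen = 120L, step = 120L)
  ## 1500 bp promoter: 12 full tiles plus one right-aligned probe
  expect_equal(length(baits), 13L)
  expect_true(all(BiocGenerics::width(baits) == 120L))
  prom <- genePromoters(genes[1])
  expect_equal(min(BiocGenerics::start(baits)), BiocGenerics::start(prom))
  expect_equal(max(BiocGenerics::end(baits)), BiocGenerics::end(prom))
  ## every promoter base covered
  cov <- GenomicRanges::reduce(baits)
  expect_true(all(IRanges::overlapsAny(prom, cov, type = "within")))

  ## promoter of exactly one probe length -> a single probe
  b1 <- designCaptureBaits(genes[1], probeLen = 120L, promoterBp = 120L)
  expect_equal(length(b1), 1L)

  ## two genes sharing a promoter region -> deduplicated probes
  shared <- c(genes[1], genes[1])
  shared$gene_id <- c("g1", "g2")
  b2 <- designCaptureBaits(shared)
  expect_equal(length(b2), 13L)
})

test_that("summarizeTrack honors stat and the NA convention", {
  gl <- GenomeLayout(c(c1 = 100), list(c1 = c(40, 60)), 10)
  tr <- SignalTrack("x", list(c1 = c(1, 2, 3, NA, NA, 1, 1, 1, 1, 1)), gl, 10)
  r <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 30))
  expect_equal(summarizeTrack(tr, r, "mean"), 2)
  expect_equal(summarizeTrack(tr, r, "sum"), 6)
  expect_equal(summarizeTrack(tr, r, "max"), 3)
  ## fully inside NA bins -> NA; half in NA -> non-NA bins only
  expect_true(is.na(summarizeTrack(tr, GenomicRanges::GRanges("c1", IRanges::IRanges(31, 50)), "mean")))
  expect_equal(summarizeTrack(tr, GenomicRanges::GRanges("c1", IRanges::IRanges(21, 40)), "mean"), 3)
  ## empty region list -> empty vector
  expect_length(summarizeTrack(tr, r[0], "mean"), 0L)
  ## constant track -> the constant
  trc <- SignalTrack("c", list(c1 = rep(2, 10)), gl, 10)
  expect_equal(summarizeTrack(trc, r, "mean"), 2)
})

test_that("pairs, matrix, bedGraph, gene and peak formats round-trip", {
  ds <- generateDataset(tinyParams(genSequence = FALSE), seed = 42)
  dir <- tempfile(); dir.create(dir)

  pairs <- data.frame(chromA = "chr1", posA = c(10L, 500L),
                      chromB = c("chr1", "chr2"), posB = c(900L, 77L))
  f <- file.path(dir, "p.pairs")
  writePairs(pairs, f)
  expect_identical(readPairs(f), pairs)

  cm <- ds$contacts$HiC[["0h"]]
  f <- file.path(dir, "m.tsv")
  writeContactMatrix(cm, f)
  cm2 <- readContactMatrix(f, ds$layout, totalPairs = totalPairs(cm))
  for (chr in chromNames(cm))
    expect_equal(cmMatrix(cm2, chr), cmMatrix(cm, chr))

  tr <- ds$tracks$H3K9ac
  f <- file.path(dir, "t.bedgraph")
  writeBedGraph(tr, f)
  tr2 <- readBedGraph(f, ds$layout, binSize(tr), "H3K9ac")
  expect_equal(trackValues(tr2, "chr1"), trackValues(tr, "chr1"),
               tolerance = 1e-6)

  f <- file.path(dir, "genes.bed")
  writeGenesBed(ds$genes, f)
  g2 <- readGenesBed(f, ds$layout)
  expect_equal(BiocGenerics::start(g2), BiocGenerics::start(ds$genes))
  expect_equal(as.character(BiocGenerics::strand(g2)),
               as.character(BiocGenerics::strand(ds$genes)))
  expect_equal(g2$gene_id, ds$genes$gene_id)

  f <- file.path(dir, "peaks.tsv")
  writePeaks(ds$peaks, f)
  p2 <- readPeaks(f, ds$layout)
  expect_equal(BiocGenerics::start(p2), BiocGenerics::start(ds$peaks))
  expect_equal(p2$acc_1h, ds$peaks$acc_1h, tolerance = 1e-12)

  ints <- data.frame(chrom = "chr1", bin1 = c(3L, 10L), bin2 = c(20L, 44L),
                     count = c(5, 9), p = c(0.01, 0.2))
  f <- file.path(dir, "ints.tsv")
  writeInteractions(ints, ds$layout, f)
  i2 <- readInteractions(f, ds$layout)
  expect_equal(i2$bin1, ints$bin1)
  expect_equal(i2$bin2, ints$bin2)
  expect_equal(i2$count, ints$count)
})
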