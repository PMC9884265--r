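test_that("cumulative binomial p-values match the brute-force tail sum", {
  ## the survival-function path must agree with direct summation
  cases <- expand.grid(N = c(100, 500, 2000), p0 = c(0.002, 0.02, 0.1),
                       k = c(0, 1, 10, 40))
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]; p0 <- cases$p0[i]; k <- cases$k[i]
    got <- pbinom(k - 1, N, p0, lower.tail = FALSE)
    want <- bruteBinomTail(k, N, p0)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_equal(pbinom(-1, 100, 0.02, lower.tail = FALSE), 1)  # k = 0
})

test_that("interaction calling is deterministic and order invariant", {
  gl <- GenomeLayout(c(c1 = 4e5), list(c1 = c(1.8e5, 2.2e5)), 1e4)
  set.seed(21)
  pairs <- data.frame(chromA = "c1", posA = sample(4e5, 5000, TRUE),
                      chromB = "c1", posB = sample(4e5, 5000, TRUE))
  a <- callInteractions(binPairs(pairs, gl), 2, 20, keepAll = TRUE)
  b <- callInteractions(binPairs(pairs[sample(nrow(pairs)), ], gl), 2, 20,
                        keepAll = TRUE)
  expect_equal(a, b)
  ## p-values reproduce the caller's own binomial tail at its p0
  N <- totalPairs(binPairs(pairs, gl))
  idx <- which(a$count > 0)[1:20]
  for (i in idx)
    expect_equal(a$p[i], bruteBinomTail(a$count[i], round(N), a$p0[i]),
                 tolerance = 1e-9)
})

test_that("anchor annotation applies the self-loop/duplicate/gene filters", {
  gl <- GenomeLayout(c(chr1 = 5e4), list(chr1 = c(2e4, 3e4)), 5e3)
  genes <- tinyGenes()   # gA at 5-7 kb (+), gB at 20-22 kb (-)
  re <- GenomicRanges::GRanges("chr1", IRanges::IRanges(40100, 40400))
  ints <- data.frame(chrom = "chr1",
                     bin1 = c(2, 2, 9, 1, 7),
                     bin2 = c(2, 9, 2, 9, 9),
                     count = 1:5)
  ann <- annotateAnchors(ints, gl, genes, re)
  ## self-loop (2,2) dropped; (2,9)/(9,2) collapsed; (7,9) has no gene
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$count, c(2L, 4L))
  ## bin 1 holds gA's promoter; bin 2 only its gene body; bin 9 the RE peak
  expect_equal(ann$anchor1Class, c("other", "promoter"))
  expect_equal(ann$anchor2Class, c("RE", "RE"))
  ## requireBoth drops the pair whose second anchor is gene-free
  both <- annotateAnchors(ints, gl, genes, re, requireBoth = TRUE)
  expect_equal(nrow(both), 0L)
})

test_that("hub detection follows the bipartite definition", {
  mk <- function(b1, b2, c1, c2) data.frame(
    chrom = "chr1", bin1 = b1, bin2 = b2,
    anchor1Class = c1, anchor2Class = c2)
  ints <- rbind(mk(1, 5, "promoter", "RE"), mk(1, 9, "promoter", "RE"))
  h <- detectHubs(ints)
  expect_equal(names(h$promoterHubs), "chr1:1")
  expect_length(h$promoterHubs[["chr1:1"]], 2L)
  expect_length(h$reHubs, 0L)

  ints2 <- rbind(mk(3, 11, "RE", "promoter"), mk(3, 15, "RE", "promoter"),
                 mk(3, 19, "RE", "promoter"))
  h2 <- detectHubs(ints2)
  expect_equal(names(h2$reHubs), "chr1:3")
  expect_length(h2$reHubs[["chr1:3"]], 3L)

  h3 <- detectHubs(mk(1, 5, "promoter", "RE"))
  expect_length(h3$promoterHubs, 0L)
  expect_length(h3$reHubs, 0L)
})

test_that("Fisher differential test matches enumeration and swaps cleanly", {
  a <- data.frame(chrom = "c1", bin1 = 1L, bin2 = 10L, count = 20)
  b <- data.frame(chrom = "c1", bin1 = 1L, bin2 = 10L, count = 2)
  d <- differentialInteractions(a, b, 1e6, 1e6)
  expect_equal(d$p, bruteFisher2(20, 1e6, 2, 1e6), tolerance = 1e-10)
  expect_equal(d$direction, "gained")

  dswap <- differentialInteractions(b, a, 1e6, 1e6)
  expect_equal(dswap$p, d$p, tolerance = 1e-12)
  expect_equal(dswap$direction, "lost")

  ## identical margins: p = 1, no call
  same <- differentialInteractions(a, a, 1e6, 1e6)
  expect_equal(same$p, 1)
  expect_equal(same$direction, "ns")

  expect_error(differentialInteractions(a, b, 0, 1e6), "positive")
})

test_that("APA is flat on a constant matrix and guards its window", {
  gl <- GenomeLayout(c(c1 = 6e5), list(c1 = c(2.8e5, 3.2e5)), 1e4)
  cm <- ContactMatrix(list(c1 = matrix(5, 60, 60)), gl)
  loops <- data.frame(chrom = "c1", bin1 = c(10L, 3L), bin2 = c(40L, 10L))
  res <- apa(cm, loops, w = 5L)
  ## second loop too close to the edge / diagonal -> excluded and counted
  expect_equal(res$nLoops, 1L)
  expect_equal(res$nExcluded, 1L)
  expect_true(all(abs(res$matrix - 1) < 1e-12))
  expect_equal(res$score, 1)
  expect_error(apa(cm, loops[2, , drop = FALSE]), "no usable loops")
})

test_that("accessibility strata count anchor overlaps", {
  gl <- GenomeLayout(c(c1 = 3e5), list(c1 = c(1.4e5, 1.6e5)), 1e4)
  m <- matrix(3, 30, 30)
  cm <- ContactMatrix(list(c1 = m), gl)
  ints <- data.frame(chrom = "c1", bin1 = c(2L, 5L), bin2 = c(20L, 25L))
  peaks <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(12000, 192000),
                                                         c(12400, 192400)))
  st <- accessibilityStrata(ints, cm, peaks)
  expect_equal(st$interactions$category, c(2L, 0L))
  ## no peaks supplied -> all category 0
  st0 <- accessibilityStrata(ints, cm, NULL)
  expect_true(all(st0$interactions$category == 0L))
  expect_equal(st0$summary$n[st0$summary$category == 0], 2L)
})
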