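test_that("proximal/distal classification applies the strand-aware rule", {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(5000, 29000), c(6000, 30000)),
    strand = c("+", "+"), gene_id = c("g1", "g2"))
  GenomeInfoDb::seqlengths(genes) <- c(chr1 = 1e5)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(4200, 50000, 5500), c(4600, 50400, 5700)))
  pk <- classifyPeaks(peaks, genes)
  ## upstream window peak -> proximal, linked; far peak -> distal;
  ## gene-body peak -> genic-other
  expect_equal(pk$class, c("proximal", "distal", "genic-other"))
  expect_equal(pk$linkedGene[1], "g1")
  ## the classes partition the peak set
  expect_equal(sum(table(pk$class)), length(peaks))

  ## minus-strand gene: upstream is to the right of the TSS (= end)
  gm <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 6000),
                               strand = "-", gene_id = "gm")
  GenomeInfoDb::seqlengths(gm) <- c(chr1 = 1e5)
  pkm <- classifyPeaks(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(6200, 6500)), gm)
  expect_equal(pkm$class, "proximal")
})

test_that("enhancer signature is a monotone quantile rule on distal flanks", {
  gl <- GenomeLayout(c(c1 = 2e5), list(c1 = c(9e4, 1.1e5)), 100)
  n <- ceiling(2e5 / 100)
  ## 20 distal peaks at 5-kb spacing; 4 planted with the enhancer signature
  starts <- seq(10000, by = 5000, length.out = 20)
  peaks <- GenomicRanges::GRanges("c1", IRanges::IRanges(starts, starts + 299))
  peaks$class <- "distal"
  peaks$linkedGene <- NA_character_
  ## per-peak flank values: planted peaks high in both acetyl marks and
  ## devoid of H3K4me3; background spreads are anti-ordered between the two
  ## acetyl marks so no background peak is high in both
  mkTrack <- function(perPeak) {
    v <- rep(1e-3, n)
    for (i in seq_along(perPeak)) {
      b <- unique(((starts[i] - 500):(starts[i] + 799)) %/% 100 + 1)
      v[b] <- perPeak[i]
    }
    SignalTrack("m", list(c1 = v), gl, 100)
  }
  planted <- 1:4
  k9 <- c(rep(10, 4), seq(2, 0.5, length.out = 16))
  k18 <- c(rep(10, 4), seq(0.5, 2, length.out = 16))
  k4 <- c(rep(0.01, 4), rep(2, 16))
  marks <- list(H3K9ac = mkTrack(k9), H3K18ac = mkTrack(k18),
                H3K4me3 = mkTrack(k4))
  sig <- enhancerSignature(peaks, marks)
  expect_equal(which(sig$signature == "enhancer-like"), planted)

  ## monotone in H3K4me3: raising it at the planted peaks removes the label
  marksK4hi <- marks
  marksK4hi$H3K4me3 <- mkTrack(c(rep(10, 4), rep(2, 16)))
  sig2 <- enhancerSignature(peaks, marksK4hi)
  expect_length(which(sig2$signature == "enhancer-like"), 0L)

  ## proximal peaks are never labeled
  peaksP <- peaks
  peaksP$class <- "proximal"
  sigP <- enhancerSignature(peaksP, marks)
  expect_true(all(sigP$signature == "none"))

  expect_error(enhancerSignature(peaks, marks[c("H3K9ac", "H3K18ac")]),
               "H3K4me3")
})

test_that("planted enhancer signatures are recovered on the preset", {
  ds <- presetDataset(1)
  pk <- classifyPeaks(ds$peaks, ds$genes)
  pk <- enhancerSignature(pk, ds$tracks)
  lab <- which(pk$signature == "enhancer-like")
  expect_gte(sum(lab %in% ds$truth$enhancerPeaks), 27)
  expect_lte(sum(!(lab %in% ds$truth$enhancerPeaks)), 5)
})

test_that("k-means recovers planted archetypes and is seed reproducible", {
  ## degenerate: identical rows, one cluster, zero inertia
  x <- matrix(1:3, 3, 3, byrow = TRUE)
  km1 <- kmeansTimecourse(x, k = 1L, seed = 1)
  expect_equal(unname(km1$cluster), rep(1L, 3))
  expect_equal(km1$inertia, 0)
  expect_error(kmeansTimecourse(x, k = 5L, seed = 1), "exceeds")

  skip_if_not_installed("mclust")
  aris <- vapply(1:5, function(s) {
    tc <- generateTimecourseProfiles(seed = s)
    km <- kmeansTimecourse(tc$profiles, k = 5L, seed = s)
    mclust::adjustedRandIndex(km$cluster, tc$truth)
  }, numeric(1))
  expect_true(all(aris >= 0.9))

  ## permuting rows relabels but does not repartition
  tc <- generateTimecourseProfiles(seed = 3)
  km <- kmeansTimecourse(tc$profiles, k = 5L, seed = 3)
  perm <- sample(nrow(tc$profiles))
  kmP <- kmeansTimecourse(tc$profiles[perm, ], k = 5L, seed = 3)
  expect_equal(mclust::adjustedRandIndex(km$cluster[perm], kmP$cluster), 1)
})

test_that("batch SOM separates planted patterns with monotone error", {
  tc2 <- generateTimecourseProfiles(nPer = 30L, k = 2L, noiseSd = 0.15,
                                    seed = 2)
  fit <- somFit(tc2$profiles, grid = c(2L, 1L), seed = 2)
  expect_equal(somPurity(fit$unit, tc2$truth), 1)

  ## one repeated profile: single occupied unit, ~zero quantization error
  one <- matrix(rep(c(0, 1, 0), each = 10), 10)
  f1 <- somFit(one, grid = c(2L, 2L), seed = 1)
  expect_lt(tail(f1$qe, 1), 1e-8)
  expect_equal(length(unique(f1$unit)), 1L)

  for (s in 1:3) {
    tc <- generateTimecourseProfiles(seed = s)
    fit <- somFit(tc$profiles, grid = c(3L, 2L), seed = s)
    expect_true(all(diff(fit$qe) <= 1e-9))
    expect_gte(somPurity(fit$unit, tc$truth), 0.9)
  }
  expect_error(somFit(matrix(numeric(0), 0, 3), c(2, 2)), "empty")
})

test_that("accessibility-expression concordance uses Spearman ranks", {
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 600), c(400, 900)))
  peaks$class <- "proximal"
  peaks$linkedGene <- c("g1", "g2")
  peaks$acc_0h <- c(1, 1); peaks$acc_1h <- c(3, 3); peaks$acc_6h <- c(2, 2)
  ## g1 in phase with accessibility, g2 anti-phased; equal library sizes
  counts <- rbind(g1 = c(10, 10, 30, 30, 20, 20),
                  g2 = c(30, 30, 10, 10, 20, 20))
  samples <- data.frame(condition = rep(c("0h", "1h", "6h"), each = 2),
                        replicate = rep(1:2, 3))
  cc <- atacExpressionConcordance(peaks, list(counts = counts, samples = samples))
  expect_equal(cc$perPeak$rho, c(1, -1))   # in phase, anti-phased
})

test_that("proximal accessibility tracks linked-gene expression on the preset", {
  ds <- presetDataset(1)
  pk <- classifyPeaks(ds$peaks, ds$genes)
  cc <- atacExpressionConcordance(pk, ds$expr)
  expect_gte(cc$medianRho, 0.6)
  expect_gt(cc$fractionPositive, 0.75)
})
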