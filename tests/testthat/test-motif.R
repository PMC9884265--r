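test_that("scanning the consensus yields the maximal score at position 1", {
  motif <- consensusPWM("TCTAGAATTC")
  hits <- pwmScan("TCTAGAATTC", motif, threshold = motif$maxScore - 1e-9)
  expect_equal(hits$position, 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, motif$maxScore, tolerance = 1e-9)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("TCTAGAATTC")))
  hitsRC <- pwmScan(rc, motif, threshold = motif$maxScore - 1e-9)
  expect_equal(hitsRC$strand, "-")
  expect_equal(hitsRC$position, 1L)

  ## sequence shorter than the motif
  expect_equal(nrow(pwmScan("ACGT", motif)), 0L)
})

test_that("pwmScan agrees bit-exactly with exhaustive window scoring", {
  motif <- consensusPWM("TCTAGAANNTTCT")
  set.seed(8)
  for (rep in 1:3) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 2000,
                      replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    thr <- motif$maxScore * 0.3
    got <- pwmScan(s, motif, threshold = thr)
    want <- brutePwmScan(s, motif, thr)
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score)
  }
})

test_that("the stringent threshold keeps random-sequence hits rare", {
  motif <- consensusPWM("TCTAGAANNTTCT", thresholdP = 1e-4)
  set.seed(12)
  hits <- vapply(1:30, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    nrow(pwmScan(s, motif))
  }, numeric(1))
  expect_lte(mean(hits), 0.4)
})

test_that("enrichment p equals the binomial tail at the measured background", {
  ds <- presetDataset(1)
  motif <- consensusPWM(ds$params$hsfConsensus)
  idx <- ds$truth$distalArchIPeaks
  en <- motifEnrichment(ds$peaks[idx], ds$genome, motif, bgDraws = 3000L,
                        seed = 4)
  expect_gte(en$m, 50)
  expect_lt(en$p, 1e-20)
  expect_gt(en$fold, 10)
  ## closed-form tail vs brute-force summation at the measured q
  expect_equal(en$p, bruteBinomTail(en$m, en$n, en$q), tolerance = 1e-12)

  ## null behavior: peaks without the planted motif
  nullIdx <- setdiff(which(ds$truth$peakKind == "other"),
                     c(ds$truth$hsfPlantedPeaks, ds$truth$distalArchIPeaks))[1:40]
  en0 <- motifEnrichment(ds$peaks[nullIdx], ds$genome, motif, bgDraws = 3000L,
                         seed = 5)
  expect_gt(en0$p, 0.05)
  expect_lt(en0$fold, 3)
})

test_that("motif files load as scoring-ready models", {
  f <- system.file("extdata", "hse_motif.jaspar", package = "heatloop")
  expect_true(nzchar(f))
  m <- readMotif(f)
  expect_equal(dim(m$pwm), c(4L, 13L))
  expect_true(all(abs(colSums(m$pwm) - 1) < 1e-6))
  ## the PFM encodes the heat-shock-element consensus: scanning it hits
  hits <- pwmScan("TCTAGAAGGTTCT", m)
  expect_gte(nrow(hits), 1L)

  ## plain consensus files work too
  f2 <- tempfile()
  writeLines(c("> myMotif", "TTGACC"), f2)
  m2 <- readMotif(f2)
  expect_equal(ncol(m2$pwm), 6L)
})

test_that("DAP peak -> target association uses the TSS window and summit", {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(10000, 12000), c(11000, 13000)),
    strand = c("+", "+"), gene_id = c("g1", "g2"))
  GenomeInfoDb::seqlengths(genes) <- c(chr1 = 1e5)
  ## summit 11000 is 1000 bp from both TSSs (10000 and 12000)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(9600, 10900, 50000), c(9800, 11100, 50200)),
    summit = c(9700, 11000, 50100))
  res <- associateDapTargets(peaks, genes, windowBp = 1000L)
  expect_equal(res$targets[[1]], "g1")              # 300 bp upstream of g1 TSS
  expect_equal(sort(res$targets[[2]]), c("g1", "g2"))  # within both windows
  expect_length(res$targets[[3]], 0L)               # no gene in range
  ## control-peak subtraction removes overlapping peaks
  res2 <- associateDapTargets(peaks, genes, windowBp = 1000L,
                              controlPeaks = peaks[1])
  expect_length(res2$targets, 2L)
})

test_that("target regulation split reproduces the printed percentages", {
  de <- data.frame(gene = sprintf("t%03d", 1:247),
                   direction = c(rep("down", 186), rep("up", 61)))
  sp <- targetRegulationSplit(de$gene, de)
  expect_equal(sp$nDown, 186L)
  expect_equal(sp$nUp, 61L)
  expect_equal(sp$pctDown, 75.3)
  expect_equal(sp$pctUp, 24.7)
  expect_equal(sp$pctUp + sp$pctDown, 100, tolerance = 0.1)

  expect_true(is.na(targetRegulationSplit(
    "x", data.frame(gene = "x", direction = "unchanged"))$pctUp))

  even <- data.frame(gene = letters[1:20],
                     direction = rep(c("up", "down"), each = 10))
  spE <- targetRegulationSplit(even$gene, even)
  expect_equal(spE$pctUp, 50.0)
  expect_equal(spE$pctDown, 50.0)
})

test_that("TF network edges require motif + accessibility + DE jointly", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3000, 4000),
                                  strand = "+", gene_id = "G")
  GenomeInfoDb::seqlengths(genes) <- c(chr1 = 6000)
  set.seed(99)
  seqChars <- sample(c("A", "C", "G", "T"), 6000, TRUE)
  seqChars[2500:2511] <- strsplit("TTGACCGGTCAA", "")[[1]]
  genome <- list(chr1 = paste(seqChars, collapse = ""))
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2400, 2700))
  peaks$acc_1h <- 5; peaks$acc_6h <- 0.5
  de <- list(`1h` = data.frame(gene = "G", direction = "up"),
             `6h` = data.frame(gene = "G", direction = "unchanged"))
  tfs <- data.frame(name = "TF1", family = "WRKY", motif = "TTGACCGGTCAA")
  net <- buildTFNetwork(tfs, peaks, de, genes, genome)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$gene, "G")
  expect_equal(net$edges$time, "1h")

  ## peak accessible only when the gene is not DE -> no edge
  peaks2 <- peaks; peaks2$acc_1h <- 0.5; peaks2$acc_6h <- 5
  net2 <- buildTFNetwork(tfs, peaks2, de, genes, genome)
  expect_equal(nrow(net2$edges), 0L)

  ## TF without motif: node kept, warning, no edges
  tfs3 <- rbind(tfs, data.frame(name = "TF2", family = "X", motif = NA))
  expect_warning(net3 <- buildTFNetwork(tfs3, peaks, de, genes, genome),
                 "TF2")
  expect_true("TF2" %in% net3$nodes$name)
  expect_equal(nrow(net3$edges), 1L)
})

test_that("the planted two-wave TF cascade is recovered exactly", {
  ds <- presetDataset(1)
  pk <- classifyPeaks(ds$peaks, ds$genes)
  net <- buildTFNetwork(ds$tfs, pk, ds$de, ds$genes, ds$genome,
                        accThreshold = ds$truth$accThreshold)
  got <- unique(paste(net$edges$tf, net$edges$gene, net$edges$time))
  want <- c(paste("HSF-like", ds$truth$hsfTargets, "1h"),
            paste("WRKY-like", ds$truth$wrkyTargets, "6h"))
  expect_setequal(got, want)

  ## record order does not change the edge set
  netR <- buildTFNetwork(ds$tfs[2:1, ], pk, ds$de, ds$genes, ds$genome,
                         accThreshold = ds$truth$accThreshold)
  expect_setequal(unique(paste(netR$edges$tf, netR$edges$gene, netR$edges$time)),
                  want)
})
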