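test_that("expected-by-distance averages each diagonal", {
  m <- matrix(c(4, 2, 1, 2, 4, 2, 1, 2, 4), 3, 3)
  expect_equal(expectedByDistance(m), c(4, 2, 1))
  expect_equal(expectedByDistance(matrix(7, 5, 5)), rep(7, 5))
  expect_equal(expectedByDistance(diag(2)), c(1, 0))
})

test_that("O/E removes the decay trend and is scale invariant", {
  m <- matrix(c(4, 2, 1, 2, 4, 2, 1, 2, 4), 3, 3)
  expect_equal(oeTransform(m), matrix(1, 3, 3))

  set.seed(3)
  r <- matrix(rpois(100, 20), 10)
  r <- r + t(r)
  oe <- oeTransform(r)
  for (d in 0:9) {
    diagVals <- oe[col(oe) - row(oe) == d]
    expect_equal(mean(diagVals), 1, tolerance = 1e-9)
  }
  expect_equal(oeTransform(5 * r), oe, tolerance = 1e-12)

  ## masked row propagates
  rm <- r; rm[3, ] <- NA; rm[, 3] <- NA
  oem <- oeTransform(rm)
  expect_true(all(is.na(oem[3, ])))

  ## zero expected with observed contacts is inconsistent
  bad <- matrix(0, 3, 3); bad[1, 3] <- 5; bad[3, 1] <- 5
  expect_error(oeTransform(bad, expected = c(1, 1, 0)), "inconsistent")
})

test_that("correlation map matches direct Pearson computation", {
  oe <- matrix(c(1, 2, 3, 4,
                 1, 2, 3, 4,
                 4, 3, 2, 1,
                 4, 3, 2, 1), 4, 4, byrow = TRUE)
  C <- correlationMap(oe)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], -1)
  ## brute-force oracle on a two-block checkerboard O/E
  chk <- outer(c(1, 1, -1, -1), c(1, 1, -1, -1))
  oe2 <- 1 + 0.4 * chk
  C2 <- correlationMap(oe2)
  oracle <- matrix(NA_real_, 4, 4)
  for (i in 1:4) for (j in 1:4) oracle[i, j] <- cor(oe2[i, ], oe2[j, ])
  expect_equal(C2, oracle)
  expect_true(all(C2[1:2, 1:2] > 0) && all(C2[3:4, 3:4] > 0))
  expect_true(all(C2[1:2, 3:4] < 0))
})

test_that("PC1 separates checkerboard blocks and follows the activity sign", {
  comp <- rep(c(1, -1), each = 4)
  set.seed(5)
  oe <- 1 + 0.4 * outer(comp, comp) + matrix(rnorm(64, 0, 0.05), 8)
  oe <- (oe + t(oe)) / 2
  corr <- correlationMap(oe)
  act <- ifelse(comp == 1, 5, 1)
  prof <- compartmentPC1(list(c1 = corr), list(c1 = act))
  lab <- compartmentLabels(prof, "c1")
  expect_equal(lab, ifelse(comp == 1, "A", "B"))
  ## independent oracle: power iteration on the centered matrix
  Cc <- scale(corr, center = TRUE, scale = FALSE)
  S <- (Cc + t(Cc)) / 2
  v <- rep(1, 8)
  for (i in 1:500) { v <- S %*% v; v <- v / sqrt(sum(v^2)) }
  v <- as.numeric(v) * sign(mean(v[comp == 1]))
  got <- pc1Values(prof, "c1")
  got <- got / sqrt(sum(got^2))
  expect_equal(abs(got), abs(v), tolerance = 1e-6)

  ## flipping the activity flips all labels
  prof2 <- compartmentPC1(list(c1 = corr), list(c1 = -act))
  expect_equal(compartmentLabels(prof2, "c1"),
               ifelse(comp == 1, "B", "A"))

  ## constant correlation matrix: degenerate, all masked
  expect_warning(
    profC <- compartmentPC1(list(c1 = matrix(1, 6, 6)), list(c1 = rep(1, 6))),
    "degenerate|masked")
  expect_true(all(compartmentLabels(profC, "c1") == "masked"))
})

test_that("feature sorting permutes the matrix and masks NA bins", {
  m <- outer(1:4, 1:4)
  asc <- sortMatrixByFeature(m, c(1, 2, 3, 4))
  expect_equal(asc$permutation, 1:4)
  expect_equal(asc$matrix, m)
  rev <- sortMatrixByFeature(m, c(4, 3, 2, 1))
  expect_equal(rev$permutation, 4:1)
  expect_equal(rev$matrix, m[4:1, 4:1])

  ## checkerboard sorted by PC1 shows block-diagonal quadrants
  comp <- rep(c(1, -1), 4)
  oe <- 1 + 0.4 * outer(comp, comp)
  srt <- sortMatrixByFeature(oe, comp)
  q <- srt$matrix
  inQ <- mean(c(q[1:4, 1:4], q[5:8, 5:8]))
  outQ <- mean(c(q[1:4, 5:8], q[5:8, 1:4]))
  expect_gt(inQ, outQ)
  ## brute-force quadrant means
  expect_equal(inQ, 1.4)
  expect_equal(outQ, 0.6)

  wNA <- sortMatrixByFeature(m, c(2, NA, 1, 3))
  expect_equal(wNA$permutation, c(3, 1, 4, 2))
  expect_true(all(is.na(wNA$matrix[4, ])))
})

test_that("saddle of a flat O/E is flat and strength grows with amplitude", {
  oe1 <- matrix(1, 30, 30)
  prof <- seq(-1, 1, length.out = 30)
  s <- saddlePlot(oe1, prof, Q = 10L, corner = 2L)
  expect_true(all(abs(s@S - 1) < 1e-12, na.rm = TRUE))
  expect_equal(s@strength, 1)

  comp <- rep(c(1, -1), 20)
  strengths <- vapply(c(0.1, 0.2, 0.4), function(a) {
    oe <- 1 + a * outer(comp, comp)
    sa <- saddlePlot(oe, comp + seq_along(comp) * 1e-6, Q = 8L, corner = 2L)
    ## brute-force group-mean oracle for the AA corner
    g <- ceiling(rank(comp + seq_along(comp) * 1e-6, ties.method = "first") * 8 / 40)
    d <- abs(outer(seq_along(comp), seq_along(comp), "-"))
    pick <- outer(g >= 7, g >= 7) & d >= 2
    expect_equal(mean(sa@S[7:8, 7:8]), mean(oe[pick]), tolerance = 1e-12)
    sa@strength
  }, numeric(1))
  expect_true(all(diff(strengths) > 0))
})

test_that("scaling curves recover a planted decay and compare conditions", {
  ## noise-free s^-1 decay: fitted slope is -1
  n <- 120
  gl <- GenomeLayout(c(c1 = n * 1e4), list(c1 = c(5.5e5, 6.5e5)), 1e4)
  d <- abs(outer(1:n, 1:n, "-"))
  m <- pmax(d, 0.5)^-1 * 1e4
  cm <- ContactMatrix(list(c1 = m), gl)
  sc <- scalingCurve(cm, "arm")
  expect_equal(sc$slope, -1, tolerance = 0.05)

  ## identical matrices give identical curves
  sc2 <- scalingCurve(ContactMatrix(list(c1 = m), gl), "arm")
  expect_equal(sc$curve, sc2$curve)
})

test_that("difference maps are zero for equal or depth-scaled inputs", {
  ds <- generateDataset(tinyParams(genSequence = FALSE), seed = 5)
  a <- ds$contacts$HiC[["0h"]]
  d0 <- differenceMap(a, a)
  expect_true(all(abs(unlist(d0)) < 1e-9))
  b <- ContactMatrix(setNames(lapply(chromNames(a), function(ch) 2 * cmMatrix(a, ch)),
                              chromNames(a)),
                     ds$layout, totalPairs = 2 * totalPairs(a))
  d2 <- differenceMap(b, a)
  expect_true(all(abs(unlist(d2)) < 1e-9))
  gl2 <- GenomeLayout(chromLengths(ds$layout), list(
    chr1 = c(8e5, 1.2e6), chr2 = c(8e5, 1.2e6)), 1e4)
  expect_error(differenceMap(a, ContactMatrix(
    lapply(nBins(gl2), function(n) matrix(0, n, n)), gl2)), "binning")
})
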