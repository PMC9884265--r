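test_that("relative interaction frequency follows 2^-dCt with scaling", {
  mk <- function(gt, cond, bio, tech, ctT, ctN)
    data.frame(genotype = gt, condition = cond, loop = "A",
               bioRep = bio, techRep = tech, Ct_target = ctT, Ct_norm = ctN)
  t1 <- mk("WT", "0h", 1, 1, 25, 20)
  expect_equal(2^-(25 - 20), 0.03125)
  tab <- rbind(mk("WT", "0h", 1, 1, 25, 20), mk("WT", "0h", 2, 1, 25, 20),
               mk("WT", "1h", 1, 1, 25, 20), mk("WT", "1h", 2, 1, 25, 20))
  rif <- relativeInteractionFrequency(tab)
  ## identical reactions across conditions: all scaled means are 1
  expect_true(all(abs(rif$mean - 1) < 1e-12))

  ## template-amount invariance: adding a constant to both Cts changes nothing
  tab2 <- tab
  tab2$Ct_target <- tab2$Ct_target + 3
  tab2$Ct_norm <- tab2$Ct_norm + 3
  expect_equal(relativeInteractionFrequency(tab2)$mean, rif$mean)

  ## missing normalization Ct drops the reaction with a warning
  tab3 <- rbind(tab, mk("WT", "1h", 3, 1, 25, NA))
  expect_warning(r3 <- relativeInteractionFrequency(tab3), "dropped")
  expect_equal(r3$n[r3$condition == "1h"], 2L)

  ## hierarchical (technical then biological) equals flat averaging when
  ## the design is balanced: compare the scaled 1h mean to the flat ratio
  set.seed(2)
  tabB <- do.call(rbind, lapply(c("0h", "1h"), function(cond)
    do.call(rbind, lapply(1:3, function(b) do.call(rbind, lapply(1:3,
      function(tc) mk("WT", cond, b, tc, 25 + rnorm(1, 0, 0.2) -
                        (cond == "1h"), 20)))))))
  rifB <- relativeInteractionFrequency(tabB)
  raw <- 2^-(tabB$Ct_target - tabB$Ct_norm)
  flatRatio <- mean(raw[tabB$condition == "1h"]) / mean(raw[tabB$condition == "0h"])
  expect_equal(rifB$mean[rifB$condition == "1h"], flatRatio, tolerance = 1e-9)
})

test_that("planted qPCR fold changes are recovered from Ct noise", {
  folds <- vapply(1:3, function(s) {
    ds <- generateDataset(tinyParams(), seed = s)
    rif <- relativeInteractionFrequency(ds$qpcr)
    rif$mean[rif$genotype == "WT" & rif$condition == "1h" & rif$loop == "A"]
  }, numeric(1))
  expect_true(all(abs(folds - 2.5) <= 0.3))
})

test_that("luciferase normalization anchors the control at 1", {
  tab <- data.frame(
    construct = rep(c("mini35S", "RE"), each = 3),
    replicate = rep(1:3, 2),
    REN = rep(1, 6),
    LUC = c(1, 1, 1, 2.0, 2.2, 1.8))
  out <- luciferaseActivity(tab)
  expect_equal(out$mean[out$construct == "mini35S"], 1)
  expect_equal(out$mean[out$construct == "RE"], 2.0)

  ## doubling every REN value leaves normalized output unchanged
  tab2 <- tab; tab2$REN <- tab2$REN * 2
  expect_equal(luciferaseActivity(tab2)$mean, out$mean)

  expect_error(luciferaseActivity(tab[tab$construct == "RE", ]), "control")
})

test_that("pooled t-test matches the density-integration oracle", {
  same <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  tt <- twoSampleT(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_lt(abs(tt$p - 0.0214), 1e-3)   # printed to three figures
  expect_equal(tt$p, bruteTPvalue(tt$t, tt$df), tolerance = 1e-4)

  sw <- twoSampleT(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$t, -tt$t)
  expect_equal(sw$p, tt$p)

  zv <- twoSampleT(c(1, 1), c(2, 2))
  expect_equal(zv$flag, "zero_variance")
  expect_lte(zv$p, .Machine$double.xmin)

  ## agrees with the standard equal-variance implementation
  ht <- t.test(c(1, 2, 3, 5), c(2, 2, 7), var.equal = TRUE)
  ours <- twoSampleT(c(1, 2, 3, 5), c(2, 2, 7))
  expect_equal(ours$t, unname(ht$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ht$p.value, tolerance = 1e-12)
})

test_that("knock-down lines separate from WT at 1h", {
  ds <- generateDataset(tinyParams(), seed = 4)
  bio <- attr(relativeInteractionFrequency(ds$qpcr), "perBio")
  a <- bio$rif[bio$genotype == "WT" & bio$condition == "1h" & bio$loop == "A"]
  b <- bio$rif[bio$genotype == "hsfa1a-1" & bio$condition == "1h" & bio$loop == "A"]
  expect_lt(twoSampleT(a, b)$p, 0.01)
})
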