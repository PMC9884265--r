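## Orchestration: simulate -> compartments -> scaling -> RE classification ->
## interaction calling -> hubs/APA/strata -> TF network -> assays, with a
## machine-readable report. Stage failures stop their dependents only.

.stageHash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full synthetic-analysis pipeline
#'
#' Executes every stage in dependency order on a generated dataset:
#' simulation, compartment calling and saddle/scaling analysis per
#' condition, regulatory-element classification with the enhancer
#' signature, interaction calling with differential analysis, hubs, APA
#' and accessibility strata, k-means/SOM time-course clustering, the TF
#' network, and the 3C-qPCR / luciferase quantifications. A stage failure
#' is recorded and stops dependent stages while independent branches
#' complete. With `resume = TRUE` and an `outDir` holding a previous run,
#' stages whose inputs (parameters and upstream results, content-hashed)
#' are unchanged are reloaded instead of recomputed.
#'
#' @param config Named list of parameter overrides for
#'   [syntheticParams()], or `NULL` for the defaults.
#' @param seed Master seed.
#' @param outDir Output directory for the report and stage caches
#'   (created; default a fresh temporary directory).
#' @param resume Reuse cached stage results with unchanged inputs.
#' @param quiet Suppress progress messages.
#' @return A pipeline report: per-stage `status`, headline `metrics`, the
#'   `seed`, parameters and output paths. Also written as
#'   `report.json` in `outDir`.
#' @export
runPipeline <- function(config = NULL, seed = 1L, outDir = tempfile("heatloop"),
                        resume = FALSE, quiet = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  params <- do.call(syntheticParams, as.list(config))
  status <- list(); metrics <- list()
  results <- new.env()
  log <- function(...) if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                                   sprintf(...)))
  runStage <- function(name, deps, fun) {
    failedDeps <- deps[vapply(deps, function(d)
      !identical(status[[d]], "ok"), logical(1))]
    if (length(failedDeps)) {
      status[[name]] <<- paste("skipped: dependency failed:",
                               paste(failedDeps, collapse = ","))
      log("stage %-14s skipped (%s)", name, failedDeps[1])
      return(invisible(NULL))
    }
    cache <- file.path(outDir, paste0(name, ".rds"))
    hashFile <- file.path(outDir, paste0(name, ".hash"))
    h <- .stageHash(list(params = params, seed = seed,
                         deps = lapply(deps, function(d) results[[paste0(d, ".hash")]])))
    if (resume && file.exists(cache) && file.exists(hashFile) &&
        identical(readLines(hashFile), h)) {
      results[[name]] <- readRDS(cache)
      results[[paste0(name, ".hash")]] <- h
      status[[name]] <<- "ok"
      log("stage %-14s reused from cache", name)
      return(invisible(NULL))
    }
    out <- tryCatch(fun(), error = function(e) e)
    if (inherits(out, "error")) {
      status[[name]] <<- paste("failed:", conditionMessage(out))
      log("stage %-14s FAILED: %s", name, conditionMessage(out))
    } else {
      results[[name]] <- out
      results[[paste0(name, ".hash")]] <- h
      saveRDS(out, cache, compress = FALSE)
      writeLines(h, hashFile)
      status[[name]] <<- "ok"
      log("stage %-14s done", name)
    }
    invisible(NULL)
  }

  runStage("simulate", character(0), function() generateDataset(params, seed))

  runStage("compartments", "simulate", function() {
    ds <- results$simulate
    act <- rebinTrack(ds$tracks$H3K9ac, binSize(ds$layout))
    out <- list()
    for (cond in params$conditions) {
      cm <- ds$contacts$HiC[[cond]]
      prof <- compartmentPC1(cm, act)
      sad <- saddlePlot(cm, prof)
      out[[cond]] <- list(profile = prof, saddle = sad)
    }
    if (params$amplitude == 0) {
      ## no compartments planted: recovery is undefined
      out$recoveryPct <- NA_real_
    } else {
      truthLab <- unlist(lapply(ds$truth$comps, function(z) ifelse(z == 1, "A", "B")))
      called <- unlist(lapply(chromNames(ds$layout), function(chr)
        compartmentLabels(out[["0h"]]$profile, chr)))
      unm <- called != "masked"
      out$recoveryPct <- if (any(unm)) 100 * mean(called[unm] == truthLab[unm]) else NA_real_
    }
    out
  })

  runStage("scaling", "simulate", function() {
    ds <- results$simulate
    out <- list()
    for (cond in params$conditions) {
      cm <- ds$contacts$HiC[[cond]]
      out[[cond]] <- list(peri = scalingCurve(cm, "pericentromere"),
                          arm = scalingCurve(cm, "arm"))
    }
    out
  })

  runStage("reclass", "simulate", function() {
    ds <- results$simulate
    pk <- classifyPeaks(ds$peaks, ds$genes)
    pk <- enhancerSignature(pk, ds$tracks)
    pk
  })

  runStage("interactions", "simulate", function() {
    ds <- results$simulate
    out <- list()
    for (cond in params$conditions)
      out[[cond]] <- callInteractions(ds$contacts$HiC[[cond]],
                                      minDistBins = params$loopDistRange[1] - 5L,
                                      maxDistBins = params$loopDistRange[2] + 20L,
                                      keepAll = TRUE)
    out$diff <- differentialInteractions(
      out[["1h"]][out[["1h"]]$significant, ],
      out[["0h"]][out[["0h"]]$significant, ],
      Na = totalPairs(ds$contacts$HiC[["1h"]]),
      Nb = totalPairs(ds$contacts$HiC[["0h"]]),
      allA = out[["1h"]], allB = out[["0h"]])
    out
  })

  runStage("hubs", c("simulate", "interactions", "reclass"), function() {
    ds <- results$simulate
    pk <- results$reclass
    sig1h <- results$interactions[["1h"]]
    sig1h <- sig1h[sig1h$significant, ]
    ann <- annotateAnchors(sig1h, ds$layout, ds$genes,
                           rePeaks = pk[pk$class == "distal"])
    list(annotated = ann, hubs = detectHubs(ann))
  })

  runStage("apa", c("simulate", "interactions"), function() {
    ds <- results$simulate
    flagged <- ds$truth$loops[ds$truth$loops$hsfa1aBound, ]
    list(loops1h = apa(ds$contacts$HiC[["1h"]], flagged),
         loops0h = apa(ds$contacts$HiC[["0h"]], flagged),
         random = apa(ds$contacts$HiC[["1h"]],
                      randomAnchorPairs(ds, 100L, substreamSeed(seed, "apa-null"))))
  })

  runStage("strata", "simulate", function() {
    ds <- results$simulate
    coup <- generateCoupledInteractions(seed = substreamSeed(seed, "strata"))
    ints <- callInteractions(coup$cm, minDistBins = 10L, maxDistBins = 60L,
                             keepAll = TRUE)
    key <- paste(ints$bin1, ints$bin2)
    planted <- ints[key %in% paste(coup$loops$bin1, coup$loops$bin2), ]
    accessibilityStrata(planted, coup$cm, coup$atacPeaks)
  })

  runStage("clustering", "simulate", function() {
    tc <- generateTimecourseProfiles(seed = substreamSeed(seed, "profiles"))
    km <- kmeansTimecourse(tc$profiles, k = 5L, seed = substreamSeed(seed, "kmeans"))
    som <- somFit(tc$profiles, grid = c(3L, 2L), seed = substreamSeed(seed, "som"))
    list(truth = tc$truth, kmeans = km, som = som,
         somPurity = somPurity(som$unit, tc$truth))
  })

  runStage("network", c("simulate", "reclass"), function() {
    ds <- results$simulate
    buildTFNetwork(ds$tfs, results$reclass, ds$de, ds$genes, ds$genome,
                   accThreshold = params$accThreshold)
  })

  runStage("concordance", c("simulate", "reclass"), function() {
    ds <- results$simulate
    atacExpressionConcordance(results$reclass, ds$expr)
  })

  runStage("assays", "simulate", function() {
    ds <- results$simulate
    rif <- relativeInteractionFrequency(ds$qpcr)
    bio <- attr(rif, "perBio")
    pick <- function(gt, cond, loop)
      bio$rif[bio$genotype == gt & bio$condition == cond & bio$loop == loop]
    tWtMut <- twoSampleT(pick("WT", "1h", "A"), pick("hsfa1a-1", "1h", "A"))
    list(rif = rif, luc = luciferaseActivity(ds$luc), tWtMut = tWtMut)
  })

  ## headline metrics
  if (identical(status$compartments, "ok")) {
    metrics$compartmentRecoveryPct <- results$compartments$recoveryPct
    for (cond in params$conditions)
      metrics[[paste0("saddleStrength_", cond)]] <-
        results$compartments[[cond]]$saddle@strength
  }
  if (identical(status$scaling, "ok"))
    metrics$scalingSlopeArm0h <- results$scaling[["0h"]]$arm$slope
  if (identical(status$interactions, "ok")) {
    ds <- results$simulate
    sig <- results$interactions[["1h"]]
    sig <- sig[sig$significant, ]
    key <- paste(sig$chrom, sig$bin1, sig$bin2)
    loops <- ds$truth$loops
    metrics$loopRecall1h <- mean(paste(loops$chrom, loops$bin1, loops$bin2) %in% key)
    dd <- results$interactions$diff
    gk <- paste(loops$chrom[loops$type == "gained"],
                loops$bin1[loops$type == "gained"],
                loops$bin2[loops$type == "gained"])
    dk <- paste(dd$chrom, dd$bin1, dd$bin2)
    metrics$gainedRecovered <- sum(dd$direction[dk %in% gk] == "gained")
  }
  if (identical(status$apa, "ok")) {
    metrics$apaScoreGained1h <- results$apa$loops1h$score
    metrics$apaScoreGained0h <- results$apa$loops0h$score
    metrics$apaScoreRandom <- results$apa$random$score
  }
  if (identical(status$strata, "ok"))
    for (k in 0:2)
      metrics[[paste0("strataMeanCat", k)]] <-
        results$strata$summary$meanStrength[results$strata$summary$category == k]
  if (identical(status$clustering, "ok"))
    metrics$somPurity <- results$clustering$somPurity
  if (identical(status$network, "ok"))
    metrics$networkEdges <- nrow(results$network$edges)
  if (identical(status$assays, "ok")) {
    bio <- attr(results$assays$rif, "perBio")
    wt1 <- mean(bio$rif[bio$genotype == "WT" & bio$condition == "1h" & bio$loop == "A"])
    metrics$rifFoldWT1h <- wt1
    metrics$tTestWtMutP <- results$assays$tWtMut$p
  }

  report <- list(seed = seed, params = params[c("depth", "amplitude", "gamma",
                                                "loopFold", "conditions")],
                 status = status, metrics = metrics, outDir = outDir)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  report$results <- as.list(results)
  class(report) <- "heatloopReport"
  invisible(report)
}

#' @export
print.heatloopReport <- function(x, ...) {
  cat("heatloop pipeline report (seed", x$seed, ")\n")
  for (nm in names(x$status)) cat(sprintf("  %-14s %s\n", nm, x$status[[nm]]))
  cat("metrics:\n")
  for (nm in names(x$metrics))
    cat(sprintf("  %-24s %s\n", nm,
                format(x$metrics[[nm]], digits = 4)))
  invisible(x)
}
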