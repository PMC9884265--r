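## Shared fixtures, generated once per test run and cached in this
## environment (helpers are sourced once by testthat, so the cache is
## shared across test files).

.fixtureCache <- new.env(parent = emptyenv())

## full study-condition preset
presetDataset <- function(seed = 1L) {
  key <- paste0("preset", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateDataset(syntheticParams(), seed)
  .fixtureCache[[key]]
}

## loops-over-decay benchmark: the cumulative-binomial caller's background
## model (coverage x distance decay) holds exactly; compartment and
## condition modifiers are off so planted loops are the only enrichment
loopBenchParams <- function() {
  syntheticParams(amplitude = 0, aaBoost = 1, bbDamp = 1, periDamp = 1)
}

loopBenchDataset <- function(seed = 1L) {
  key <- paste0("bench", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateDataset(loopBenchParams(), seed)
  .fixtureCache[[key]]
}

## compartment-free null replicates for the saddle-strength null
nullDataset <- function(seed = 1L) {
  key <- paste0("null", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateDataset(
      syntheticParams(amplitude = 0, nGainedLoops = 0L, nStableLoops = 0L),
      seed)
  .fixtureCache[[key]]
}

## down-scaled parameter set for fast structural tests
tinyParams <- function(...) {
  syntheticParams(
    chromLength = 2e6, depth = 2e5, nGenes = 400L,
    nProximalPeaks = 60L, nDistalPeaks = 80L, nEnhancerPeaks = 10L,
    nArchetypeIDistal = 20L, nHsfPlanted = 15L,
    nHsfTargets = 8L, nWrkyTargets = 5L, nDE1h = 30L,
    nGainedLoops = 4L, nStableLoops = 4L, ...)
}

loopKey <- function(df) paste(df$chrom, df$bin1, df$bin2)

## tiny two-gene annotation used by several unit tests
tinyGenes <- function() {
  gr <- GenomicRanges::GRanges(
    c("chr1", "chr1"),
    IRanges::IRanges(c(5000, 20000), c(6999, 21999)),
    strand = c("+", "-"),
    gene_id = c("gA", "gB"))
  GenomeInfoDb::seqlengths(gr) <- c(chr1 = 50000)
  gr
}
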