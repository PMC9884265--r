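# heatloop

Integrative analysis of 3D chromatin reorganization under heat stress, built
for studies that combine Hi-C / capture-Hi-C / HiChIP contact data with
ATAC-seq, histone-mark ChIP-seq, RNA-seq, TF binding (DAP-seq) and
locus-level validation assays (3C-qPCR, dual luciferase). The motivating
system is the transcriptional heat-stress response of tomato, where heat
transiently rewires enhancer–promoter contacts under the control of heat
shock factors (HSFs), strengthens A–A compartment interactions and
decompacts pericentromeric heterochromatin — but every analysis operates on
generic binned matrices, tracks, peaks and count tables.

## What it computes

**Compartments.** For a binned intra-chromosomal contact matrix *M*, the
expected contact at separation *d* is the diagonal mean
*E(d) = mean{ M<sub>ij</sub> : |i−j| = d }*; the observed/expected map is
*OE<sub>ij</sub> = M<sub>ij</sub>/E(|i−j|)*. Compartments are the sign of
the leading eigenvector (PC1) of the centered Pearson correlation map of
*OE*, per chromosome, oriented so A (PC1 > 0) has the higher mean activity
signal (H3K9ac). Saddle plots bin the genome into *Q* = 50 PC1 quantile
groups; compartment strength is
*(AA&#773; × BB&#773;)/(AB&#773; × BA&#773;)* over the 5×5 extreme-quantile
corners. *P(s)* scaling curves report mean raw contact frequency against
genomic separation separately for chromosome arms and pericentromeres, with
a log–log slope.

**Interaction calling.** A HOMER-style cumulative binomial: with *N* total
intra-chromosomal pairs, bin coverages *c<sub>i</sub>* and the normalized
distance-decay weight *f(d)*, each tested bin pair gets
*p₀ = (c<sub>i</sub>/N)(c<sub>j</sub>/N) f(|i−j|)/Z* (with *Z* making the
expected probabilities a distribution over the matrix) and the p-value
*P(X ≥ k)*, *X ~ Binomial(N, p₀)*, thresholded at 0.05 (BH optional).
Differential interactions between conditions use Fisher's exact test on
depth-conditioned 2×2 tables. Downstream: promoter-/RE-centric hub
detection, anchor-accessibility stratification, and aggregate peak analysis
(APA: mean O/E submatrix around loop pixels, center score over the
short-distance background corner).

**Regulatory elements.** Accessible peaks are split into TSS-proximal
(within 1.0 kb upstream of a TSS, strand-aware), TSS-distal (≥ 1 kb from
every gene body and promoter window) and genic-other. Distal peaks whose
nucleosome flanks are high in H3K9ac and H3K18ac and devoid of H3K4me3
(cohort quantile rule) are labeled enhancer-like. Time-course accessibility
profiles are clustered by seeded k-means++ (k = 5) and a batch
self-organizing map; proximal-peak accessibility is correlated (Spearman)
with linked-gene expression.

**Motifs and networks.** PWM log-odds scanning (both strands, exact
DP-calibrated score thresholds), binomial motif enrichment against seeded
length-matched genomic background windows, DAP-peak→target-gene association
around TSSs, and a time-resolved TF→gene network requiring motif hit +
accessible peak in the promoter + differential expression at the same time
point.

**Assays.** 3C-qPCR relative interaction frequency
*RIF = E^(−(Ct_target − Ct_norm))* normalized to an uncut region and scaled
to the reference group; dual-luciferase LUC/REN activity normalized to the
minimal-promoter control; pooled-variance two-sample Student's *t*-tests.

**Synthetic data.** A seeded generator plants all of the above — two
5-Mb chromosomes at 20-kb bins, power-law decay (γ = 1), A/B checkerboard
(amplitude 0.4), heat-condition modifiers (A–A ×1.3, B–B ×0.7,
pericentromere ×0.5 at 1 h, reverting at 6 h), 20 promoter–RE loops of
fold 3 (10 transiently heat-gained, HSF-bound), chromatin-signature tracks,
coupled expression, a two-wave TF cascade and assay tables — and returns
the ground truth so every stage can be scored.

## Worked example

```r
library(heatloop)
report <- runPipeline(seed = 1, quiet = TRUE)
print(report)
```

```
heatloop pipeline report (seed 1 )
  simulate       ok
  compartments   ok
  ...
metrics:
  compartmentRecoveryPct   100
  saddleStrength_0h        5.537
  saddleStrength_1h        5.317
  saddleStrength_6h        5.608
  scalingSlopeArm0h        -1.234
  loopRecall1h             1
  gainedRecovered          10
  apaScoreGained1h         4.495
  apaScoreGained0h         1.351
  apaScoreRandom           1.372
  strataMeanCat0           1.567
  strataMeanCat1           2.553
  strataMeanCat2           3.631
  somPurity                1
  networkEdges             35
  rifFoldWT1h              2.523
  tTestWtMutP              1.53e-05
```

Reading the numbers: all 500 genome bins are assigned to their planted
compartment; compartment strength ≈ 5.5 at the planted checkerboard
amplitude; the arm scaling slope is near the planted decay exponent (the
fitted −1.23 includes the compartment texture on top of γ = −1); all 20
planted loops are recalled at 1 h and all 10 heat-gained loops are labeled
"gained" by the Fisher differential test; the APA center score at the
HSF-bound loops jumps from ≈ 1.4 (0 h) to ≈ 4.5 (1 h) while random anchor
pairs stay near the compartmental background; interaction strength rises
with the number of accessible anchors (1.6 → 2.6 → 3.6); the SOM separates
the planted accessibility archetypes perfectly; the TF network recovers the
35 planted cascade edges; and the 3C-qPCR module estimates the planted
wild-type 1 h fold change of 2.5 with a highly significant wild-type vs
knock-down separation.

Individual stages are ordinary functions — `generateDataset()`,
`compartmentPC1()`, `saddlePlot()`, `scalingCurve()`, `callInteractions()`,
`differentialInteractions()`, `apa()`, `classifyPeaks()`,
`enhancerSignature()`, `kmeansTimecourse()`, `somFit()`, `pwmScan()`,
`motifEnrichment()`, `buildTFNetwork()`,
`relativeInteractionFrequency()`, `luciferaseActivity()` — see their help
pages and the methods vignette (`vignettes/heatloop-methods.Rmd`).

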