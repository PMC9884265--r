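---
title: "heatloop: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{heatloop: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind each analysis stage,
the tunable parameters with their defaults and rationale, what the
synthetic-data generator does and does not emulate, and the numerical and
design decisions a maintainer would want to know. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## Data model and conventions

All coordinates are 1-based and closed, the GenomicRanges convention; BED
and bedGraph input/output converts at the boundary through rtracklayer, so
a single convention holds everywhere internally. A `GenomeLayout` fixes
chromosome lengths, one pericentromeric interval per chromosome and a bin
size; bins tile each chromosome left to right (last bin may be short). A
bin belongs to the pericentromere when its midpoint falls inside the
interval; everything else is chromosome arm. The TSS of a minus-strand
gene is its annotation end; promoters extend upstream in strand direction
(1.5 kb for capture-bait design, matching typical promoter-capture panels;
1.0 kb for the proximal-peak rule).

Contact matrices are per-chromosome, symmetric, raw counts; `totalPairs`
records the library size including inter-chromosomal pairs dropped at
binning. The sparse interchange format is a `chrom bin_i bin_j count`
upper-triangle TSV with a bin-table sidecar; floats survive a round trip
to 7 significant digits, coordinates exactly.

## Matrix balancing

`balanceMatrix()` is plain iterative proportional fitting: divide rows and
columns by their marginals (normalized to mean 1) until unmasked row sums
agree within `tol = 1e-3`, at most 200 iterations. Bins with raw marginal
below 5% of the median positive marginal are masked (`NA`) — these are the
unmappable/empty bins whose inclusion destabilizes the iteration. The
procedure is idempotent and invariant to global scaling; non-convergence
returns the best iterate with a warning rather than failing, because a
partially balanced matrix is still usable for O/E-based analyses.

## Compartments, saddles, scaling

The expected-by-distance model is the per-diagonal mean of unmasked
entries; O/E therefore has unit diagonal means by construction (asserted
to 1e-9 in tests). The correlation map uses pairwise-complete Pearson
correlation of O/E rows; zero-variance rows are masked. PC1 is the leading
eigenvector of the column-centered (then symmetrized) correlation map,
computed **per chromosome** — inter-chromosomal PCA is out of scope. A
leading-eigenvalue gap below 1e-8 (relative) marks the chromosome
degenerate and masks it, which is what happens on a constant correlation
map. The sign of PC1 is not identifiable from the matrix alone, so it is
oriented by an activity track (H3K9ac by default): flipped if needed so
mean activity over PC1 > 0 bins is at least that over the rest. Flipping
the activity track flips all labels; this is a convention, not an
inference.

Saddle plots rank unmasked bins genome-wide by PC1 into `Q = 50`
equal-occupancy groups and average O/E over intra-chromosomal pairs at
separation ≥ 2 bins (the near-diagonal carries distance artifacts, not
compartment signal). Strength is the ratio product
`(AA × BB)/(AB × BA)` over `corner = 5` extreme groups; the sum form
`(AA + BB)/(AB + BA)` is also reported. The ratio product is the default
because it responds symmetrically to A- and B-side changes.

One subtlety matters for null behavior: ranking a matrix by a PC1 derived
from that same matrix overfits — on compartment-free data the noise
eigenvector still sorts bins by their own noise, inflating strength above
1 (we measure ≈ 1.13 at the desk-scale depth). Where the *absolute* null
level matters, strength is therefore quantified cross-replicate: PC1 from
one biological replicate, saddle on the other. That removes the selection
bias (null strength 1.00 ± 0.05) while leaving real-compartment strength
monotone in the planted amplitude. Within-sample saddles remain the
default for condition comparisons, where the bias cancels.

Scaling curves average **raw** counts per log2-spaced separation bin
(spacing 0.5 in log2) over pairs with both bins in the region class, and
fit a log–log slope between 3 bins and a quarter of the region span
(least squares; the near-diagonal and the sparse far tail are excluded
from the fit). Raw rather than depth-normalized counts is deliberate: the
generator models contact loss (heat decompacts pericentromeres) as lost
ligation events, i.e. a smaller library, not as redistribution — the
analysis must not re-inflate arm curves through CPM normalization. This
mirrors the experimental caveat that heterochromatin contact loss
mechanically increases usable sequencing depth elsewhere. Difference maps
(e.g. RNAPII HiChIP − Hi-C), by contrast, are depth-normalized to counts
per million valid pairs before subtraction, because there the comparison
is across assays of different depth.

## Interaction calling and downstream

The caller is a cumulative-binomial model in the HOMER tradition: the
background probability of a pair is the product of its bin coverage
frequencies times the distance-decay weight, renormalized so the expected
probabilities form a distribution over the whole matrix (`Σ p₀ = 1`); the
p-value is the upper binomial tail at the library size, computed through
the regularized incomplete beta function (`pbinom`), which matches a
brute-force tail summation to 1e-12 relative for N ≤ 2000. Defaults: raw
p ≤ 0.05 (the conventional threshold for such callers); BH adjustment is
the default for synthetic benchmarking and recommended generally. Two
calling resolutions are conventional — fine (hundreds of bp) for
short-range promoter interactomes, 20 kb for long-range — and both are
ordinary parameters here, since the caller only sees bins.

The model's background assumes coverage × decay; it does **not** model
compartments. On checkerboarded matrices, A–A pairs are genuinely enriched
over that background and will be called. For that reason the numeric
recall/precision benchmarks run on a loops-over-decay construction
(amplitude 0, condition modifiers off), which is the regime the model is
specified for; the qualitative condition effects (saddle corners, APA heat
gain) are benchmarked on the full compartmental preset. Precision is
evaluated against a candidate set of planted loops plus 200 sampled
non-loop pairs matched in distance and compartment.

Anchor annotation labels each anchor `promoter` / `RE` / `other`, removes
self-loops, collapses duplicate unordered pairs (first-seen metadata kept)
and drops interactions with no gene annotation on either anchor; whether
one or both anchors must be gene-annotated is ambiguous in practice, so
"at least one" is the default with `requireBoth = TRUE` available.
Differential calling is Fisher's exact test on
`(k_a, N_a − k_a; k_b, N_b − k_b)` with BH — exact, symmetric under group
swap, and appropriate for the small per-pixel counts; the direction label
is by rate comparison. APA stacks `(2w+1)²` O/E windows (default `w = 5`,
minimum 3) over loop pixels; loops within `w` of an edge or with
separation ≤ 2w are excluded and counted. The center score divides the
center pixel by the mean of the 3×3 **lower-left** corner — the
short-distance side, the standard background choice because it is the
conservative (highest-background) corner.

## Regulatory elements and clustering

Proximal means overlapping the strand-aware window `[TSS − 1000, TSS)`;
distal means ≥ 1 kb from every gene body *and* every promoter window;
peaks inside gene bodies or the in-between margin form a third class
(`genic-other`) so that both named categories stay pure. A flag
(`allowGenicDistal`) relaxes the gene-body exclusion without changing the
default. Each proximal peak is linked to its nearest TSS.

The enhancer signature operates on nucleosome flanks: ± 500 bp around the
accessible interval, excluding the interval itself (the accessible core is
nucleosome-depleted). Thresholds are cohort quantiles over distal-peak
flanks — high means ≥ the 0.75 quantile for H3K9ac and H3K18ac, devoid
means ≤ the 0.25 quantile for H3K4me3 — because the underlying biology is
stated qualitatively (high/low), signal units are arbitrary, and quantile
rules are invariant to track scaling. The rule is monotone (raising
H3K4me3 can only remove labels) and never labels proximal peaks, whose
flanks carry the H3K4me3-high promoter signature.

Profiles are row-standardized before clustering (shape, not magnitude, is
the object of interest). k-means uses seeded k-means++ initialization with
Lloyd refinement (assignment fixpoint, ≤ 300 iterations) and 10 restarts
keeping the lowest inertia — a single start falls into local optima on a
noticeable fraction of seeds with five archetypes over three time points;
restarts are standard and stay fully seed-reproducible. Cluster ids are
relabeled by descending size. The batch SOM initializes prototypes
linearly on the first two principal components, uses a Gaussian
neighborhood with radius decaying linearly from `max(grid)/2` to 0.5 over
50 epochs, and guarantees a non-increasing quantization error: if a
neighborhood-smoothed epoch would increase it, that epoch applies a plain
batch k-means step instead (which cannot increase distortion).

## Motifs and the TF network

PWMs are built from IUPAC consensus strings (ambiguity codes split the
probability mass, `N` is background) with pseudocount 0.01, scored as
log2-odds against the background composition. Score thresholds are
calibrated exactly: the null score distribution of a background window is
convolved column by column on a 1e-3 score grid (dynamic programming), and
the threshold is the smallest score whose tail probability is ≤ the target
(default 1e-4 per position), minus one grid step per column to absorb
discretization. Scanning covers both strands with forward-strand
coordinates; `N` bases contribute log-odds 0. Enrichment compares the
fraction of peaks with ≥ 1 hit to 10,000 (configurable) seeded
length-matched genomic windows excluding the peaks, with an upper binomial
tail; a zero background rate with observed hits is reported as
`p < 1/bgDraws` with a flag.

Network edges require the conjunction: TF motif hit inside a peak
overlapping the gene's promoter, peak accessible at the time point, gene
differentially expressed at that time point. Edges use a stricter motif
threshold (1e-6 per position) than exploratory scanning, because a single
false motif hit fabricates a regulatory claim. TF nodes carry their own
expression direction; output is sorted and independent of input order.
Target-regulation percentages are reported at one decimal, rounded half
away from zero, the convention of the field's summary figures. Halo-tag
control subtraction is peak-level exclusion, not signal deconvolution.

## Validation assays

Relative interaction frequency assumes amplification efficiency
`E = 2` per cycle (exposed as a parameter):
`RIF = E^(−(Ct_target − Ct_norm))`, with the normalization Ct from a
region uncut by the restriction enzyme, making RIF invariant to template
amount. Technical replicates are averaged before biological ones (equal to
flat averaging when the design is balanced), and the reference group (WT
at 0 h by default — the reference must be stated, it is not inferable)
anchors the scale at 1 per loop. Luciferase activity is the per-replicate
LUC/REN ratio, normalized to the minimal-promoter control's mean, so the
control is exactly 1 and any common REN rescaling cancels. The t-test is
the pooled-variance Student form (`df = n_a + n_b − 2`) because that is
the named test for these comparisons; Welch is available behind a flag.
Zero pooled variance returns `t = 0, p = 1` for equal means and a flagged
machine-minimum p otherwise.

## The synthetic generator

Defaults define the study-like conditions: 2 chromosomes × 5 Mb at 20-kb
bins (250 bins each); pericentromere at 40–60% of each chromosome (all
B compartment); arms of alternating 25-bin A/B blocks arranged so A and B
are balanced and translation-symmetric on the arms; decay exponent
γ = 1.0; checkerboard amplitude 0.4; 10⁶ valid pairs per chromosome at
0 h. At 1 h, A–A intensity ×1.3, arm B–B ×0.7, pericentromeric pairs
×0.5; 6 h reverts fully. Each condition's library size is drawn
proportional to its total intensity — contacts lost in pericentromeres are
*lost*, not redistributed — which, together with the symmetric arm layout
(the ×1.3 and ×0.7 cancel exactly in the arm average), keeps arm scaling
curves stable across conditions while the pericentromeric curve halves.

Twenty promoter–RE loops of fold 3 are planted in A-compartment arm bins
at separations of 12–35 bins (240–700 kb, typical for plant
enhancer–promoter contacts); anchors are distinct bins hosting a real
promoter (bin 1) and a distal-RE slot (bin 2). Ten loops are transient
heat-gained (present only at 1 h, flagged HSF-bound); ten are stable. The
separation range is also a power statement: at the preset depth the
expected pixel count at separation *d* bins is roughly
`10⁶ / (d · n ln n)` ≈ 15–40 over this range, which is what a per-pixel
Fisher test needs to detect a fold-3 gain at BH 0.05 — loops planted at
megabase separations would be statistically invisible at desk scale, and
a benchmark against undetectable truth measures power, not correctness.
HiChIP matrices re-weight RNAPII-anchored loop pixels ×4. Counts are one
multinomial draw per chromosome over the upper triangle, so totals are
exact and everything downstream sees genuine sampling noise.

Tracks are planted mean landscapes at 200-bp bins times multiplicative
Gamma(shape 4, mean 1) noise: H3K9ac and ATAC ×3 in A bins (H3K9ac also
orients PC1 after re-binning to 20 kb); all marks ×4 at promoters; the 30
planted enhancers get H3K9ac/H3K18ac ×6 and H3K4me3 ×0.05 on their
flanks; RNAPII ×4 at promoters and ×3 at loop REs. Peaks: 200 proximal,
300 distal (width 300 bp); 60 distal peaks are 1 h-transient
(accessibility archetype low-high-low) and 50 of them carry a planted
heat-shock-element consensus; accessibility profiles for the remaining
coupled proximal peaks follow their linked gene's latent expression
profile with exponent 0.8 and log-normal noise (sd 0.2). Latent
(non-designed) genes fluctuate with log2-sd 1.5 across the time course —
heat reprograms broadly — which gives the accessibility–expression
coupling enough dynamic range for rank correlations over only three time
points. Expression is negative binomial (dispersion 0.05, 2 replicates as
in the study design), with 100 genes differentially expressed at 1 h
(|log2FC| = 2, transient) including the 20 HSF-wave targets, and 15
WRKY-wave targets at 6 h. The simple DE caller (median-of-ratios size
factors, t-test on log2 normalized counts, BH) is intentionally basic
plumbing; note that at 2 replicates a t-test with 2 degrees of freedom
cannot reach high recall at BH 0.05 for these effect sizes, so its
recovery benchmark runs at 4 replicates. qPCR tables encode a WT 1 h/0 h
fold of 2.5 and knock-down folds of 0.6 with Ct noise sd 0.15 cycles
(3 biological × 3 technical replicates); luciferase folds are 2.5 and 3.5
with log-normal noise sd 0.1, n = 3.

One master seed expands into fixed-label substreams (`substreamSeed`), so
adding a component never perturbs existing draws and identical seeds give
byte-identical datasets.

**What the generator does not emulate.** Restriction-fragment artifacts
(dangling ends, re-ligations), mappability structure, copy-number and
repeat-driven coverage biases, capture-efficiency heterogeneity across
baits, trans-chromosomal contacts, TADs/insulation (not analyzed here),
replicate-level batch effects, and realistic genome sequence composition
(the genome is i.i.d. uniform with planted motifs). Passing recovery tests
therefore demonstrates that the estimators are correct under their stated
models at realistic depth and noise — not that they are robust to every
artifact of real libraries.

**Problem sizes.** The shipped benchmarks use the preset above (500 bins,
10⁶ pairs per chromosome, 500 peaks, 1000 genes), three seeds for
stochastic recovery claims and five for clustering; the full test suite
and the acceptance script each complete in a few minutes on one CPU.
These sizes were chosen as the smallest at which compartment PCA, saddle
corners and per-pixel loop statistics are stable.

## Known limitations

- The caller's background ignores compartments; under strong
  checkerboards it reports genuine A–A enrichment as interactions.
  A compartment-aware expected model would be the natural extension.
- Per-chromosome PC1 cannot compare compartment phase across chromosomes;
  the activity-track orientation resolves sign per chromosome only.
- The SOM's monotone-error fallback trades a little neighborhood
  smoothing for a guaranteed non-increasing quantization error.
- Fisher differential calling on single pixels has limited power below
  ~15 expected counts per pixel; pooling windows before testing would
  extend the detectable distance range.
- The assay module models normalization and testing, not plate effects or
  primer-efficiency curves (efficiency is a parameter, not a fit).
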