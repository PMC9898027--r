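---
title: "Continuous indexing of fibrosis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous indexing of fibrosis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, what the synthetic data generator
does and does not emulate, and the numerical and design choices made where
the method leaves room. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The ranking model

Fibrosis severity is learned as an *ordering*, not a regression target.
Human graders are much more reliable at "which of these two regions is
worse?" than at assigning absolute grades, so the training signal is a set
of pairwise comparisons. The model assigns each tile a scalar score
$s(x)$, and the probability that tile $a$ outranks tile $b$ is the
logistic of the score difference,

$$P(a \succ b) = \frac{1}{1 + e^{-(s_a - s_b)}},$$

trained by minimising the binary cross-entropy of these probabilities
against the comparison labels (the RankNet objective). Because only score
*differences* enter the loss, the score scale is arbitrary; after
training, scores are min--max normalised over the training reference tiles
and clipped to $[0, 1]$ to give the Continuous Index of Fibrosis (CIF).
Min--max was chosen over sigmoid or rank-based normalisation because it is
the simplest order-preserving map onto $[0,1]$; the anchors are frozen
with the model so unseen tiles cannot shift the scale.

**Scoring backbone.** The scorer is a fixed convolutional feature bank —
darkness, a dark-pixel indicator at gray level 0.55 and its 3×3
smoothing, Sobel gradient energy, Laplacian magnitude, four oriented
line-detector responses, and the within-tile darkness standard deviation —
pooled (mean) over each tile via summed-area tables, followed by a linear
scoring head trained on the pairwise loss. This choice reflects two
things: the contribution of the method is the ranking objective and its
calibration, not a particular network; and silver-stained reticulin is
dark, thin, linear material on a pale background, which small oriented
kernels capture directly. The head is zero-initialised (the model is
linear in its trainable part, so no symmetry breaking is required), which
also makes the "0 epochs leaves the model unchanged" contract exact.
Optimisation is full-batch gradient descent with classical momentum 0.9,
learning rate 0.5, 300 epochs, and an L2 penalty of $10^{-4}$; feature
standardisation is computed from the first round's training tiles and
frozen thereafter.

**Human-in-the-loop rounds.** Training proceeds in three rounds. In each
round pairs are proposed, labeled, and the head is retrained; within a
round 20% of pairs are held out, and the final reported accuracy is the
final model evaluated on the union of all rounds' held-out pairs. Two
pair-selection strategies are provided: uniform sampling without
replacement over distinct pairs, and an uncertainty strategy that
proposes the pairs with the smallest absolute score difference (among
nearby ranks). The bundled reference protocol uses uniform sampling in
all rounds: concentrating later rounds on near-tie pairs would make the
held-out pool unrepresentatively hard and the reported accuracy
incomparable across rounds.

**Annotator panel.** `simulate_annotators()` models each of three experts
as reporting the oracle comparison with probability equal to their
concordance (default 0.884), independently; disagreements are resolved by
majority vote (the reconciliation rule is otherwise unspecified in the
underlying protocol, and majority voting is unbiased and deterministic).
Two closed forms make this simulator testable: two independent raters
agree with probability $p^2 + (1-p)^2$, and the majority of three matches
the oracle with probability $3p^2(1-p) + p^3$.

## 2. Tiling and inclusion filters

Tiles are $512 \times 512$ px with stride 256 at full scale; positions
are 0-based with half-open windows, enumerated row-major, and boundary
remainders are dropped rather than padded (padding would distort the
area fractions the filters depend on). A tile is analysed only if fat
occupies $< 50\%$, bone $< 1\%$ and vessels $< 10\%$ of its area — all
strict inequalities, matching the stated thresholds; a tile exactly at a
threshold is excluded. Color input is converted to grayscale with Rec.601
luminance weights (configurable; the conversion exists to remove stain
color variation, and no specific formula is prescribed). An optional
analyzable-tissue mask further restricts the grid (a tile must be more
than half analyzable), standing in for manual annotation of suitable
regions.

The bundled synthetic cohorts use a half-scale geometry — 768² images,
128/64 tile/stride — preserving the 2:1 tile:stride ratio. This keeps the
per-sample tile grid (11×11) large enough for topology while holding the
full test suite and acceptance script to a few minutes of CPU.

## 3. Per-sample features

From each CIF map: the **average CIF** over included tiles; the **bin
distribution** $p_0..p_3$ over four bins (default equal-width edges 0,
0.25, 0.5, 0.75, 1 — the mapping of CIF to WHO grades is described only
as "broad", so the edges are configuration, not dogma); and
**heterogeneity**, the Shannon entropy $-\sum_k p_k \ln p_k / \ln 4$.
Normalising by $\ln 4$ puts heterogeneity in $[0,1]$, consistent with
reported per-sample values below 1; whether the original quantity was
normalised is not stated, and this choice is flagged as an
interpretation. Bins are half-open $[e_k, e_{k+1})$ with the top bin
closed so a score of exactly 1 is counted. Excluded tiles are never
imputed. Overlay rendering averages the scores of all tiles covering a
pixel (stride < size makes tiles overlap; averaging is symmetric and
order-independent) before colorisation.

## 4. Topology of the score map

The input to persistent homology is the tile-score grid, one cell per
tile — not the pixel-level overlay. The filtration is super-level:
thresholds sweep from the maximum score downward, and the set
$\{ \text{score} \ge t \}$ grows as $t$ falls.

*Dimension 0 (fibrotic foci).* A union-find sweep processes cells in
descending score order; a component is born at its peak cell, and at a
merge the younger component (lower birth) dies — the elder rule. Ties in
cell values are broken row-major, applied identically in the main
algorithm and the oracle, giving a total order and deterministic
barcodes. Components alive at the end are open (infinite) bars; the
number of open dimension-0 bars equals the number of connected
components of the grid support. Zero-persistence bars are dropped.

*Dimension 1 (holes).* Computed by boundary-matrix reduction over
$\mathbb{Z}/2$ on the cubical complex whose top cells are the grid cells
(T-construction): lower-dimensional cells enter with the maximum over
their incident cells. This gives the foreground 8-connectivity — the
standard convention for image super-level sets — with the complementary
4-connectivity implicit for holes. Holes enclosing permanently excluded
(`NA`) cells never die; they are genuine absence of tissue, reported as a
`mask_holes` count and excluded from the barcode by default
(`keep_open = TRUE` restores them, and the oracle-equivalence tests use
that mode since the Euler-characteristic count includes them).

*Verification.* An in-package brute-force oracle rebuilds each
super-level set explicitly, counts components by flood fill and cycles by
the Euler characteristic $C - V + E - F$ of the cell closure. The test
suite and the acceptance script check that the alive-bar counts of both
dimensions match the oracle at every distinct threshold on hundreds of
random grids, including grids with excluded cells and ties; a
perturbation test checks bottleneck-type stability at machine scale.

*Bar statistics.* Counts, total/max persistence, mean birth and
persistence entropy per dimension, plus two hotspot counters: the number
of dimension-0 bars born at or above an absolute threshold (default 0.6,
chosen a priori to sit between diffuse-background scores and hotspot
peaks), and the number of finite dimension-0 bars with persistence at
least 0.15. The second counter exists because per-sample baseline shifts
move absolute births but not persistences; which exact statistics the
original analysis used is not recoverable from the available text, so
the vector is a reasoned, configurable superset. Open bars contribute to
counts and births but are excluded from persistence sums unless a death
floor (e.g. the global minimum) is supplied.

## 5. Cohort space, classification and statistics

Features are z-scored before PCA, and both the standardisation and the
two retained components are frozen at fit time: indexing a new or
sequential biopsy must not move the space if longitudinal trajectories
are to be meaningful. Component signs are fixed deterministically
(largest-magnitude loading positive). The classifier is a 100-tree
random forest under stratified, seeded 3-fold cross-validation;
out-of-fold probabilities are pooled into a single AUC (the headline
number; per-fold AUCs are also reported since the aggregation rule is
otherwise unspecified), and Gini importances come from a forest refit on
all data, normalised to sum to 1. By default the forest consumes the raw
feature vector; passing a fitted disease space switches it to the 2-D
PCA coordinates (both readings of the original setup are supported).
Group comparisons use the two-sided Mann–Whitney–Wilcoxon test — exact
when both groups have at most 20 samples and no ties, otherwise the
normal approximation with tie and continuity correction — with explicit
Bonferroni adjustment (`n_comparisons` is always an argument, never
inferred) and distribution-free order-statistic 95% confidence intervals
for group medians (sample range when $n < 6$, where 95% coverage is
unattainable).

## 6. The synthetic generator

Every stage is testable because the generator exposes the latent truth
the pipeline is supposed to recover: a per-pixel severity field in
$[0,1]$. Appearance is derived from it — local fiber density (Poisson
candidates thinned by $0.05 + 0.95\,\sigma$), thickness (truncated normal
with mean scaled by $0.6 + 0.8\,\sigma$) and crossing frequency (an
intersection bias reseeds fibers near existing ones) all increase with
local severity, the three visual cues of worsening reticulin fibrosis.
Severity is a per-sample base level plus a smooth random field (bilinear
interpolation of a coarse Gaussian grid) plus hotspot disks: circular
microfoci whose severity is raised by a boost, placed uniformly or by a
Matérn-style parent/offspring rule so that foci cluster. Tissue context —
bright fat vacuoles, gray bony trabeculae, dark-walled vessels — is drawn
as mutually exclusive masks so the inclusion filters have something to
filter. Additive Gaussian intensity noise (sd 8 gray levels) prevents the
scorer from keying on brightness alone.

Default study conditions (chosen once, during design, as a realistic and
learnable regime; the pairwise information ceiling of the tile features
was checked against an independent logistic fit before freezing):
768² images; candidate fiber density 4500 per megapixel; thickness
2.0 ± 0.5 px; background/fiber gray 205/55; fat/bone/vessel area 8/4/2%.
The five class presets are reactive (base 0.05), ET-like (0.15 ± 0.08,
0–1 hotspots), PV-like (0.30 ± 0.08, 0–2 hotspots), prePMF-like (base
distribution identical to ET-like, 2–5 clustered hotspots of radius 48 px
and boost 0.6) and MF-like (0.55 ± 0.10). ET-like and prePMF-like
differing *only* in hotspot prevalence is deliberate: it isolates the
question the topological features exist to answer, and keeps average CIF
a weak discriminator between them.

**What passing tests do and do not show.** The generator emulates
severity-dependent fiber geometry, tissue context and spatial hotspot
structure; it does not emulate stain/scanner variation, true collagen
morphology, osteosclerosis, cellularity or annotation error in tissue
masks. Performance numbers on synthetic cohorts (ranking accuracy,
Spearman recovery, discrimination AUCs) therefore validate the
*machinery* — that the pipeline recovers a latent severity ordering and
detects spatially structured hotspots when they exist — and are not
estimates of clinical performance, which depends on trained weights and
cohorts that are not part of this package.

## 7. Problem sizes and determinism

The bundled experiments are sized for a single CPU: the reference
protocol trains on ten graded 768² samples with 3 × 700 pairs;
discrimination cohorts are 30 + 30 samples over 10 seeds; oracle
equivalence uses 200 random 8×8 grids; the null-calibration study uses
1000 replicates of five features. All randomness — generator, pair
sampling, annotator noise, splits, forests — derives from explicit seeds
through a seed-derivation helper that restores the caller's RNG state,
and identical seeds reproduce results bit-for-bit. The two hot numeric
primitives (replicate-padded convolution and integral images) are
compiled; the convolution is verified in tests against both a pure-R
shift-add reference and `EBImage::filter2`.

## 8. Known limitations

* The scorer's capacity is deliberately small; on image domains whose
  severity cues are not captured by oriented dark-line statistics it
  would need a richer (e.g. learned convolutional) backbone behind the
  same ranking interface.
* Dimension-1 reduction is dense list-based and intended for tile-grid
  scales (hundreds of cells), not pixel-resolution maps.
* Whole-slide container formats (NDPI/MRXS) are out of scope; inputs are
  PNG/TIFF rasters with companion masks.
* Bone/fat/vessel segmentation is an input, not a capability; the
  generator's masks are exact, so mask-error robustness is untested.
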