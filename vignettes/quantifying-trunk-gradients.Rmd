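---
title: "Quantifying anteroposterior expression gradients in planarians"
author: "plangrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anteroposterior expression gradients in planarians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plangrad)
```

## The measurement problem

Planarian trunk identity — the body region carrying the pharynx and mouth —
is bounded by overlapping, body-wide expression gradients of positional
control genes: *ndl-3* declining from the anterior, *ptk7* peaking in the
trunk, and *wntP-2* rising toward the posterior. Perturbing these genes by
RNAi shifts the trunk boundary and can produce ectopic posterior mouths and
pharynges. Asking quantitative questions about such phenotypes requires
several measurements that are easy to do inconsistently by hand:

* the **shape** of a body-wide gradient from a colorimetric (NBT/BCIP)
  whole-mount in situ stain, comparable across animals of different sizes;
* **per-cell expression states** from a triple fluorescent in situ
  hybridization (FISH), i.e. which combination of the three genes each
  subepidermal cell expresses at high level, and how those states
  distribute along the axis;
* **screen statistics** over phenotype count tables (penetrance, exact
  tests against a control condition, false-discovery correction);
* **morphometrics**: sizes and positions of expression domains and organs
  normalized to body length, and qPCR fold changes.

plangrad implements each of these as a small, seeded, testable pipeline
stage, together with a synthetic-image generator that plants known cells and
gradients so every stage can be validated against ground truth.

## Coordinate and intensity conventions

Images are numeric matrices (or row x col x 3 arrays) on an 8-bit scale
`[0, 255]`. The anteroposterior axis runs along image rows with the anterior
at row 1. Normalized axial position `u` runs from 0 at the anterior tip to 1
at the posterior tip of the body mask, computed from the mask's axial
bounding box — no anatomical landmarks are needed. The 8-bit range matches
the "arbitrary units" of the expression cutoffs used downstream (default 55,
sweep 30–75).

## The synthetic worm

`simulateWorm()` draws one animal:

1. **Body mask** (`makeWormMask`): a superellipse half-width profile
   `(4 v (1 - v))^p` with taper exponent `p = 0.35`, times a small seeded
   smooth modulation (three sine terms, up to 5% amplitude). The exponent is
   deliberately blunter than an ellipse (`p = 0.5`): planarian heads and
   tails are rounded, and with a sharp elliptical taper the axial extremes
   of the mask could hold no cells at all (cells are disks that must fit
   inside the body), which would systematically depress measured profiles
   exactly where the anterior and posterior gradients peak. The enclosed
   area stays within ~6% of the ellipse of the same axes.
2. **Cells** (`sampleCells`): a Poisson number of disk cells — mean =
   density x mask area — with radii uniform in 3–5 µm (cross-sections
   28–79 µm², inside the 24–166 µm² window the segmentation filter
   expects). Default density is 10 000 cells/mm²: with these radii that is
   roughly half the projected area covered, the confluent look of a
   subepidermal cell layer in a maximum projection. Centers keep a minimum
   spacing of one mean radius; disks may otherwise touch and overlap, so the
   segmentation stage faces realistic merged objects. `thinNonTouching()`
   derives the idealized non-touching fields used for recovery tests.
3. **Expression** (`assignExpression`): per cell and gene,
   `mu_g(u) * exp(N(0, sigma))`. The mean functions are
   `ndl3 = 20 + 120 exp(-u / 0.25)`,
   `ptk7 = 20 + 120 exp(-(u - 0.45)^2 / (2 * 0.18^2))`,
   `wntP2 = 20 + 120 exp(-(1 - u) / 0.25)` — an anterior-decaying, a
   trunk-peaked and a posterior-rising profile whose high/low boundaries at
   cutoff 55 carve the axis into the qualitative domains seen in triple
   FISH (anterior *ndl-3*-only, broad trunk *ptk7*, tail-tip
   *wntP-2*-only). Noise is multiplicative lognormal with `sdlog = 0.3`
   (FISH intensities are nonnegative and right-skewed; ~30% CV).
4. **FISH render** (`renderFishImage`): each cell painted as a disk of its
   per-gene intensity added over a uniform background (default 20), then a
   1 px Gaussian blur. Overflow beyond 255 is clipped and counted. The
   ground-truth table (cells plus true class at the stated cutoff) rides
   along as an attribute.
5. **WISH render** (`renderWishImage`): a light background (default 235)
   minus a darkness field proportional to expression — dark staining where
   expression is high, so that inversion recovers intensity proportional to
   expression. The stain of a cell spreads to twice its radius and the
   darkness field is blurred with sigma 20 px (10 µm): colorimetric
   precipitate is diffuse at dissecting-scope resolution, and a
   whole-animal stain looks smooth, not like a dot plot. The darkness gain
   (0.7) keeps peak staining inside the 8-bit range rather than saturating.

What the generator does **not** emulate: 3-D stacks and optical sectioning,
organ anatomy (pharynx, CNS), vignetting and photobleaching, staining
batch effects, and curved or bent animals. Tests passing on this generator
show the *procedures* are correct and robust to the modeled noise; they do
not certify performance on real images with artifacts outside the model.

## Axis profiles (colorimetric quantification)

The bench procedure is reproduced literally: invert the image
(`invertImage`, `255 - x`), walk a line from anterior to posterior along a
lateral region, average a perpendicular strip at each step, normalize, bin.

* **Path**: real profiles are drawn by hand; the deterministic surrogate
  (`lateralPath`) is the mask midline offset laterally by a quarter of the
  local width, with strip width = max body width / 6. Left or right side is
  equivalent by symmetry.
* **Sampling** (`extractRawProfile`): unit arc-length steps,
  nearest-pixel perpendicular offsets, no interpolation — simple and
  reproducible; sub-pixel schemes would be an extension. Pixels outside
  the body mask are excluded with a warning.
* **Normalization** (`normalizeProfile`): subtract the profile minimum
  (the background estimate), then divide by the maximum of the result; the
  order is fixed. Positions are binned into 100 half-open equal bins
  `[k/100, (k+1)/100)` (last bin closed) by averaging samples per bin;
  empty bins are filled by linear interpolation. A constant profile has no
  contrast and yields all zeros with a warning rather than 0/0.
* **Aggregation** (`aggregateProfiles`): per-bin sample mean and SD
  (n − 1 denominator) across animals; gradients are summarized over 6
  simulated animals, matching the 4–6 animals per probe of the bench
  procedure.

## Cell segmentation

`segmentWorm` composes the FISH quantification: the three channels are
merged by **arithmetic mean** (keeps the result in range and treats the
genes symmetrically), thresholded by Li's minimum cross-entropy method, and
run through a particle filter.

**Li threshold** (`liThreshold`): the criterion is
`eta(t) = -sum_{g<=t} h(g) g ln mu0(t) - sum_{g>t} h(g) g ln mu1(t)`.
The default method evaluates `eta` exactly at every candidate threshold via
cumulative sums and returns the global minimizer. Two numerical choices are
pinned: (i) the criterion is flat across unoccupied grey levels, so minima
sit on plateaus; the returned threshold is the floor of the plateau
midpoint (for a histogram with masses only at 10 and 200 this lands
strictly between them, with both classes pure). (ii) The classical
fixed-point iteration `t <- (mu0 - mu1) / (ln mu0 - ln mu1)` is available
as `method = "iterative"`; it is the historical formulation but can stall
in a local minimum of the discrete criterion on irregular histograms, which
is why the exact search is the default. Foreground is strictly above the
threshold. A histogram with fewer than two occupied levels is rejected —
no threshold separates anything.

**Particle filter** (`segmentParticles`): connected components
(8-connectivity by default; 4 available), holes filled before measurement
(a stained disk with a dim center is one cell), then two windows: physical
area within 24–166 µm² (converted through the user-supplied pixel size —
magnification is never inferred from files) and circularity
`4 pi A / P^2` within `[0, 1]`. Circularity is estimator-sensitive, so the
perimeter estimator is pinned: the weighted-boundary method (border pixels
weighted 1, sqrt(2), or (1 + sqrt(2))/2 by their local configuration),
under which a rasterized disk scores near 1; values are clipped to
`[0, 1]`. One threshold from the merged image defines the regions measured
in **all** channels (`measureCells`): per-region mean intensity per
channel, centroid, and `u` from the body mask. Regions whose centroid
falls outside the mask are excluded and counted.

## Expression classes

A cell is "hi" for a gene iff its mean intensity **>= cutoff** (the tie
rule is pinned as >=; default cutoff 55 in 8-bit units, the same cutoff
for all three channels). The three hi/lo calls map to the fixed classes
1 *wntP-2*-hi only, 2 *ptk7*-hi *wntP-2*-hi, 3 *ptk7*-hi only, 4 all hi,
5 *ptk7*-hi *ndl-3*-hi, 6 *wntP-2*-hi *ndl-3*-hi, 7 *ndl-3*-hi only,
8 all low. Regions are 8 equal axial bins (`floor(u * 8) + 1`, last bin
closed) for whole-animal synthetic data; for real imaged fields the region
is user-supplied metadata. Class fractions are per region; a region with no
cells reports missing values, never zero — an empty denominator is not
evidence of absence. Cells from several animals are pooled before the
fraction tables (the per-animal breakdown stays available in the cell
table). `thresholdSweep` repeats the classification across 10 cutoffs in
30–75; because the per-gene hi-set can only shrink as the cutoff rises,
the all-hi (class 4) total is non-increasing and the all-low (class 8)
total non-decreasing in the cutoff — a hard invariant the tests assert.

## Screen statistics

`fisherExact` computes the two-sided p of a 2x2 table by full
hypergeometric enumeration, summing all tables (at fixed margins) whose
point probability is at most that of the observed table. The
minimum-likelihood definition of "as extreme", with a relative tie
tolerance of 1e-7, is the dominant convention for 2x2 exact tests and
reproduces the printed `p = 1.000` for the 7/9 vs 7/10 comparison; the
suite checks it exhaustively against `stats::fisher.test` for all tables
with N <= 16. `bhCorrect` is the Benjamini–Hochberg step-up (via
`stats::p.adjust`), validated against a brute-force reference.
`enhancementScreen` tests each condition's affected/unaffected counts
against the designated control condition (for the enhancement screen, the
control + *ptk7* dsRNA condition), corrects across all tested conditions,
and flags significance at alpha = 0.05. Conditions scored on fewer than 5
animals are tested but flagged low-power, not dropped. p-values are kept at
full precision; rounding happens only at the CLI layer.

## Morphometrics and qPCR

Axial positions come from projecting mask pixels onto the mask's principal
axis (sign-aligned so the anterior maps low); for the axis-aligned
synthetic worms this reduces to the row coordinate, and a rotated animal is
handled by the same code. `domainLength` is the domain's axial extent over
the animal's axial length; `organPosition` is the distance from the
posterior tip to a chosen anchor over the animal length. The anchor
default is the domain **centroid** (pharynx position); domain-boundary
measurements use the **anterior or posterior edge** — the bench
descriptions name different anchors in different figures, so all three are
flags and none is presented as the only correct choice. Both measures are
invariant to translation and to uniform scaling of mask and domain
together.

`qpcrRelativeAbundance` implements the delta-delta-Ct method with assumed
amplification efficiency 2 (primer efficiency verified upstream):
`dCt = Ct_target - Ct_reference` per sample, `ddCt` relative to the mean
of the calibrator group, fold = `2^-ddCt`, and a two-tailed Welch t-test on
per-sample dCt values across groups (skipped with a warning when both
groups are constant). The reference gene is whatever the input provides
(*ubiquilin* or *clathrin* in the source data).

## Determinism and problem sizes

All randomness descends from one integer seed via fixed per-stage offsets;
identical seeds give bit-identical cell tables, images and CSV bodies, and
every pipeline CSV header records the package version, seed and an MD5
hash of the canonical YAML serialization of the configuration.

The test suite and the acceptance script run on deliberately desk-scale
problems: single animals of 300 x 80 px for unit tests, six animals of
1000 x 200 px for gradient recovery, 10^4 cells for distributional checks,
10^4 replicates for the exact-test null calibration, and exhaustive 2x2
enumeration to N = 16. These sizes were chosen so the whole suite runs in
minutes on one core while leaving the statistical checks enough power (the
binomial/Poisson 3-SE bands and the KS test at n = 10^3 are all computed
at these sizes).

## Known limitations

* Touching cells are kept as merged particles (usually then discarded by
  the area window); there is no watershed splitting, so dense fields
  under-count cells. This mirrors the original particle-analysis approach.
* Bent or curved animals are profiled along their principal axis without
  curvature correction; strongly C-shaped specimens need straightening
  upstream.
* The hi/lo cutoff is global per run. Per-channel cutoffs exist in
  `coexpressionCounts` but are off by default, since the source procedure
  used one cutoff for all channels.
* The WISH profile measures staining, which confounds expression level
  with local cell density; the synthetic generator reproduces this
  honestly (its profile recovers gradient *shape*, i.e. rank order, not
  absolute intensity units).
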