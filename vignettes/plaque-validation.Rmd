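---
title: "Validating intravascular plaque classifiers against histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating intravascular plaque classifiers against histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquematch)
```

## The problem

Machine-learning classifiers attached to intravascular imaging catheters —
NIRS-IVUS (near-infrared spectroscopy combined with intravascular
ultrasound) and OCT (optical coherence tomography) — segment coronary
cross-sections into lumen, vessel wall and plaque tissue classes: fibrotic
tissue (FT), calcium (Ca) and necrotic core (NC). Whether those estimations
can be trusted has to be established against histology, the reference
standard for plaque composition. That comparison is geometrically awkward:
a histological section comes from a depressurized, excised, shrunken vessel
at micron-scale pixel resolution, while the imaging frame shows the same
cross-section pressurized in vivo at a coarser resolution and an arbitrary
rotation. `plaquematch` implements the full validation pipeline: it
re-shapes an annotated histology section onto the matched imaging-frame
geometry and then quantifies agreement of plaque size and tissue
composition.

## The co-registration model

Both frames carry manually annotated lumen and external elastic membrane
(EEM) borders, stored as closed polygons (`contour()`), and a per-pixel
tissue label mask. Matching is driven by expert-placed landmark pairs —
corresponding points on the two lumen borders, typically anchored at
side-branch ostia and the circumferential plaque pattern.

Every point of the vessel wall is described in *band coordinates* relative
to the lumen border: its normalized arc-length position $s \in [0,1)$ along
the border, and its outward depth $d$ in millimetres. The warp maps an
imaging pixel at $(s_{img}, d)$ to the histology sample at
$(g(s_{img}), d)$, where

* $g$ is the circumferential map: a strictly monotone, circularly
  continuous, piecewise-linear interpolation through the landmark pairs
  (`build_arclength_map()`). It wraps across the $1 \to 0$ seam, so the
  histology section's rotation is absorbed by the landmarks.
* radial transfer preserves *physical depth*: depth in millimetres is kept
  and converted between the two pixel sizes. This embodies the method's
  central assumption that plaque is neither compressed nor elongated between
  the pressurized vessel and the section; what shrinkage mostly does is
  collapse the lumen, which band coordinates absorb by construction.

Two deliberate implementation choices differ from a literal "cut strips and
paste them" description while computing the same correspondence:

* **Inverse mapping.** Forward-pasted strips overlap or leave gaps wherever
  the lumen is concave. Iterating over *target* pixels and pulling source
  labels guarantees a gap-free warped mask.
* **Nearest-neighbour label transfer.** Labels are categorical; any
  interpolation would invent tissue classes at boundaries.

Where the histology lumen is concave, outward normals can cross; a source
sample constructed as "border point at $g(s)$ plus $d$ along the outward
normal" can then fold back inside the lumen. Such samples are marked
invalid rather than silently re-resolved through a different correspondence
rule: the folding marks exactly the place where the method's geometric
assumption breaks, and hiding it would overstate the warp's validity. For
the star-shaped lumens of real coronary cross-sections (and of the
synthetic generator) folding does not occur at plaque depths.

`strip_depth_mm` — the strip thickness — is user-specifiable; its default
is the imaging frame's deepest EEM point plus 0.5 mm so the whole plaque is
covered. The circumferential sampling resolution defaults to 720 positions
(0.5 degrees), finer than any structure the analyses resolve. Samples
mapped beyond the histology EEM keep the background label and never enter
plaque-level tallies. These choices are declared, not inferred: the
original description leaves strip thickness and the in-plane interpolation
rule open.

What the warp conserves is worth stating precisely, because a depth band
$[a,b]$ around a lumen of radius $r$ has physical area
$\pi\,((r+b)^2-(r+a)^2)$, which *changes* with $r$. Depth-preserving
transfer therefore reproduces each tissue band at its source depths in the
*target* geometry, and the warped band area matches the analytic band area
of the target lumen — not the band area measured around the collapsed
histology lumen. The conservation tests check exactly that closed form, at
lumen dilation factors 0.5–2 and pixel-size ratios 0.25–4.

## Quantitative agreement

Per frame and per source (histology vs classifier), the pipeline computes
EEM area, lumen area, plaque area (EEM minus lumen), plaque burden (plaque
area / EEM area x 100) and FT/Ca/NC areas; contour quantities use the
shoelace formula, mask quantities pixel counts times squared pixel size.
Lumen areas are computed but never compared across sources: a decompressed
section's lumen is not comparable to a pressurized one, so the quantitative
table deliberately omits it.

The statistical battery follows the conventions of method-comparison
studies:

* **Bland-Altman**: mean difference (fixed direction histology minus
  classifier, so negative bias = classifier overestimates), sample SD of
  differences, limits of agreement at 1.96 SD.
* **Lin's concordance correlation coefficient (CCC)** with population
  (1/n) moments, penalizing both scatter and location/scale shift; its 95%
  CI uses the Fisher z-transform with Lin's asymptotic standard error.
  `|CCC| <= |r|` always (Lin's inequality) and `CCC(x, x) = 1`.
* **Mann-Whitney U** defined as the count of pairs `a_i > b_j` plus half
  the ties; exact permutation enumeration of the group assignment when
  either sample has at most 8 observations (ties handled exactly), the
  tie-corrected normal approximation with continuity correction otherwise.
* a **Kolmogorov-Smirnov gate** (each group against a fitted normal, alpha
  = 0.05) that routes a two-group comparison to Student's t-test or to the
  rank test, recording which branch ran.
* **Pearson correlation** for the relation between per-frame plaque-area
  error and plaque burden.

Significance is two-sided at 0.05 throughout; no multiplicity correction is
applied, matching the analysis the pipeline mirrors.

## Qualitative agreement

Plaque-level overlap reports the share of histology-defined plaque that the
classifier also labels plaque, plus the non-overlap in each direction.
Composition agreement has two granularities, both using histology as the
reference:

* **Region level**: each connected component of one tissue class in the
  warped histology (an ROI, 8-connected by default, minimum area 0.01 mm²
  to suppress warp speckle) contributes one count to the cell (histology
  class, predominant classifier class inside the ROI). Predominance ties
  break by the fixed priority Ca > NC > FT, mirroring the histological
  precedence of calcium over necrotic core. An ROI whose pixels carry no
  classifier tissue at all is tallied *missed* when it lies mostly outside
  the classifier's EEM border, and *unclassified* otherwise — the source
  description never defines this case, so the package surfaces it
  separately instead of folding it into a class.
* **Area level**: cell (h, m) accumulates the area labelled h by histology
  and m by the classifier; histology tissue outside the classifier EEM
  accumulates in the missed account (tissue the modality could not see,
  e.g. beyond OCT's penetration), tissue inside the EEM left unlabeled in
  the unclassified account. Matrix mass + unclassified + missed equals the
  warped plaque area — a conservation identity the tests enforce.

From either matrix: per-class sensitivity (diagonal over row sum),
precision (diagonal over column sum), F-score (harmonic mean), and overall
accuracy (100 x trace / total). Overall sensitivity/precision/F are
row-sum-weighted averages of the per-class values; under that weighting,
overall weighted sensitivity is algebraically identical to accuracy/100.
The classifier "lipid" output class is remapped to NC at load time,
reflecting the assumption that detected lipid corresponds to histological
necrotic core.

## Macrophage-rich regions

When a CD68 immunostain mask accompanies a histology frame, a plaque pixel
counts as macrophage-rich if the CD68-positive fraction within a sliding
circular window (clipped to the plaque) reaches 40%. The neighbourhood over
which "concentration" is measured is not defined by the original
description; this package declares a circular window of default radius
0.1 mm. Analysis covers the entire plaque, not only fibrous caps. Raising
the threshold never grows the rich region (a tested monotonicity), and a
sub-pixel window degenerates to the raw positive mask.

## The synthetic generator

No cadaveric data accompany the method, so the generator is the package's
ground-truth source and is itself first-class, tested code. A frame is:

* a star-shaped lumen $r(\theta) = r_0 (1 + \sum_k a_k \cos(k\theta +
  \phi_k))$ with low-order harmonics ($k = 2, 3$), base radius drawn from
  1.0–1.5 mm;
* an EEM as the normal offset of the lumen by a smoothly varying wall
  thickness (0.6–1.2 mm base, 25% cosine variation), giving EEM areas
  around 10–17 mm² and plaque burden near 60% — a mid-sized diseased
  coronary segment;
* up to two Ca and two NC inclusions: ellipses anchored at (arc length,
  depth) positions but drawn in physical coordinates, so each analytic area
  is exactly $\pi a b$; placement rejects overlaps (calcium takes precedence
  where collisions would occur, as in histological annotation convention)
  and errors after bounded retries if an inclusion cannot fit.

Histology degradation collapses the lumen radially (default shrink 0.85,
i.e. a 28% lumen area loss — sections shrink visibly but the wall largely
keeps its depth structure), optionally rescales globally, applies a smooth
monotone circumferential distortion (default amplitude 0.02) plus a random
rotation, and resamples at the histology pixel size (7.5 µm vs 15 µm for
imaging). Labels are carried along the known depth-preserving transport, so
the warp's ideal output is known exactly, and landmark pairs are emitted at
true correspondences — the piecewise-linear landmark map then approximates
the smooth distortion the way real expert landmarks would.

The classifier simulator relabels *regions* according to a row-stochastic
misclassification matrix: every inclusion is one region, and the contiguous
FT background is split into angular sectors (16 by default) so that "region"
has a defined granularity — classifiers err on local patches, not globally.
It can jitter inclusion boundaries (Gaussian displacement), offset the EEM
to inject an exact area bias (solved by root-finding on the offset polygon
area), and in OCT mode truncate the EEM at a configurable depth while
relabelling tissue beyond the attenuation depth as NC — emulating the
penetration loss that makes deep tissue read as necrotic core.

Randomness is one stream per master seed, split per frame by counter, so
cohorts are reproducible regardless of generation order and byte-identical
across runs.

What the generator does *not* emulate: ultrasound/OCT texture, NIRS
chemograms, annotation error in the landmarks themselves, and the
histology-processing artifacts (folds, tears, differential shrinkage of
tissue types). Passing tests therefore demonstrate the pipeline's
correctness and its behaviour under controlled error modes, not the
classifiers' real-world performance.

## Numerical choices and degenerate inputs

* Coordinates are 0-based pixel indices, row-major, y down; a pixel's label
  covers its full unit square, and polygon areas use the shoelace formula.
* Contours are normalized counter-clockwise at construction with the start
  vertex preserved (landmark arc lengths refer to it); degenerate
  (zero-area) and self-intersecting polygons are rejected.
* Nearest-point ties on equidistant boundary segments resolve toward the
  smaller arc length — reproducibility over elegance.
* The per-pixel nearest-point kernel uses a nearest-vertex pruning pass and
  reports the inside/outside side from the cross product at the nearest
  edge; the generic point-in-polygon test (used for validation and small
  queries) is exact even-odd ray casting.
* Constant vectors make CCC undefined (error); one constant vector yields a
  degenerate CCC with a collapsed CI. Empty histology plaque makes the
  overlap proportion undefined (error). Empty confusion matrices error;
  classes absent from the reference are excluded from weighted averages.

## Problem sizes in the test-suite and acceptance script

The suites run the pipeline at sizes chosen for a laptop-class single CPU:
identity cohorts of 8 frames at 15 µm pixels, conservation checks at 512²
imaging grids, and a 50-frame recovery cohort at 12 µm/5 µm pixels with
four fixed-size Ca and NC inclusions per frame and misclassification rates
of 0.05 — sizes at which the binomial sampling error of a recovered matrix
cell (~0.015) sits well inside the ±0.03 acceptance band while the
nearest-neighbour discretization bias stays below ~1% of a row. The
published confusion tables are recomputed exactly as printed.

## Known limitations

* Histology tissue shrinkage is emulated and inverted only in its
  lumen-collapse component; a true global scale change violates the
  depth-preservation assumption and is deliberately left uncorrected, as in
  the method itself.
* The warp is not elastic/diffeomorphic registration; landmark quality
  bounds circumferential accuracy.
* Region-level ROIs are defined on the *warped* histology; defining them on
  native histology before warping could split or merge components
  differently at boundaries.
* The overall weighted precision and F-score of one published OCT table do
  not reproduce from its printed cells under row-sum weighting (the
  weighting actually used there is indeterminate); the package reports
  row-sum-weighted values and documents the discrepancy rather than
  matching those four cells.
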