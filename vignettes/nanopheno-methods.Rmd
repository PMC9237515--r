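---
title: "Models and methods behind nanopheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanopheno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nanopheno connects two measurement worlds around one biological
question — which cells in a heterogeneous culture are stem-like, and
what do they do when cultured clonally. On the imaging side it turns
multi-channel fluorescence of nanopen microfluidic chips into per-cell
marker levels and growth trajectories; on the expression side it gates
single-cell RNA-seq profiles on the same marker vocabulary and scores
differentiation potency from network entropy. This vignette explains
the models, the defaults, and the design choices that were genuinely
open.

## The chip and its imaging model

A chip is a grid of isolated nanopens, imaged as a set of fields of
view (FOVs) in a brightfield channel (OEP) and several fluorescence
channels (DAPI, FITC, TRED, CY5). Every pen has a fixed rectangular
region of interest (ROI) so that pens can be compared across
timepoints and channels. Coordinates are 0-based `(row, col)` pixels
and ROIs are half-open rectangles `[r0, r1) × [c0, c1)`; half-open
disjoint rectangles make containment tests unambiguous, so a detected
center belongs to at most one pen with no tie-breaking needed in
practice.

**Registration.** Images drift by small translations between captures.
`register_fov()` searches integer offsets within ±20 px (configurable)
for the translation that maximizes intensity at the layout's fiducial
feature points, summed over a 3×3 window per point. Two failure modes
are distinguished: a flat score surface (featureless image — nothing to
register on, detected as the best score failing to dominate the median
by 20 %) and a best match on the search boundary (true offset beyond
the admissible range). Only integer-pixel translation is modeled;
rotation and scale drift are out of scope, which matches chips whose
stage repositioning error is translational.

**Detection.** Cells appear as bright, near-circular bodies in OEP.
`hough_circles()` is a classic circular Hough transform: pixels whose
gradient magnitude exceeds a relative threshold (default 25 % of the
image maximum) vote for centers at every integer offset on circles of
each candidate radius (default 3–15 px, capped by the pen size);
accumulator scores are normalized by circumference so a fully supported
circle scores ~1, and candidates above 0.5 survive. Duplicate peaks are
removed by greedy non-maximum suppression with a physical separation
rule: two genuine cells cannot have centers closer than about the sum of
their radii, so a candidate within `0.7 × (r₁ + r₂)` of a kept circle
(floored by `min_sep`) is suppressed. The 0.7 factor keeps tangent
cells separable while removing the radius-confusion duplicates a single
disk generates.

Two filters then remove false positives, in order: candidates outside
every pen ROI are discarded, and candidates must reach a peak intensity
`T` within a `(2h+1)²` neighborhood of the center (defaults `T` =
65,535, `h` = 2 px). `T` defaults to the 16-bit saturation ceiling:
on-chip cells under OEP reliably saturate the sensor, so *reaching*
saturation separates cells from bright debris. Strictly exceeding
65,535 is impossible for 16-bit data, so the criterion is implemented
as `peak ≥ T`; whether the original acquisition software read a single
pixel or a neighborhood maximum is not knowable from outside, so the
neighborhood half-width is exposed as a parameter (`h = 0` reproduces a
single-pixel read).

**Quantification.** Per cell and channel, `raw` is the mean intensity
over the detected disk. Two normalization denominators are provided
because both appear in practice: the default `fov_background` divides
by the mean intensity over all *cell-free* pen ROIs of the FOV — a
ratio that cancels global illumination differences between FOVs and
chips, which is what makes multi-chip comparison possible — while
`own_roi` divides by the cell's own pen ROI mean. The default is
`fov_background` because cross-FOV and cross-chip comparability is the
property the downstream binning relies on; `own_roi` remains available
for FOVs with no empty pen (the package raises an explicit error
telling you so rather than silently switching).

## Pseudo-sorting: from intensities to subtypes

The mammary stem-cell marker vocabulary is binary per channel — Epcam
−/+, Cd49f low/high, Sca-1 low/high — and four patterns name the
subpopulations of interest:

| Subtype | Epcam | Cd49f | Sca-1 |
|---------|-------|-------|-------|
| P5      | −     | high  | low   |
| P6      | −     | low   | low   |
| P7      | +     | high  | low   |
| P8      | +     | high  | high  |

The other four patterns map to UNASSIGNED; unassigned cells are kept in
all outputs because they still occupy pens and must be accounted for in
growth stratification.

Rather than a hand-picked intensity threshold per channel,
`fit_level_model()` clusters each channel's normalized intensities with
K-means at k = 2 and labels the cluster with the larger center HIGH (or
POS for Epcam — the vocabulary differs, the computation does not). k is
fixed at 2 because the label vocabulary is strictly binary; a finer
model would have no place to put its extra levels. The 1-D k = 2
problem is solved exactly — the optimal partition of points on a line
is a threshold split, found by scanning the sorted split points — so
the fit is deterministic, permutation-invariant, and equal to the best
restart any stochastic K-means could find; the conventional seed and
restart count are recorded in the model for provenance but are not
needed by the solver. Clustering is per chip: normalization makes
intensities comparable across chips, but pooling chips before
clustering would let a chip with a skewed subtype mix shift the other
chips' boundaries, so the more conservative per-chip scope is the
default.

## Growth kinetics

Tracking is pen-level, not cell-level: pens are identity-preserving
containers, so counts per pen per timepoint are sufficient for the
quantity of interest, the proliferation ratio `final / t0` (computed
for pens with at least one cell at t0; a pen with cells appearing only
later is flagged and excluded). Classification is a strict three-way
split at ratio 1 — PROLIFERATED above, APOPTOTIC below, NO_RESPONSE at
exactly 1 — with an optional dead-band for callers who want "no
response" to absorb small fluctuations; the default dead-band is 0
because no principled margin is available a priori.

Summaries stratify by subtype (only pens whose t0 occupants share one
subtype: attributing a mixed pen's growth to one subtype is undefined)
and by t0 cell count (bins 1–4, the chip-loading design). Capture rates
are percents of occupied pens containing a target subtype, rounded to
one decimal; the relative improvement between two capture rates is, by
default, computed *on the one-decimal-rounded rates* and rounded again.
This rounding-then-ratio convention exists so that improvements quoted
from reported rates are exactly reproducible from those rates
(14.8 → 26.7 gives 80.4 %); the unrounded variant is available via
`rounded = FALSE` (it gives 80.5 % on the same pen counts).

## scRNA-seq QC and marker gating

`qc_filter()` applies the standard two-step filter: features detected
in fewer than 15 cells are dropped first (the object-construction
filter), then cells are kept when mitochondrial percent < 20, detected
features > 2,000, and total counts < 45,000 — all strict inequalities,
applied to statistics computed on the feature-filtered matrix. The
feature-count ceiling sometimes quoted for multiplets (45,000
*features*) exceeds any transcriptome, so 45,000 is interpreted as the
total-molecule (nCount) ceiling and 2,000 as the feature floor — the
only coherent reading. Mitochondrial genes are recognized by the mouse
`mt-` symbol prefix, case-insensitively and configurably.

"Scaled expression" is realized as depth-normalization to 10,000
counts, `log1p`, then per-gene z-scoring across cells; the 0.3 marker
gate presupposes a continuous scaled axis with a bimodal distribution
whose upper mode starts near 0.3, and the z-scored log-normalized axis
is the conventional choice with that property. The scaling tag is
recorded in `gate_result` outputs so alternative scalings can be
compared. Cell-cycle scoring and regression — a published-package step
between normalization and gating in full workflows — is deliberately
not reproduced here; gating operates on the scaled matrix directly.

## Potency by network entropy

Differentiation progressively silences pathways unrelated to a cell's
final function, so transcriptional *promiscuity* — breadth of activity
across the interactome — decreases as cells differentiate. The entropy
rate of a random walk makes that notion quantitative. With expression
`x` superimposed on an undirected interaction network as mass-action
edge weights `w_ij = x_i x_j`:

- transition probabilities: `p_ij = w_ij / Σ_k w_ik`
- stationary distribution: `π_i ∝ Σ_j w_ij` (exact, by detailed
  balance on a symmetric weight)
- entropy rate (nats): `SR = − Σ_i π_i Σ_j p_ij log p_ij`

The normalized score divides `SR` by `log λ_max` of the unweighted
adjacency matrix — the maximal entropy rate any walk on that graph can
attain — making scores lie in [0, 1] and comparable across networks of
different size. A single-edge graph has `log λ_max = 0`; its walk is
deterministic (`SR = 0`) and the normalized score is reported as `NA`
with a warning rather than an error, so the raw rate remains available.

Pipeline order is: kNN smoothing of *raw* counts (k = 8; each cell's
smoothed profile is the sum of raw counts over itself and its k nearest
neighbors in log1p depth-normalized Euclidean space — summation keeps
the output integer-valued and count-natured), then renormalization to
10,000 counts, then per-cell entropy. Smoothing the raw counts and
renormalizing afterwards (rather than smoothing normalized values)
preserves the count statistics that motivate smoothing in the first
place: dropout zeros. Whether the original smoothing included the cell
itself or weighted its neighbors is not documented anywhere we could
find; including the cell with unit weight is the choice here, and k is
exposed. Zero expression on a network node would disconnect the walk,
so zeros are lifted by a pseudo-offset, default `1e-6 ×` the cell's
mean nonzero network-restricted value — small enough not to move any
score at double precision, large enough to keep transition rows
stochastic.

Gene–score associations use *unsmoothed* depth-normalized counts
(smoothing would leak neighborhood structure into the correlations):
Spearman rho per gene with the asymptotic t approximation for p-values
and Benjamini–Hochberg adjustment across tested genes; constant genes
have undefined rank correlation and are excluded from the adjustment's
test count rather than imputed.

## What the generators emulate — and what they do not

`simulate_chip()` renders pen grids with per-FOV background levels
(Gaussian between-FOV variation), a multiplicative log-normal
chip-illumination factor, per-pixel Gaussian noise, fiducial crosses,
and cells as hard disks with a Gaussian-tapered edge (σ = 1 px) —
pure hard disks would hand the Hough transform unrealistically crisp
gradients. OEP disks plateau at the saturation ceiling exactly
(saturation clips the sensor after optics, so the plateau is exact
while edges taper); fluorescence plateaus are set multiplicatively so
a cell's normalized intensity targets ~3.0 for HIGH/POS levels and
~1.3 for LOW/NEG, with optional per-cell log-normal jitter
(`intensity_cv`). Growth follows a per-subtype Poisson branching
process whose per-step multiplier compounds to the subtype's expected
proliferation ratio, truncated at a per-pen crowding capacity of 9
rendered cells. The physical chip design of 22 FOVs over 3,500 pens is
not an even grid; the simulator uses a regular grid (default 22 × 160)
and treats the 3,500 as a documentation constant, not an enforced
invariant.

Not modeled: point-spread functions, spectral bleed-through between
fluorophores, cell morphology beyond disks, cell migration between
pens, or identity tracking across timepoints. Passing the image tests
therefore demonstrates correctness of the geometry, thresholding,
normalization and binning logic — not robustness to optical artifacts
real chips can show.

`simulate_counts()` plants subtypes by the marker-pattern table
(positive markers contribute a fixed raw count so gate ground truth is
exact; the `OTHER` class uses a Sca-1-only pattern, which gates to
UNASSIGNED, so every planted class is recoverable), routes a per-cell
mitochondrial fraction to `mt-` genes, and draws the remaining library
multinomially from a cluster profile — either a shared log-normal
background or, for potency experiments, a "promiscuous" (all genes
active) versus "specialized" (few genes active) design. Real data's
gene–gene correlation structure, batch effects and ambient RNA are not
emulated. `simulate_ppi()` produces a connected scale-free toy graph;
it is synthetic and carries no biological interaction information — the
real interactome is always a user input.

## Numerical choices and problem sizes

All simulator randomness derives from a single integer seed with
save/restore of the RNG state, so identical specs give bit-identical
images and matrices. The test and acceptance suites run at desk scale:
synthetic chips of 2–4 FOVs with 16–36 pens each (a few hundred planted
cells), count matrices of 40–500 cells over 60–300 genes, interactomes
of ≤ 100 nodes, and 100-replicate loops for the stochastic properties;
these sizes estimate every quantity the package reports while keeping
a full run in minutes on one core. The brute-force entropy oracle
(dense transition matrix, eigen-decomposed stationary distribution) is
kept in the test code, deliberately separate from the production path,
and agrees with it to ≈ 1e-15 on random connected graphs of up to 8
nodes.

## Known limitations

- Registration is translation-only and integer-pixel.
- The Hough detector assumes near-circular cells and reports integer
  centers and radii; sub-pixel refinement is not attempted.
- Pseudo-binning assumes each channel's intensity distribution is
  two-moded; a chip containing only one level in some channel is
  reported as a degenerate-channel error instead of being silently
  split.
- Entropy scores depend on the supplied interactome; scores are
  comparable across cells within one network but not across different
  networks except through the λ_max normalization.
- The QC headline on public data (survivor counts of a deposited
  accession) requires downloading that accession; the package validates
  the filter logic against an independent per-cell predicate on
  constructed matrices instead.
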