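---
title: "platecyto methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{platecyto methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platecyto)
```

## Scope

`platecyto` is an open re-implementation of the analysis layer of a
plate-based image cytometer as used for DNA-damage-response (DDR) screens:
per-nucleus quantification of immunofluorescence from multi-channel well
images, control-anchored gating, DNA-content cell-cycle analysis,
multiplexed marker statistics, and dual-stain viability with dose–response
fitting. Commercial instruments perform these steps in closed software;
this package makes every step explicit, parameterised and testable.

Because real instrument images from such screens are rarely deposited, the
package ships a synthetic plate generator with an exact per-cell ground
truth ledger. Every downstream claim in the test suite is a *recovery*
statement — the pipeline recovers what the generator put in — never a claim
about the biology of any real cell line.

## The synthetic well model

A well is a set of single-channel images (Hoechst, up to three marker
channels, and optionally PI and calcein) sharing one cell population.

**Nuclei.** Each nucleus is an isotropic Gaussian spot, `sigma = radius/2`,
truncated at `3*sigma`, whose discrete kernel is normalised to sum to one.
The rendered spot therefore integrates *exactly* to the cell's ledger
signal, which is what makes 1%-level recovery tests meaningful. Radii are
normal with configurable mean (default 8 px) and CV (default 0.1).

**Placement.** Centers are rejection-sampled with two hard-core
constraints: a floor of 2.2 × mean radius (nuclei never overlap), and
3 × the larger radius of any pair, which keeps the truncation disks of the
two rendered spots disjoint on either side of their Voronoi bisector. The
second constraint is what guarantees that a pixel-partition measurement can
recover each cell's integrated signal exactly; with only the first, the
dim skirts of adjacent spots overlap and per-cell errors of several percent
are unavoidable. Clumped or touching nuclei are deliberately *not*
simulated: the generator validates the measurement chain, not the hardest
segmentation regime.

**DNA content.** A G0/G1 cell carries `g1_dna_intensity` (default 20 000
a.u.) of integrated Hoechst signal, a G2/M cell twice that, and an S-phase
cell a uniform draw between the two — the classic 2N/4N histogram with an
S bridge. All DNA signals get multiplicative Gaussian jitter of CV
`dna_cv` (default 0.05, a typical instrument-grade CV for DNA stains).

**Markers.** Each marker channel is a two-component log-normal mixture:
positives at `positive_mean` (default 20 000 a.u.), negatives at
`negative_mean` (default 500 a.u.), common log-sd `lognormal_sigma`
(default 0.4). At the defaults the components are separated by ~9 log-sd,
i.e. the gating problem is easy by construction; tests that claim ±3-point
recovery of positive fractions hold under this separation and say nothing
about overlapping mixtures.

**Viability.** Dead cells (probability `dead_fraction`) carry PI signal
and zero calcein; live cells the reverse. Dead cells keep their Hoechst
signal, so "total cells" counted on the Hoechst channel includes them —
this matches the subtraction-mode viability arithmetic below.

**Noise.** Constant background (default 100 a.u.) plus additive Gaussian
pixel noise (default sd 5 a.u.), applied after optional linear
bleed-through mixing of the noiseless channels. Poisson shot noise is
omitted: the instrument noise model is unknown, and an additive Gaussian
suffices for recovery testing. Images written to disk are 16-bit TIFFs,
one file per well and channel, with intensities interpreted as 16-bit
counts.

**Determinism.** Everything derives from one seed; a dose plate derives
per-well seeds as `master XOR hash(well_id)` so each well is reproducible
regardless of simulation order.

## Segmentation and per-cell quantification

`segment_nuclei()` is a deliberately standard chain: Gaussian smoothing
(sigma 2 px) → global Otsu threshold → hole filling → distance-transform
watershed (optional, for touching objects) → area filter → consecutive
relabeling. The commercial algorithm it replaces is undisclosed, so the
goal is a transparent baseline that provably recovers the generator's
cells, not a state-of-the-art segmenter.

Two robustness details matter in practice:

* The Otsu threshold is floored at `median + 6 * MAD` of the smoothed
  image. Otsu always splits an image in two, so a well with *no* cells
  would otherwise be shattered into hundreds of noise speckles; the floor
  makes "no signal" yield zero objects, which the dose–response module
  relies on at fully suppressive drug concentrations.
* Thresholding operates on the min–max normalised image, making the mask
  invariant to constant offsets.

`apply_mask()` reports, per nucleus and channel, the background-corrected
integrated intensity (the quantity gated on throughout) and the mean.
Background defaults to the median of out-of-mask pixels per channel.
Integration uses a *Voronoi-limited expansion* of each labelled nucleus
(default 12 px): a global threshold necessarily cuts a Gaussian spot at
some isophote and loses its dim skirt — about 30% of the integrated
signal at our spot shape — so the aperture is grown into the background,
with competing cells meeting at their bisector so nothing is counted
twice. Centroids and areas always come from the unexpanded mask.
Negative corrected intensities are kept, not clipped.

## Gating

Gates are one-dimensional thresholds on integrated intensity, placed at an
empirical quantile (default q = 0.99) of the pooled secondary-antibody-only
control (CT) cells, i.e. a nominal 1% false-positive rate on
background-like cells. The instrument operator draws such gates by hand on
2D dot plots; a CT quantile is the reproducible, monotone equivalent of
"just above the background cloud". Positivity is strictly greater-than, so
a degenerate (all-equal) control distribution gates nothing — the right
semantics for a control.

Consequences worth knowing:

* Estimated percent positive carries a predictable `+100*(1-q)`-point
  false-positive floor from the negative population.
* Raising a threshold can only lower percent positive (used as a property
  test).
* Quadrant analysis assigns each cell to exactly one joint combination of
  2–3 gates; fractions partition the population exactly and marginals
  reproduce the per-marker statistics by construction.
* The channel-overlap check applies every *other* marker's gate to
  single-stained control tables; its default tolerance is the gates'
  nominal false-positive rate plus 2 percentage points.

Replicate comparison is a two-sided pooled-variance Student's t-test with
significance called at p < 0.01. Two constant groups with equal means give
p = 1; the symmetric degenerate case (constant but different) gives p = 0.

## Cell-cycle analysis

`fit_dna_histogram()` bins the per-nucleus Hoechst integrated intensities
(default 256 bins), smooths the counts with a small Gaussian kernel
(sd 2 bins), and anchors the fit on two peaks:

* **G1 peak** — the *leftmost* mode with at least 10% of the maximal
  smoothed count. The tallest mode would be wrong whenever a drug arrests
  most cells in G2/M (the 4N peak then dominates), which is precisely the
  situation the analysis is for.
* **G2 peak** — the strongest local mode between 1.6 and 2.4 × G1,
  falling back to exactly 2 × G1 (flagged) when none exists. Fits whose
  G2/G1 ratio leaves [1.8, 2.2] are flagged rather than rejected.

Phase windows are `peak * (1 ± 0.15)`; per-cell calls are a closed-window
lookup (below G1 window: sub-G1; between windows: S; above G2 window:
>4N). Window calling is used instead of mixture deconvolution
(Dean–Jett–Fox/Watson is an explicit non-goal) because it matches the
box-gate output of plate cytometers and is deterministic.

**S-bridge correction.** Window *counting* is structurally biased: the
S-phase plateau runs underneath both peak windows, so plain counts
overstate G0/G1 and G2/M and can understate S by >10 points when S is
large. The reported *fractions* therefore estimate the plateau density
from the inter-window gap and reallocate the implied S mass out of the two
windows (mass-conserving, so fractions still sum to 1 exactly; per-cell
labels are untouched). With the correction, recovery errors on the stock
scenarios drop from up to ~10 points to under ~2 points. The correction
assumes an approximately flat bridge — its accuracy degrades for strongly
early- or late-S-weighted populations — and can be disabled
(`s_bridge_correction = FALSE`).

Fractions are scale-invariant: multiplying all intensities by a constant
changes peaks and windows proportionally and no call.

## Viability and dose–response

Dead cells are PI-gate positives. Live cells are either calcein-gate
positives (cells positive for both stains count as dead — PI dominance —
and are tallied in a QC field) or, in subtraction mode, total minus dead,
where live + dead = total holds exactly. Subtraction mode is the default
because cytoplasmic calcein contouring fails for many adherent lines.
Growth is `100 * total / mean(untreated totals)`.

The dose–response model is a four-parameter logistic on log10
concentration, fitted by multi-start Levenberg–Marquardt (`minpack.lm`)
with top ≤ 110, bottom ≥ −10 and a free Hill slope. Zero-concentration
wells anchor the 100% normalisation but are excluded from the log-scale
fit. The IC50 is the concentration where the *fitted curve* crosses 50%
growth — not the curve midpoint, which differs whenever inhibition
saturates below 100%. Curves that never reach 50% in the tested range are
reported as a bound (`"> cmax"`) and flagged, never extrapolated into a
number.

Mechanism classification is a step function of the percent dead evaluated
at a reference concentration: <30 primarily cytostatic, 30–50
cytostatic ≥ cytotoxic, 50–70 cytostatic ≤ cytotoxic, ≥70 mainly
cytotoxic. Lower bin bounds are closed (30, 50 and 70 belong to the upper
bin) — the published bins use strict inequalities on both sides and leave
the boundaries undefined, so a convention had to be fixed. The reference
defaults to the tested concentration nearest the fitted IC50 (on the log
scale) and can be set to a fixed concentration instead; which choice an
instrument report uses is generally not stated, so both are exposed.

## Problem sizes and numerical choices

The test-suite and acceptance problem sizes are chosen so each statistical
tolerance is comfortably inside its sampling error: 200 cells per well for
image-level recovery (512–640 px square wells), 2 000 cells for gating
recovery (±3 points), 5 000 for cell-cycle fractions (±5 points), 10 000
for quadrant independence (±2 points on the double-positive fraction), and
a 24-well plate (7 half-log concentrations × 3 replicates + untreated) for
end-to-end IC50 recovery (±20% at 10% count CV; ±1% noiseless).
Degenerate inputs are handled explicitly rather than by tolerance: empty
wells yield empty tables, constant images yield zero labels, degenerate
control distributions gate nothing, and zero untreated denominators are
errors, not infinities.

## Known limitations

* Nuclei are isolated by construction; clustered growth, debris and foci
  substructure are out of scope, so passing tests do not certify
  performance on confluent or clumped real wells.
* Gates are 1D thresholds; correlated marker backgrounds or 2D gate
  geometries are not modelled beyond the linear bleed-through check.
* The S-bridge correction assumes a flat bridge.
* Marker statuses are drawn independently of phase and of each other
  unless a scenario couples them, so biological co-occurrence structure is
  absent from the defaults.
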