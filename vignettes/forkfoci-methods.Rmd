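---
title: "Quantifying protein association at replication foci from SMLM localization data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein association at replication foci from SMLM localization data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forkfoci)
```

## The measurement problem

Single-molecule localization microscopy (SMLM) resolves replication and
DNA-repair foci in nuclei at a few tens of nanometers, an order of
magnitude below the diffraction limit. A multicolor experiment yields one
localization table per channel — fitted molecule positions in nanometers —
for a nucleus containing on the order of a hundred spatially distinct
nascent-DNA (naDNA) replication foci per optical slice, plus protein or
DNA-damage markers whose immunolabelled signal appears as a single punctum
overlapping a focus.

The scientific questions this package answers are organized in three
tiers:

1. **Does a marker associate with replication foci more than chance would
   produce?** The nucleus is dense: hundreds of clusters in each channel
   guarantee many overlaps by chance alone, and the chance level varies
   with nuclear size and labeling density from cell to cell.
2. **When two markers both respond, do they occupy the same foci or do
   they exclude one another?**
3. **Within a jointly occupied focus, are the two proteins intimately
   associated (potentially interacting) or spatially separated on the
   DNA?**

## Tier 1: Monte Carlo-normalized colocalization

Each channel is rendered as a 2D count histogram with a 20 nm pixel pitch
(`render`), and clusters are segmented inside a nuclear region of interest
by Otsu thresholding of the in-ROI pixel counts followed by 8-connected
component labeling (`segment_clusters`). The observed overlap between two
channels — either the number of channel-1 foci sharing at least one pixel
with a channel-2 cluster (for sparse punctate markers) or the total shared
area (for accumulating markers) — is divided by the mean overlap across 20
Monte Carlo simulations in which every channel-2 cluster is rigidly
translated, shape preserved, to an independent uniform position inside the
ROI (`randomize_clusters`, `coloc_factor`).

The resulting *colocalization factor* is 1 when observed associations are
indistinguishable from random placement, 2 when there are twice as many
as random, and so on. Because the null is simulated per nucleus from that
nucleus's own clusters and mask, the factor is self-normalizing across
nuclei that differ in size, focus count, and labeling density. Condition
means are compared by the difference of per-nucleus factor means against
the control condition, with a two-sided Welch t-test
(`summarize_condition`); a decrease in association therefore appears as a
negative change. No multiple-testing correction is applied anywhere in
the pipeline; significance annotations (ns/*/**/***/****) are rendering
conventions only.

Numerical conventions worth stating:

* pixels are half-open bins, `floor((x - x0)/pitch)`, so a localization
  exactly on an edge belongs to the higher pixel;
* foreground is *strictly above* the Otsu threshold, ties to background,
  which makes the two-valued degenerate case deterministic;
* clusters smaller than `min_area_px = 2` pixels are discarded
  (suppresses single stray localizations);
* cluster centers of mass are localization-count-weighted centroids
  (binary centroids available by flag);
* random redistribution uses rejection sampling with all cluster pixels
  required inside the ROI (attempt cap 10,000), translations only — no
  rotation;
* a null with mean zero flags the factor as NaN with a warning rather
  than dividing silently.

## Tier 2: three-color co-occupancy

Among naDNA foci overlapping at least one of two markers A and B (the same
at-least-one-shared-pixel rule as tier 1), `classify_foci` records which
markers each focus carries; foci carrying neither are counted separately
as unaffected and excluded, which focuses the readout on the engaged
subpopulation. `cooccupancy_fractions` reports the fractions positive for
A only, B only, or both — pooled (fractions sum to exactly 1) or as
per-nucleus means with their s.e.m. Exclusionary recruitment of two
markers appears as a "both" fraction near the chance level; dependence
appears as a "both" fraction approaching one of the marginals.

## Tier 3: intrafocus architecture

For each focus carrying both markers, `pair_distances` measures the
Euclidean distance between the count-weighted centers of mass of the
nearest A–B cluster pair inside that focus. The histogram of these
distances (20 nm bins, one rendering pixel) is fitted by least squares
with a single free Gaussian (`fit_association`).

The interpretive scale comes from a dual-label calibration: one protein
species labeled simultaneously in two colors targets the same underlying
structure, and its center-of-mass distance histogram is well approximated
by a Gaussian centered near 135 nm with a width at half height of 70–80
nm — the offset floor set by antibody linkage geometry and localization
error, not by true separation. Accordingly:

* a single-Gaussian center within 135 ± 37.5 nm is classified
  **intimate**;
* a center beyond 180 nm is **distal** — same focus, spatially separated;
* the interval (172.5, 180] nm is not covered by either rule; rather than
  force a side, `classify_association` reports **indeterminate** (the
  same label is used for centers below the calibration window);
* histograms not described by a single Gaussian are fitted with a
  **double** model: component 1 fixed at the calibration standard
  (center 135 nm, FWHM 75 nm) with only its area free — first alone, then
  a second fully free Gaussian for the remaining distances, then a joint
  refinement with component 1 still fixed. The double model is preferred
  only when it improves the AIC by at least 6 (the qualitative criterion
  "not easily described by a single Gaussian" needs a quantitative
  tie-break; 6 is the conventional strong-evidence threshold). When the
  calibration standard itself is being measured, the single model is
  forced (`model = "single"`) so the reported center is an estimate, not
  the fixed component echoed back.

`render_distribution_map` turns a fitted curve into the contoured 2D map
used for display: each distance column holds a perpendicular Gaussian
profile whose integrated area equals the fitted intensity at that
distance, so column sums reproduce the 1D curve exactly. The
perpendicular FWHM defaults to each component's own fitted FWHM; this
output is cosmetic and nothing downstream consumes it.

## Chromatic registration

Multicolor SMLM requires mapping each channel onto a reference channel.
`fit_map` fits bivariate polynomial surfaces (degree 3 by default, full
cross terms) to fiducial bead pairs matched by mutual nearest neighbors
within 500 nm (`match_beads`; ambiguous beads are discarded). Coordinates
are centered and scaled internally, so degree-3 monomials on a 40 µm
field stay well conditioned. With at least 20 pairs, a deterministic 20%
split (every fifth pair) is held out to report an honest residual; the
returned coefficients are then refit on all pairs. The map is applied to
localization coordinates (`apply_map`) rather than pixel images — exact
and resolution-independent, with every non-coordinate field preserved.
The registration residual of a well-spread bead field is around 10 nm,
comparable to the per-channel localization precision.

## What the synthetic generator emulates — and what it does not

`generate_nucleus` plants ground truth for every downstream stage: an
elliptical nucleus (semi-axes 5 × 4 µm) with 100 naDNA foci at least
300 nm apart (spatially distinct at the 20 nm rendering pitch), marker
puncta assigned to foci by configurable co-occupancy fractions, radial
marker-to-focus offsets drawn from a Gaussian truncated at zero with
uniform angle, Poisson localization counts per punctum (blinking
multiplicity without a temporal model — the analysis is frame-agnostic),
Gaussian localization noise per channel (defaults 8 nm in the red/blue
channels and 16 nm in the green channel), and uniform background
localizations (default 2 per µm² per channel; real non-focal background
density is not well characterized, so this is a free parameter).

Default scales: focus spread sigma 70 nm with a mean of 400 localizations
(dense nascent-DNA labeling integrated over thousands of frames), punctum
spread sigma 40 nm with a mean of 80 localizations, marker offset center
80 nm with FWHM 75 nm — small enough that a punctum overlaps its focus,
matching the observation that immunolabelled markers present as a punctum
*within* the larger naDNA focus. The dual-label calibration generator
(`generate_calibration_foci`) is separate: its radial offset defaults to
the calibration standard (center 135 nm, FWHM 75 nm), its puncta are
bright (300 localizations — accumulation-type targets), and its default
of 150 foci keeps the sampling error of a fitted width to a few
nanometers.

The generator does **not** emulate: camera frames or PSF shape (the
pipeline starts at localization tables), axial (3D) structure, spatially
varying background, focus-shape anisotropy, drift, or multiple damage
sites per focus. Passing tests on synthetic data therefore validate the
estimators — calibration of the factor's null, recovery of planted
fractions and offsets, mapping error — not the biological labeling
efficiency or antibody specificity of a real experiment.

A known artifact worth understanding: thresholding a Poisson-noisy
Gaussian spot at a low Otsu threshold fragments its periphery into small
satellite clusters. Satellites inherit their focus's position, so tier-1
factors and tier-2 fractions are essentially unbiased (verified against
planted truth), but they do inflate the raw cluster count per channel.
The null calibration also shows a small (~3%) deficit below 1 from ROI
edge effects: real clusters straddling the mask boundary are clipped,
while the null re-places those clipped shapes fully inside. Both effects
are properties of the assay itself, not of the simulation.

## Study-level orchestration and reproducibility

`run_study` executes the three tiers over multiple conditions — from
in-memory configurations or from a dataset directory written by
`generate_study` (per-nucleus CSVs, PNG masks on the 20 nm grid, JSON
manifest with every planted parameter) — and fails a nucleus loudly with
a recorded reason, aborting if more than half fail. All randomness
derives deterministically from one run seed (per-nucleus seeds are a
fixed function of condition and nucleus index), so identical inputs give
byte-identical reports. An optional blinded mode is deliberately *not*
implemented at load time; labels travel with the data and blinding is an
acquisition-time practice.

Validation scale: the bundled acceptance analysis uses 30 nuclei of ~100
foci each for the factor calibration (null and 3× planted enrichment),
150 calibration foci per seed for the distance standard, and 120-bead
fields for registration — sizes chosen to keep each check's Monte Carlo
error several times smaller than the tolerance it is judged against.

## Limitations

* Pixel-level overlap (≥ 1 shared 20 nm pixel) is the colocalization
  primitive; no sub-pixel geometry or localization-level pair
  correlation is computed.
* The count metric is focus-centric ("how many channel-1 foci are
  positive"), not pair-counting; pair counting is available by flag and
  matters when single foci host several marker clusters.
* Whether the channel with fewer or more clusters is randomized is fixed
  (channel 2 by convention) and documented rather than adaptive.
* The double-Gaussian model fixes component 1 at the calibration
  standard; if a sample's true proximal mode differs from the standard
  (different antibody geometry), the mixture areas are biased.
* The generator's nuclei are convex ellipses; real nuclear masks are
  irregular, which mainly changes the edge-clipping rate discussed above.
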