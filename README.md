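# forkfoci

Quantitative analysis of multicolor single-molecule localization
microscopy (SMLM/STORM) data for replication-fork and DNA-damage biology.

During S phase a nucleus contains on the order of a hundred spatially
distinct nascent-DNA (naDNA) replication foci per optical slice. Under
replicative stress, repair and fork-protection proteins (and direct
break labels such as TUNEL) form puncta at a subset of those foci. The
nucleus is crowded, so raw overlap counts between channels are dominated
by chance and by cell-to-cell differences in size and labeling density.
`forkfoci` implements the analysis chain that turns per-channel
localization tables into defensible association statistics:

1. **Monte Carlo-normalized colocalization.** Channels are rendered at a
   20 nm pixel pitch and segmented by Otsu thresholding inside the
   nuclear ROI. The observed two-channel overlap (count of positive
   foci, or shared area) is divided by its mean over 20 simulations in
   which one channel's clusters are rigidly redistributed uniformly
   within the ROI:

   *F* = overlap(observed) / ⟨overlap(randomized)⟩

   *F* = 1 means associations are explained by chance; *F* = 3 means
   triple the random level. Conditions are compared as differences of
   per-nucleus factor means (Welch two-sample t-test).
2. **Three-color co-occupancy.** Among foci carrying at least one of two
   markers, the fractions positive for A only, B only, or both —
   distinguishing colocalization, exclusivity, and dependence.
3. **Intrafocus architecture.** Center-of-mass distances between
   colocalized marker pairs, histogrammed at 20 nm and fitted with
   Gaussians against a dual-label calibration standard (center 135 nm,
   FWHM 70–80 nm). Single fits centered in 135 ± 37.5 nm are *intimate*;
   beyond 180 nm, *distal*; mixtures use a double model with the
   calibration component fixed.

Supporting modules: localization-table and mask I/O, fixed-pitch
rendering, polynomial chromatic registration from fiducial bead fields
(mutual-NN matching, degree-3 bivariate surfaces, held-out residuals),
and a synthetic-data generator that plants ground truth (focus
positions, co-occupancy fractions, intrafocus offsets, chromatic
distortions) so every stage is testable without microscope data.

## Worked example

A two-condition synthetic study: in the control, marker puncta are
placed uniformly at random in the nucleus (no true association); in the
treated condition, 38% of replication foci carry a marker.

```r
library(forkfoci)

conditions <- list(
  control = sim_config(cooccupancy = c(A = 0, B = 0, AB = 0),
                       random_puncta = c(A = 80, B = 80)),
  cpt     = sim_config(cooccupancy = c(A = 0.18, B = 0.12, AB = 0.08),
                       random_puncta = c(A = 40, B = 40)))

res <- run_study(conditions, n_nuclei = 6, control = "control",
                 pair = c("nadna", "A"), metric = "count", seed = 42)
print(res)
#> study_result: 12 nuclei, 0 failures; pair nadna/A metric count
#> cpt: 2.682 +/- 0.170 (n=6) vs control: 1.026 +/- 0.076 (n=6)
#>   delta 1.656 +/- 0.187, Welch t=8.872, p=4.99e-05 ****

print(res$cooccupancy$cpt)
#> co-occupancy (pooled, 293 foci): A only 47.1%, B only 33.8%, both 19.1%
```

The control condition calibrates to a factor of ~1 (its puncta really
are random), the treated condition reads ~2.7× the random level, and the
per-focus classification recovers the planted marker mixture. Single
operations are exposed directly — `render`, `segment_clusters`,
`coloc_factor`, `classify_foci`, `pair_distances`, `fit_association`,
`match_beads`/`fit_map`/`apply_map` — and `generate_study` +
`inst/scripts/run-study.R` provide an on-disk dataset workflow.

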