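---
title: "Quantifying puncta clustering and colocalization with focusq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying puncta clustering and colocalization with focusq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focusq)
```

## The measurement problem

After activation of the STING innate-immunity pathway, fluorescently tagged
ATG8-family proteins such as LC3B first appear as many small perinuclear
puncta and later coalesce into one or a few large bright foci per cell.
Three per-cell readouts capture this biology:

1. **Pearson colocalization** between the structure channel and a second
   marker channel (an immunostained autophagy receptor, ubiquitin, ...),
   computed over the pixels of each segmented cell.
2. **Structure positivity**: the fraction of individual puncta/foci whose
   mean secondary-channel intensity exceeds that of the surrounding cellular
   region by a fixed ratio.
3. **Radial dispersion**: the normalized mean intensity as a function of
   integer pixel distance from the intensity-weighted centroid of the
   signal in each cell. Clustered foci give a tall narrow peak followed by a
   sharp decline; dispersed puncta give a lower, broader profile.

All three are aggregated hierarchically: cells are summarized per imaging
site by the median, sites per well by the median, and wells per condition by
the mean and sample standard deviation (n − 1), matching the common
triplicate-well design. Medians at the two inner levels make the per-image
summaries robust to occasional mis-segmented cells; the outer mean ± SD over
wells is what error bars on a figure represent.

## Segmentation model

**Background subtraction** uses grayscale morphological opening with a disc
of radius `background_radius` (default 25 px). The opening estimates the
slowly-varying floor — anything wider than the disc survives, anything
narrower (all puncta and foci) is removed from the estimate — and the
estimate is subtracted and clipped at zero. A flat field maps to ~0 and a
spot on a constant background keeps its amplitude. Note that opening a
*noisy* flat field tracks a low quantile of the noise, so the subtracted
background retains a small positive residual (about 2–3 noise SDs); the cell
intensity threshold must sit above this residual.

**Single cells** are segmented in two steps. Foreground is the
background-subtracted primary channel above `cell_intensity_threshold`
(default 27, chosen above the post-subtraction background residual and below
the cytoplasmic level of the synthetic scenes), hole-filled, with connected
components below `cell_min_area` (300 px) discarded — small debris cannot be
a cell. The foreground is then partitioned into single cells by a watershed
on the Gaussian-blurred (`watershed_blur_sigma` = 10 px) primary image. The
watershed tolerance is deliberately high (50 intensity units): disconnected
foreground components can never be merged by a watershed, so tolerance only
controls spurious splitting of one cell whose blurred bright structures
create multiple shallow maxima. For genuinely touching cells the variant
`use_nuclear_channel_in_watershed = TRUE` blurs the primary + nuclear merge
and seeds the watershed from thresholded nuclei, so each nucleus claims one
cell.

**Puncta/foci** are found by blur-divide equalization: the
background-subtracted image is divided by a heavily blurred copy of itself
(`equalization_blur_sigma` = 25 px ≈ one cell radius, removing details
smaller than a cell), giving an image whose intensities are comparable
between dim and bright cells; a small ε = 10⁻⁶ × image max guards the
division and pixels whose blurred value falls below ε map to 0. Structure
pixels must be bright in *both* the raw background-subtracted image
(`raw_bright_threshold`, default 100) and the equalized image
(`equalized_bright_threshold`, default 1.5); the two binary masks are
multiplied, then multiplied by the cell mask so structures outside cells
vanish. Connected components (8-connectivity, so diagonal pixels of a small
bright spot do not fragment it) below the mode's minimum area — 35 px for
foci, 5 px for puncta — are removed as noise; the comparison keeps
components with area ≥ the minimum, since the filter's purpose is noise
removal. A structure spanning two cells is assigned to the cell holding the
majority of its pixels, ties to the lower cell id, which is deterministic.

All thresholds are manual, exposed in `segmentation_config()`, and must be
held constant across images and conditions within a run. The defaults are
calibrated to the synthetic generator's default intensity model and will
need adjustment for real microscope data.

## Positivity scoring

For each structure, the surrounding cellular region is the morphological
dilation of the structure by a disc (`dilation_radius`, default 5 px) minus
(a) the pixels of *all* structures in the image — the plural reading: a
neighboring punctum must not contaminate its neighbor's local region — (b)
background pixels outside the cell segmentation, and (c) pixels of other
cells, so the region never bleeds across a cell boundary. The ratio of the
secondary channel's mean over the structure to its mean over this region is
the positivity score; a structure is positive when the ratio is *strictly*
greater than the threshold (default 1.25 — a ratio of exactly 1.25 is
negative). Structures whose region is empty after the exclusions (or has
nonpositive mean) are unscorable: they are flagged, counted in QC, and
excluded from fractions. Two site-level fractions are reported: positive
structures / scorable structures, and cells containing ≥ 1 positive
structure / cells containing ≥ 1 structure.

## Dispersion profile

Cells qualify if their structure mask carries at least
`min_structure_pixels` (default 5, reusing the punctum minimum) nonzero
pixels. Within a qualifying cell the centroid is the intensity-weighted mean
pixel coordinate of the primary channel over the cell mask. Every in-cell
pixel is assigned the ring `round(d)` of its Euclidean distance `d` to the
centroid, so ring k covers [k − 0.5, k + 0.5) and rings stay populated near
the centroid; pixels outside the cell are never counted, and empty rings are
absent rather than zero. Ring values are the mean intensity of their pixels
divided by the cell's mean intensity, which makes the pixel-count-weighted
mean of the profile exactly 1 — a useful invariant the tests assert to
1 part in 10⁹.

Cross-cell aggregation takes, at each ring, the median over the well's cells
that *possess* that ring: padding short profiles with zeros would bias the
tails of large cells downward. Condition curves are the mean ± sample SD
over wells. Peak statistics summarize a profile by its maximum (ties to the
smallest distance), the distance of that maximum, and the half-max width —
the number of contiguous rings around the peak with value ≥ half the peak.

## The synthetic generator

`generate_scene()` renders what the pipeline must measure, with planted
ground truth: non-overlapping elliptical cells (major semi-axis 18–26 px,
axis ratio ≤ 1.5 so the watershed faces non-circular shapes), circular
nuclei at 0.35 of the minor semi-axis, and structures drawn as isotropic 2D
Gaussian spots with σ = radius/2 — the diffraction-limited appearance that
stresses thresholding more honestly than hard disks. Dispersed cells carry
8 puncta (radius 2 px) scattered uniformly in the annulus between nucleus
and membrane with a minimum mutual separation of 2·radius + 3 px, so
planted structures are distinct objects a segmenter can in principle
resolve; clustered cells carry one focus (radius 5 px, thresholded area
≈ 50 px ≥ 35) placed just outside the nucleus edge (offset 2 px),
emulating the perinuclear phenotype. A configurable fraction of structures
(rounded to the nearest structure) also carries secondary-channel signal.

The intensity model is: background 20 + a left-to-right linear ramp of 10 +
cytoplasmic fill 25 inside cells + structure amplitude 400 + additive
Gaussian noise (SD 5), clipped at zero. The amplitudes were chosen once so
that structures dominate the diffuse pool, as they do in STING-activated
cells where most tagged LC3B relocalizes to membranes; with a diffuse-pool-
dominated model the normalized dispersion profile flattens toward 1 for
both pattern classes and the half-max width carries no phenotype signal,
i.e. the generator would fail to emulate the biology it exists to emulate.
Noise is additive Gaussian rather than Poisson — sufficient for the
pipeline's contrast logic and simpler to reason about. Identical specs
(including the seed) render bit-identical scenes; per-(well, site) seeds are
derived from the base seed by a deterministic string hash so partial
re-renders reproduce the same fields.

What the generator does **not** emulate: photon (Poisson) noise,
point-spread-function blur and vignetting, 3D structure, cell-to-cell
expression variability, touching/overlapping cells (a constructed fixture
covers that code path in the tests), or drug-specific phenotype classes.
Passing tests on synthetic scenes therefore demonstrate the correctness of
the measurement logic under controlled truth, not segmentation robustness
on real microscope images.

## qPCR relative expression

`relative_expression()` implements the Livak 2^−ΔΔCt method: ΔCt = Ct_gene −
Ct_reference per biological sample (technical replicate Cts averaged first),
ΔΔCt = ΔCt − mean ΔCt of the untreated samples of that gene, fold =
2^−ΔΔCt. The reference gene defaults to ACTB (β-actin). When an
`experiment` batch column is present the untreated normalization is applied
within each batch — independent experiments carry their own baselines —
otherwise untreated samples are pooled; `batch_col = NULL` forces pooling.
Two identities follow from the algebra and are asserted by the tests: the
geometric mean of untreated folds is exactly 1, and adding a constant to
every Ct of a plate leaves folds unchanged.

## Reproducibility and problem sizes

`run_pipeline()` is a pure function of its `run_config()`: result CSVs carry
only the package version and the config hash (no timestamps), so identical
configurations produce byte-identical outputs, which the tests verify by
checksum. The test suite and the acceptance script use 256 × 256 px fields
with 6 cells each — large enough for ~48 planted puncta per field and small
enough that the full suite runs in well under a minute per property: the
pattern-discrimination check uses 20 paired 3-well plates, positivity
recovery uses five planted fractions × 3 wells, and segmentation recovery
uses 10 independent seeds.

## Known limitations

- Thresholds are manual by design (as in the original analysis style);
  there is no automatic threshold selection.
- The watershed-on-intensity variant can merge genuinely touching cells;
  use the nuclear-seeded variant when a nuclear channel exists.
- Pearson correlation is computed on all pixels of the cell mask without
  intensity weighting; strongly bleached or saturated cells should be
  excluded upstream.
- 16-bit TIFF output quantizes intensities to integer counts; analyses of
  written plates can differ from in-memory analyses by sub-count rounding.
- No amplification-efficiency correction (Pfaffl) in the qPCR module.
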