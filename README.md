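# focusq

Quantification of fluorescent puncta and foci in multi-channel cell images.

## What it measures, and for whom

Cell biologists studying selective autophagy and STING innate-immune
signaling follow fluorescently tagged ATG8-family proteins (e.g.
mScarletI-LC3B): upon pathway activation the protein first forms many small
dispersed perinuclear **puncta** that later coalesce into one or a few large
bright **foci** per cell, and these structures recruit autophagy receptors
(p62, NBR1, NDP52, TAX1BP1, OPTN) visible in a second channel. `focusq`
turns plate-organized multi-channel 2D fields of view into per-condition
numbers for that biology:

- **Per-cell Pearson colocalization** `r = cov(P, S) / (sd(P) sd(S))` over
  the pixels of each segmented cell, between primary (P) and secondary (S)
  channels.
- **Structure positivity**: per punctum/focus, the ratio of mean secondary
  intensity over the structure to that over its surrounding cellular region
  (dilation minus structure and background pixels); strictly `ratio > 1.25`
  counts as positive. Reported as the fraction of positive structures and
  the fraction of cells with ≥ 1 positive structure.
- **Radial dispersion profile**: normalized mean intensity per integer
  pixel ring around the intensity-weighted centroid of each cell's signal.
  A tall narrow peak means clustered foci; a low broad profile means
  dispersed puncta. Summarized by peak value, peak distance and half-max
  width.
- **qPCR relative expression** by the Livak method:
  ΔCt = Ct_gene − Ct_ACTB, ΔΔCt = ΔCt − mean ΔCt(untreated), fold = 2^−ΔΔCt.

Everything is aggregated cell → site (median) → well (median) → condition
(mean ± SD over wells). Segmentation follows the classic recipe: morphological
background subtraction, intensity threshold + size filter + watershed for
single cells, and blur-divide equalization with dual manual thresholds and
mode-specific size exclusion (≥ 35 px foci, ≥ 5 px puncta) for structures.

A synthetic-scene generator (`generate_scene()`, `generate_plate()`) renders
fields with planted cells, pattern classes, colocalization fractions and
noise together with their ground truth, so the entire pipeline is testable
without microscope data.

## Worked example

Simulate a two-condition plate (dispersed vs clustered, three wells each,
planted colocalization fraction 0.5) and run the full pipeline:

```r
library(focusq)
cfg <- run_config(output_dir = "results/demo",
                  layout = plate_layout(c("dispersed", "clustered"), 3, 1),
                  seed = 1)
res <- run_pipeline(cfg)

prof <- res$tables$dispersion_condition
for (cd in c("clustered", "dispersed")) {
  s <- profile_peak_stats(prof[prof$condition == cd, ])
  cat(sprintf("%-10s peak %.2f at ring %d, half-max width %d\n",
              cd, s$peak_value, s$peak_distance, s$halfmax_width))
}
#> clustered  peak 1.99 at ring 5, half-max width 11
#> dispersed  peak 1.26 at ring 10, half-max width 26

res$tables$positivity_condition
#>   condition                    statistic mean sd n_wells
#> 1 clustered      fraction_cells_positive  0.5  0       3
#> 2 clustered fraction_structures_positive  0.5  0       3
#> 3 dispersed      fraction_cells_positive  1.0  0       3
#> 4 dispersed fraction_structures_positive  0.5  0       3
```

The clustered condition's profile peaks almost 2× the cell mean and decays
within ~11 rings — a sharp perinuclear focus — while the dispersed
condition is lower and twice as broad. Both conditions recover the planted
structure-positivity fraction of 0.5 exactly; at cell level the conditions
differ because a clustered cell has a single focus (positive with
probability ½) while a dispersed cell has eight puncta (almost surely ≥ 1
positive). All tables are also written as CSVs under `output_dir`, each
stamped with the package version and the run's config hash; identical
configurations reproduce byte-identical files.

To analyze images on disk instead, point `run_config(input_manifest =
"plate/manifest.yaml", structure_mode = "punctum")` at a YAML manifest
mapping channel roles to path templates (see `?load_plate`). A thin CLI is
included at `inst/cli/focusq.R` with `simulate`, `run` and `qpcr`
subcommands.

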