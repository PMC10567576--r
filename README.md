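# curvadh

Image quantification for **curved adhesions** — curvature-dependent
integrin-β5/FCHo2 cell–matrix adhesions that form where the plasma membrane
wraps high-curvature surfaces (engineered nanobars/nanopillars, ECM protein
fibres). The package re-implements, as tested and reusable R code, the
custom quantification stages used to establish this adhesion class:

* **Lattice registration** of periodic nanostructure arrays from
  bright-field or membrane images (autocorrelation peak detection with
  sub-pixel and harmonic refinement), tiling of per-structure square
  windows, window averaging, and derivation of bar-end/bar-side or
  pillar-disc/annulus ROI masks (0–9 / 10–20 px defaults).
* **Ratiometric quantification**: the per-bar end/side ratio of an integrin
  channel normalized by the end/side ratio of a membrane marker
  (`ratio_norm = (end/side)_integrin / (end/side)_membrane`, which cancels
  per-bar uneven-wrapping factors exactly), pillar/membrane ratios
  normalized per cell, enriched-pillar classification, and per-cell
  Spearman correlation of any protein of interest with enrichment.
* **Dynamics**: per-pillar intensity traces from time-lapse series,
  top-25%/bottom-75% intensity grouping, normalized temporal SD.
* **FRET tension readout**: Tsai "Moments" auto-threshold of the donor
  channel, curved/focal classification by pillar-disc intersection,
  cell-normalized acceptor/donor ratios.
* **Object colocalization**: curved adhesions = ITGβ5 ∩ FCHo2, focal
  adhesions = ITGβ5 ∩ vinculin, in 2D (≥ 10 px) and 3D (≥ 25 voxels).
* **3D infiltration depth**: membrane-shell cell segmentation (≥ 500
  voxels), fibre-matrix surface peeling to a height map z(x, y) (50 px
  blur default), per-cell depth below the surface.
* A **synthetic-image generator** with recorded ground truth (enrichment
  factors, wrap fields, traces, depths, seeds) that emulates every
  geometry above — the basis of all recovery tests.

## Worked example

Render ten-cells-worth of the fabricated nanobar geometry (200 nm × 2 µm
bars, 5 µm pitch, 0.1 µm/px) with a planted integrin end enrichment of 1.9
and per-bar uneven-wrapping confounds, then recover it:

```r
library(curvadh)
set.seed(7)
field <- render_structure_field(
  lattice_spec(),                       # fabricated geometry defaults
  channels = list(
    registration = channel_spec("registration"),
    membrane     = channel_spec("membrane"),
    integrin     = channel_spec("integrin", end_enrichment = 1.9)),
  wrap = runif(64, 0.7, 1.3),           # uneven-wrapping confound
  seed = 7, dims = c(370, 370))

lat <- detect_lattice(field$channels$registration,
                      pitch_band = c(2, 10), pixel_size = 0.1)
sprintf("pitch %.3f um, residual %.3f um", lat$pitch, lat$residual)
#> "pitch 5.000 um, residual 0.007 um"

win  <- tile_windows(lat, dim(field$channels$registration))
rois <- derive_bar_rois(average_windows(field$channels$registration, win))
res  <- end_side_ratios(field$channels$integrin, field$channels$membrane,
                        win, rois, background = c(20, 20))
res$per_cell
#>   cell n_bars mean_ratio_norm
#> 1    1     49        1.908506
head(res$per_bar[, c("window", "ratio_integrin", "ratio_membrane", "ratio_norm")], 3)
#>   window ratio_integrin ratio_membrane ratio_norm
#> 1      1       1.899766      0.9880284   1.922785
#> 2      2       1.926925      0.9577690   2.011890
#> 3      3       1.908833      0.9662266   1.975554
```

The detected pitch matches the 5 µm array; the per-cell mean normalized
end/side ratio recovers the planted 1.9 even though the raw membrane ratios
per bar fluctuate with the wrap factors — the membrane normalization is
what removes them. A field with no enrichment (`end_enrichment = 1`)
recovers 1.0 the same way.

Reproducible end-to-end runs go through a YAML config
(see `inst/extdata/config-bars.yaml`) and either `run_pipeline()` or the
CLI:

```sh
Rscript inst/cli/curvadh bars --config inst/extdata/config-bars.yaml --out out/
```

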