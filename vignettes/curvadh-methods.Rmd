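---
title: "Quantifying curved adhesions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying curved adhesions: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvadh)
```

## The measurement problem

Vertically etched SiO~2~ nanobars and nanopillars deform the plasma
membrane of cells cultured on them with defined curvature: bar ends and
pillar circumferences are high-curvature sites, bar side walls and the flat
substrate between structures are low-curvature references. Curvature-sensing
proteins — most prominently integrin β5 and the F-BAR protein FCHo2, whose
colocalization defines *curved adhesions* — enrich at the curved sites. The
quantitative readouts this package implements are:

1. **End/side ratio** on nanobars: mean intensity over bar-end ROIs divided
   by mean intensity over bar-side ROIs, per bar, *normalized by the same
   ratio of a co-imaged membrane marker* (CaaX/CellMask). The membrane
   normalization is what separates genuine curvature preference from uneven
   membrane wrapping: any per-bar multiplicative wrap factor hits both
   channels identically and cancels exactly in the quotient.
2. **Pillar/membrane ratio** on nanopillars, using a disc ROI (0–9 px from
   the pillar centre) and a flat annulus ROI (10–20 px), each normalized by
   the cell-wide mean ratio so the per-cell average is 1 by construction.
3. **Ratiometric FRET** of talin tension sensors: acceptor/donor ratios over
   adhesion masks segmented from the donor channel by the moment-preserving
   (Tsai "Moments") auto-threshold, split into curved vs focal classes by
   intersection with the pillar-disc map, normalized by the cell-wide mean.
4. **Object-based colocalization**: curved adhesions = ITGβ5 ∩ FCHo2
   objects, focal adhesions = ITGβ5 ∩ vinculin objects, with size filters of
   10 px (2D) and 25 voxels (3D).
5. **Infiltration depth** in 3D fibre matrices: cell centroids from a
   membrane-marker stack, matrix surface as a height map z(x, y), depth =
   surface height minus centroid height.

None of the original microscopy data are required: every analysis stage is
exercised against a bundled synthetic generator whose hidden parameters are
recorded as ground truth.

## The synthetic world

`render_structure_field()` renders multichannel fields on a square lattice
with the fabricated geometry as defaults: 200 nm × 2 µm bars (1.4 µm height
is not modelled — imaging is treated as a 2D section), 5 µm pitch, 0.1 µm
per pixel. The intensity model for membrane-bound channels is
phenomenological:

* flat cell membrane: `base_intensity` photons/pixel,
* structure footprint: `W_s * base_intensity`, where the per-structure wrap
  factor `W_s > 0` applies jointly to *all* membrane-bound channels,
* curvature-affected sub-region (the terminal caps of depth equal to the
  bar width, or the whole pillar disc): an extra factor `E`, the channel's
  end enrichment; `E = 1` means no curvature preference,
* everything plus `background`, then Poisson photon noise, additive Gaussian
  read noise (`sd = 2` photons, an sCMOS-like default; the source protocol
  reports no camera statistics) and clipping at zero.

Defaults `base_intensity = 200`, `background = 20` give per-ROI relative
errors of a few percent, comparable to a reasonably exposed epifluorescence
image. There is **no PSF blur by default**: the noiseless render equals the
closed-form expectation pixel for pixel, which is what makes exact oracle
tests possible. Consequences of this choice are discussed under *Bar ROI
geometry* below.

What the generator does **not** emulate: optical sectioning and defocus,
bleaching, spatially varying background, membrane ruffling, or any physical
membrane mechanics — enrichment factors are painted, not simulated. A green
recovery test therefore establishes that the *pipeline arithmetic* is
unbiased under the stated noise model, not that the biology is correctly
modelled.

Pillars are rendered with an effective footprint diameter of 1.8 µm
(default), i.e. the membrane-wrapped projection that the 0–9 px disc ROI is
meant to capture at 0.1 µm/px — the physical pillar is narrower, but the
signal a real image shows at a pillar is the wrapped membrane plus PSF, and
the ROI definition (9 px ≈ 0.9 µm radius) is pinned to that projection.

## Lattice registration

The array is detected from the 2D autocorrelation (FFT-based): the primary
lattice vector is the *shortest* strong local maximum whose length lies in
the configured pitch band — taking the global maximum instead would
occasionally return a diagonal or a harmonic, which are peaks of comparable
height. The vector is refined twice: quadratic sub-pixel interpolation at
the peak, then re-estimation at the highest harmonic that fits in the image
(dividing the harmonic position by its order divides the interpolation
error likewise). The lattice phase comes from the argument of the
first-order Fourier coefficient along each lattice axis; the residual
reported is the RMS offset of local intensity centroids from the ideal
grid, after absorbing the mean offset into the origin. Images without
significant periodicity in the band (normalized autocorrelation peak
below 0.1) fail with `"no lattice"` rather than returning a guess.

Windows are congruent squares, side = largest odd integer not exceeding the
pitch, centred on integer-rounded node positions; a window is `in_cell`
when ≥ 80% of its pixels lie in the cell mask (the published protocol only
says ratios are computed for structures "in a cell"; 80% keeps windows
whose membrane reference is dominated by actual cell).

## Bar ROI geometry

The published construction derives the ROIs from the *averaged* window —
averaging first, ROI derivation second — and this package follows that
order: Otsu threshold of the averaged registration/membrane window, largest
connected component as the bar footprint, principal axis from the PCA of
footprint pixel coordinates (footprints rounder than eccentricity 1.2 are
rejected as "not a bar"). The end mask is the pair of terminal caps of
depth `cap_depth`, the side mask is the rest of the footprint, both
optionally dilated laterally by `flank_width`.

Two geometric choices deserve justification:

* **Cap depth defaults to the measured bar width.** The generator defines
  its curvature-affected region the same way (terminal caps of depth = bar
  width). With both conventions aligned, the noiseless direct end/side
  ratio of a channel with enrichment `E` is *exactly* `E` — the identity the
  unit tests pin down.
* **`flank_width` defaults to 0,** i.e. masks restricted to the exact
  footprint. A dilated mask (the natural choice for PSF-blurred real data)
  includes flat-membrane pixels whose intensity equals the flat `base`;
  because these pixels carry no enrichment, they dilute the end mean and
  bias the normalized ratio toward 1 (with a 2-px dilation, a true 1.9
  recovers as ≈ 1.14 in the default synthetic world). In a world without
  PSF blur the unbiased mask is the footprint itself; the parameter remains
  available and should be set to roughly the PSF radius when analysing
  blurred data.

## Ratiometrics and exclusion rules

Backgrounds are subtracted as the median of the cell-free region (or passed
explicitly). Bars or ROIs whose denominator is not positive after
subtraction are *excluded and logged*, never clamped — clamping would bias
ratios upward. Per-cell summaries are plain means over the surviving
structures: one data point per cell for bars, one per ROI for pillars (the
published convention). The enriched-pillar threshold `T = 1.5` sits midway
between the null ratio 1.0 and the reported integrin β5 effect 1.9; the
criterion behind the published "~30% of nanopillars" is not stated in the
protocol, so `T` is an explicit, configurable default, and the recovery
test plants a separable enrichment (E = 2.5) for which classification is
threshold-robust.

Spearman correlation uses midranks (the standard tie convention) via
Pearson on ranks; the test suite checks it against the
`1 − 6Σd²/(n(n²−1))` formula on all 120 permutations of 5 elements and
under strictly monotone transforms.

## FRET specifics

The Moments threshold reproduces the 256-bin GUI dialect bit for bit:
min–max rescale to integer levels 0–255, closed-form solution of the
three-moment-preserving two-level system, threshold = first level whose
cumulative histogram reaches the preserved fraction p₀ (with an epsilon so
that an exactly symmetric histogram does not run off the scale). The
exhaustive-search oracle (all 256 cuts, solving the two representative
levels from the first two moments and scoring the third-moment mismatch)
agrees either exactly or as the last-cut-below-p₀ vs first-cut-above-p₀
bracket pair; the tests assert precisely that.

Per-class FRET ratios default to the **mean of pixelwise ratios** — the way
GUI ratiometric workflows operate — with the ratio-of-means alternative one
argument away, since the source protocol does not say which was used.
Pixels below the donor floor (background median + 3 SD by default) are
excluded to keep per-pixel ratios stable.

## Colocalization

Channels are thresholded independently (Moments), intersected, labelled
with the GUI-default connectivities (8 in 2D, 26 in 3D) and size-filtered
(10 px / 25 voxels). The interactive 3D threshold used originally is
unrecorded, so the 3D path substitutes the same deterministic Moments
threshold per stack, with a numeric override — a declared deviation chosen
for reproducibility. Connectivity ignores voxel anisotropy; the output
flags anisotropic voxel sizes instead of resampling. The
"intersection count ≤ each channel's count" invariant is guaranteed only
for blob-shaped objects (each object overlapping at most one partner), and
is tested on such fields.

## 3D segmentation and depth

Cell segmentation follows the published three-step outline with the
unpublished kernels made concrete: gradient magnitude by central
differences in micrometre units (the named GUI plugin's kernel is not
documented), Otsu threshold, box closing (radius 2) plus hole filling to
seal the hollow membrane shells, 26-connected labelling, 500-voxel volume
filter, centroids in micrometres.

The surface estimate blurs each slice laterally (σ = radius/2, radius
default 50 px as published), thresholds the blurred stack (Otsu — the
macro's internal threshold is unrecorded), takes the topmost above-threshold
z per column, interpolates empty columns from neighbours (flagged), and
finally smooths the height map laterally at half the blur σ: single-column
dips reflect local gaps in fibre coverage, not topography, at the scale the
blur radius declares interesting. Depth is
`z_surface(x_c, y_c) − z_c`, positive *below* the surface; cells above the
nominal surface get negative depths, not zero, so surface-dwelling
populations straddle 0 symmetrically. Test fixtures use stacks a few times
smaller than the published 200–300 µm matrices (scaled down for runtime);
the geometry is unchanged.

## Numerical notes and limitations

* All randomness flows from a single integer seed per render, recorded in
  the ground-truth sidecar; renders are bit-identical across runs.
* Tiles, masks and labels are pure integer/pixel operations; physical units
  enter only through recorded pixel/voxel sizes.
* The TIFF layer is a minimal in-package baseline codec (uncompressed,
  grayscale, 8/16-bit integer or 32-bit float, multi-page, JSON metadata in
  the ImageDescription) because the supported R stack ships no TIFF
  package; it is not a general-purpose TIFF reader.
* Float32 storage means image round-trips are exact to ~1e-6 relative, not
  bit-exact; ground-truth JSON sidecars round-trip losslessly.
* Lattice detection assumes a square, undistorted array; rotated arrays are
  supported, sheared or graded-pitch arrays are not.
* The drift check in trace extraction searches ±5 px of cross-correlation
  lag; on images with no registrable structure it reports itself
  inconclusive and assumes a static field rather than failing.
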