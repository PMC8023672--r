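---
title: "Visualizing and gating multiplexed imaging data with imcviz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualizing and gating multiplexed imaging data with imcviz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imcviz)
```

## The data model

Multiplexed imaging experiments produce three co-registered artefacts per
acquired region, and `imcviz` mirrors them with three containers:

- an `image_stack` — a rows × cols × channels array of non-negative
  intensities (arbitrary units; for IMC, ion counts), with ordered unique
  channel names;
- a `segmentation_mask` — a rows × cols integer matrix in which 0 is
  background and each positive value labels one cell object (ids need not be
  consecutive);
- a `cell_table` — one row per cell keyed by `(image_name, object_id)`,
  holding a cells × markers expression matrix plus metadata columns such as
  `cell_type` or `area_px`.

Multi-image experiments use the `image_collection`, an ordered, uniquely
named set of stacks *or* masks with a per-image metadata table (condition,
donor, ...). All cross-container joins go through `pair_by_name()`, which
matches by **exact** image-name equality and reports (never silently drops)
names present on only one side. Silent mismatches between a mask and a
same-named stack are the main QC hazard in this kind of data, so unequal
pixel dimensions under one name are a hard error, while cell rows whose
object id is absent from the mask are merely surfaced in the pairing report
— what to do with them is a rendering decision.

Coordinates are (row, col), 0-based, origin top-left, matching raster
storage order; this convention is used everywhere, including reported
centroids.

## File formats

Stacks are plane-per-channel (page-ordered) TIFFs; interleaved RGB TIFFs
are rejected, because IMC-style tooling writes one page per marker. Masks
are single-page TIFFs whose values must be exact non-negative integers:
masks are *never* rescaled on read, since rescaling a label image corrupts
object ids. Stacks may opt into an `on_read_scale` divisor (e.g. 65535 for
16-bit data meant to land in [0,1]); the default is no scaling.

Written float TIFFs store 32-bit samples in [0,1], so `write_stack()` takes
a `scale` divisor and `read_stack(on_read_scale = 1/scale)` inverts it;
round trips are exact to 32-bit float precision (~1e-7 relative). Mask round
trips are bit-exact up to label 65535. Rendered images are written as 8-bit
PNG (`round(v * 255)`), so re-read values match within 1/255; out-of-range
values are an error rather than being clipped silently — clipping is always
the caller's explicit decision. Cell tables are plain CSV (comma, UTF-8,
header, "." decimal) and round-trip keys exactly, expression to better than
1e-9 relative, and factor metadata with its observed levels.

## Rendering

**Mask colouring by feature.** Each plotted cell's value $v$ maps to
$t = \mathrm{clip}((v - lo)/(hi - lo), 0, 1)$ and $t$ is interpolated
piecewise-linearly along the colour ramp. Interpolation is linear in RGB
space — not Lab or HSV — which is deterministic, dependency-free and
matches common raster tooling; renderings may therefore differ slightly in
perceptual spacing from tools that interpolate elsewhere. The default range
is the min/max over the *plotted* cells of the current image; pass an
explicit range for cross-image comparability. A single plotted cell (or a
constant feature) makes the range degenerate and resolves to $t = 0$, the
first ramp colour. Mask objects without a cell row take the missing colour
(white by default, the "all other cells" convention); cell rows without a
mask object produce a warning annotation, not an error.

**Composites.** Per channel, the bcg (background/contrast/gamma) chain is
pinned as: multiply by contrast, add background, clamp at 0, raise to
gamma, then window by the range into [0,1]. The clamp before gamma exists
because a negative base under a fractional exponent is undefined; only the
contrast-multiplication step of this chain is externally prescribed, the
rest is fixed here for reproducibility. Channel contributions are
`u * colour`, summed and clipped at 1 — additive blending was chosen over
screen blending because it reproduces the familiar appearance of composite
overlays where co-localized markers mix (yellow + blue, etc.) and is
commutative, which the tests assert as channel-order invariance. The
six-channel cap is a hard error: beyond six, colour collisions make a
composite actively misleading.

**Outlines.** A boundary pixel is an object pixel with an 8-connected
neighbour carrying a different label; pixels beyond the image border count
as background, so objects touching the edge are outlined there too.
Thickness > 1 grows the outline by iterative inward dilation (only into
pixels of the same object), so outlines never spill outside their object —
interior pixels of the underlying composite stay visible. Outline colours
come from a single colour or per-cell from a categorical palette; levels
missing from the palette fall back to the missing colour rather than
failing, because a QC overlay should show every boundary.

**Scale bars and grids.** A scale bar of physical length $L$ µm is
`round(L / pixel_size_um)` pixels, drawn bottom-left; requesting a bar wider
than the image, or a bar on an image with unknown pixel size, is an error.
`render_grid()` places panels row-major into `ceiling(n/columns)` rows,
padding to the largest panel — layout depends only on input order, so grid
PNGs are byte-reproducible.

## Intensity transforms

`normalize()` rescales each channel affinely into [0,1] with bounds from
the channel min/max (`minmax`) or from percentiles (`percentile`, linear
interpolation between order statistics, i.e. R's `quantile(type = 7)`,
pinned so results are reproducible across environments). Bounds are
computed per image (`separate`, the default — appropriate when staining
intensity varies between acquisitions) or pooled (`joint` — appropriate
when absolute comparisons across images matter). A degenerate channel
(`hi == lo`) maps to zero. The percentile default `c(0, 99)` suppresses the
hot-pixel tail typical of ion-count data. `scale_intensity()` is the
simpler tool used for display contrast — elementwise multiplication of
named channels with no clipping (clipping is a render-time decision).

`cell_density()` divides the count of matching cells by the **full image
area** (per mm² when the pixel size is known, per megapixel otherwise).
Tissue- or islet-restricted areas would need a tissue segmentation step
this package does not provide, so densities over sparse tissue are
underestimates relative to a tissue-area denominator; rankings within a
dataset of similar tissue coverage are unaffected. Ranking ties break by
ascending image name — deterministic output is a hard requirement, and a
tie broken by input order would silently depend on file listing order.

## Gating

Gates are closed intervals; a value exactly at a bound is kept. The choice
is pinned (open intervals would be equally defensible) because ties at
thresholds are common after transform-induced clumping, and an unstated
convention is the kind of thing that silently changes populations between
runs. Sequences beyond 24 gates warn but run: the 24-marker ceiling is a
practical limit of interactive gating panels, not a mathematical one. Only
per-marker intervals are offered — no polygon/ellipse gates and no
automated threshold finding. Gating operates on the expression matrix as
stored; any transformation must be applied upstream, and the exported
provenance sidecar (label + `{marker, min, max}` list, YAML) makes the
applied gates re-playable: re-applying them to the source table reproduces
the exported keys exactly.

## The synthetic generator

The generator exists so that every operation above can be verified against
planted ground truth. Cells are **discs**: radii uniform in
`radius_range`, centres at integer pixels placed by rejection sampling with
centre separation strictly greater than the radius sum plus one pixel, and
a margin of one radius from the border. Discs give closed-form pixel
supports (every pixel within radius of the centre), trivially verifiable
disjointness, and exact expected areas — realism of cell shape is
deliberately sacrificed, since none of the rendering/gating logic depends
on it. Placement failure after a bounded number of attempts is an error
suggesting fewer or smaller cells, not a hang.

Intensities are `background + signature[type, marker]` inside each cell.
The default signature gives each type one defining marker (beta: PIN high
with SYP; Th: CD4 with CD45; Tc: CD8a with CD45; "other": low everything),
so midpoint thresholds separate populations exactly in the noise-free case.
Noise models: `gaussian` adds zero-mean noise truncated at 0 (preserving
the non-negativity invariant), `poisson` replaces each pixel by a Poisson
draw with the clean value as mean — the natural model for ion counts.
Under Poisson noise a cell of area $A$ and mean $\lambda$ has measured-mean
standard deviation $\sqrt{\lambda/A}$; tests use a $4\sigma$ band with
$A \ge 30$ px (radius ≥ 4 guarantees ≥ 49 px), so a single comparison
fails with probability ≈ 6×10⁻⁵ — with fixed seeds the suite is fully
deterministic, and the band documents the budget that would apply under
seed variation.

Each generator call runs on its own seeded stream and restores the caller's
RNG state, so fixtures are bit-reproducible and never perturb user code.

`make_t1d_like_scenario()` assembles the full study-shaped fixture: three
condition groups (healthy, recent onset, long duration) whose planted
beta-cell proportions fall monotonically (0.50, 0.30, 0.10) while the
combined Tc/Th proportion peaks in the middle group (0.10, 0.40, 0.20) —
beta-cell loss with an early wave of immune infiltration. Defaults are 3
images per condition, 40 cells per 128×128 image at 1 µm/px, radii 4–6 px,
background 0.1, no noise; these sizes keep any demonstration or check on
the scenario comfortably under a few seconds while leaving ~100 cells per
planted population, enough for stable precision/recall statements. The
scenario also returns ground-truth gate sequences at the midpoints between
signature levels.

What passing on this fixture does **not** show: robustness to irregular
cell shapes and touching cells, spillover between channels, hot pixels,
staining batch effects, or mis-segmentation — real data has all of these,
and the package's correctness claims are about its operations, not about
upstream data quality.

## Numerical and degenerate-input decisions

- All [0,1] clipping is `pmin(pmax(x, 0), 1)`; rendered outputs are
  asserted in-range on every test render.
- `hi == lo` in any affine rescale (normalization, feature ramps) resolves
  to 0 / first ramp colour rather than NaN.
- An all-background mask is valid (empty object set); measuring it yields a
  0-row table; outlining it returns the base image unchanged.
- Empty selections export header-only CSVs that re-read as 0-cell tables.
- Label images are validated on ingest: the first fractional or negative
  pixel is reported with its (row, col) position.
- Image names come from filename stems up to the first extension;
  collisions are errors, never silently suffixed.

## Problem sizes used in the checks

The acceptance checks regenerate everything from a seed: 3 images of
256×256 px with 200 cells each for the measurement round trip; 50 random
32×32 label images against the brute-force boundary oracle; 100 random
tables × 1–5 random gates against exhaustive filtering; 20 random 1–6
channel stacks for blending properties; and the 9-image scenario (clean and
Poisson-noised) for population recovery. These sizes were chosen as the
smallest at which each property is exercised across all code paths
(multiple images, non-consecutive ids, all noise models) while the whole
suite stays interactive.

## Known limitations

- No lazy/chunked image access; collections are assumed to fit in memory.
- No OME-TIFF metadata, MCD reading, or HDF5/Zarr backends.
- Density uses the full image area (see above).
- Legends and scale annotations are structured records on the
  `rendered_image`; their graphical drawing is minimal (the scale bar) —
  publication figure assembly is left to the caller.
- Colour interpolation in RGB space can look perceptually uneven for long
  ramps; supply more ramp anchors if that matters.
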