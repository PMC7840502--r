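---
title: "Cube-based image cytometry: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cube-based image cytometry: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubecyte)
```

## The analysis model

Confocal stacks of biofilms and other structured microbial communities
rarely permit single-cell segmentation, yet their internal organization —
density gradients, reporter expression with depth, strain mixing — is
exactly what one wants to measure. cubecyte follows the cube-cytometry
idea: classify every voxel as biomass or background (semantic
segmentation), dissect the binary biovolume into a cubical grid of
user-defined physical edge length, and treat each occupied cube as a
pseudocell object carrying a vector of parameters. Gating, custom derived
parameters, lineage tracking and kymographs then operate on cubes exactly
the way flow-cytometry tools operate on cells.

All arrays are indexed `(z, y, x)` with `z = 1` the substratum-adjacent
plane; voxel `(z, y, x)` has its center at
`((z - 0.5) dz, (y - 0.5) dy, (x - 0.5) dx)` micrometres. Voxel pitch is
always supplied explicitly (a sidecar configuration) rather than read from
TIFF resolution tags, which are unreliable in practice; this makes every
physical quantity reproducible from the configuration alone.

## Segmentation

Four automatic threshold algorithms are provided, plus a manual level and
import of presegmented (optionally labeled) masks:

* **Otsu** — maximizes the between-class variance
  $\sigma_b^2(t) = \omega_0\omega_1(\mu_0-\mu_1)^2$ over the interior
  edges of a 256-bin equal-width histogram spanning the observed range.
  Class moments come from bin midpoints, so an exhaustive scan over the
  same histogram reproduces the result exactly; ties go to the lowest
  level.
* **Ridler–Calvard** — the intermeans iteration
  $T_{k+1} = (\mathrm{mean}(v \le T_k) + \mathrm{mean}(v > T_k))/2$
  from the global mean, stopped when the update falls below `rc_tol`
  (default $10^{-6}$ intensity units, hard cap 1000 iterations).
* **Robust background** — the name appears in the biofilm literature
  without a published formula, so the definition here is the package's
  own and is stated explicitly: discard the dimmest and brightest 5% of
  voxels and set the level to mean + 2 sd of the remainder (both
  parameters exposed). It is intended for images dominated by a
  well-behaved background with a small bright biomass fraction.
* **Maximum correlation** — the level maximizing the Pearson correlation
  between the gray image and its binarization, scanned over the same
  256-bin candidate set as Otsu.

Foreground is strictly *greater than* the level. This makes "manual level
at the maximum intensity" yield an empty mask — an unambiguous, if
arbitrary, convention. Despeckling removes 26-connected components (8 in
2D) below `min_object_voxels`. Hole filling is per-z-slice (2D) on
purpose: filling in 3D would seal real vertical channels, which are a
genuine biofilm feature. The median filter footprint and the Gaussian
kernel are anisotropy-aware (a physical radius/sigma is converted to
voxels per axis), since confocal z pitch typically exceeds the xy pitch.

## Dissection

The cube edge is given in micrometres and converted per axis to a voxel
span by rounding (minimum 1), so datasets with different pitches remain
physically comparable. Cube regions are half-open index ranges
`[i*s, min((i+1)*s, n))`; cubes cut by the image border are kept and
flagged `truncated`, and their fill fraction uses the truncated region as
denominator. Dropping them would bias rim statistics; padding to full
size would dilute density. Every foreground voxel belongs to exactly one
cube, so summed cube biovolume equals the whole-biofilm biovolume
exactly — this conservation is asserted in the tests. For 2D images the z
span is 1 and the volume is dissected into squares. Imported labeled
masks bypass the grid entirely: each label becomes one record, which is
how external single-cell segmentations enter the same analysis stream.

## The per-cube parameter set

With two fluorescence channels the parameter set totals 49:

* 13 geometry/distance parameters: fill fraction (local density), voxel
  count, biovolume, centroid (x, y, z), distance to the outer surface, to
  the substratum, to the centre of mass and to its substratum projection,
  local thickness, exposed surface area, local surface-to-volume ratio;
* 5 neighborhood parameters: occupied-neighbor count, neighborhood mean
  fill, fill-gradient magnitude, relative height, normalized surface
  distance;
* 8 intensity statistics per channel (mean, population sd, cv, median,
  min, max, sum, range);
* 5 gray-level co-occurrence texture statistics per channel (contrast,
  correlation, energy, homogeneity, entropy);
* 3 pairwise channel correlations (Pearson, Spearman, Manders overlap)
  and 1 density–intensity correlation per channel.

Cube statistics are computed over foreground voxels only; parameters
describe biomass, not the background inside a cube's bounding box. The
one exception is the fill fraction, whose denominator is the region size.

**Distances.** The distance to the outer surface is an exact anisotropic
Euclidean distance transform (separable lower-envelope algorithm,
implemented in C++) from each foreground voxel center to the nearest
background voxel center. The volume is padded with one background layer
on all faces except, in `attached` mode, the substratum face, which is
padded with a mirror of the base slice — a surface-attached biofilm is
not "exposed" at its contact plane. `floating` mode (for aggregates)
pads all faces with background. The original tool's convention here is
not documented; both modes are exposed and the choice is recorded with
the results. A cube's surface distance is the mean over its foreground
voxels rather than a single centroid sample, which is robust for
partially filled cubes.

**Local thickness** is the mean, over the cube's distinct occupied
xy-columns, of the whole-biofilm column height at those columns, with
column height `(1 + highest foreground z index) * dz` ignoring interior
gaps (the COMSTAT thickness-map convention).

**Texture.** Each cube's foreground intensities are quantized to 8 equal
levels between the cube's own min and max; co-occurrence pairs are pooled
over one-voxel offsets along all three axes, symmetrized and normalized.
Local quantization makes texture contrast-invariant per cube. Cubes with
fewer than 8 foreground voxels (or no adjacent pairs) carry NaN — at that
size a co-occurrence matrix is noise. Entropy uses the natural log; a
constant cube has energy 1, contrast 0, homogeneity 1, entropy 0 and
undefined (NaN) correlation.

**Density correlation.** A within-cube density is a single number, so the
correlation between a channel and density is defined across the cube's
27-cube neighborhood: Pearson correlation between neighbor mean
intensity and neighbor fill fraction, NaN when fewer than 3 occupied
cubes are available.

NaN is the universal missing-value token; gates exclude NaN records from
both the gate and its complement, so the gate and complement partition
the records that are defined in the gated parameters.

## Whole-biofilm metrics

The structure registry (biovolume, maximum and mean thickness,
substratum coverage, exposed surface area, roughness coefficient
$R_a^* = \frac{1}{N}\sum_i |L_i - \bar L| / \bar L$, surface-to-volume
ratio) follows the COMSTAT conventions. Two mean-thickness variants are
emitted — averaged over all columns and over biomass-occupied columns —
because the two definitions coexist in the literature under one name.
Surface area is voxel-face counting, which for a digitized sphere
overestimates the smooth-sphere area by a known factor of about 1.5
(asserted as an invariant in the tests); it is kept because it is the
compatible convention. A triangulated-mesh area is not emitted.

Colocalization between two channels over the mask: Pearson, the Manders
overlap coefficient, the Manders split coefficients M1/M2 (binarization
levels default to per-channel Otsu over the mask voxels), volume overlap
fractions and relative biovolume abundances.

**Spatial correlation functions.** Indicator fields are centered over the
analysis window; the cross-covariance is computed for every integer voxel
lag by zero-padded FFT and divided per lag by the number of valid voxel
pairs — no periodic wraparound, because a biofilm window is not periodic.
Values are normalized by the zero-lag standard deviations and
shell-averaged into radial bins using physical lag lengths, with the zero
lag reported as its own bin so an autocorrelation starts at exactly 1.
The cluster-size estimator is the first crossing of $1/e$ (linear
interpolation between bin centers); the separation estimator is the first
interior local maximum of the cross-correlation at $r > 0$. Both
estimators are this package's concretization of the respective summary
quantities, which the field names without fixing a formula.

## Time series

Frame registration estimates rigid integer xy drift as the argmax of the
FFT cross-correlation of z-projected masks, with ties broken toward the
smallest shift so that pure symmetric growth registers as zero drift.
There is no z registration (surface-attached growth assumption; disable
tracking for floating aggregates). Because a fixed grid cuts shifted
content differently, masks are drift-corrected (`align_masks()`) *before*
dissection; tracking a translated series is then identical to tracking
the original, which is verified exactly in the tests for pure
translations. When a colony grows and drifts simultaneously the drift is
identifiable only up to the growth margin (the overlap objective has a
plateau); the tie-break then biases the estimate toward zero.

Lineages connect a cube to its largest-overlap predecessor (shared
foreground voxels; ties to the lowest cube id), each child keeping one
parent so the graph is a forest. A cube colonized for the first time has
no voxel overlap with the previous frame; by default it is attached to
the occupied 26-neighbor with the most biomass (recorded with weight 0
and `direct = FALSE`) so that an expanding front joins existing lineages
instead of spawning roots. This attachment rule is the package's own
choice; set `attach_new = FALSE` for strict overlap-only tracking.

Kymographs aggregate a cube parameter into (distance bin) x (time)
cells as foreground-voxel-weighted means — weighting prevents sparse rim
cubes from dominating a bin. Total biovolume can replace time on the x
axis; frames are then pooled into equal-width volume bins (default: as
many bins as frames).

## The synthetic generator

`make_colony()` and friends produce the study volumes: substratum-attached
hemispheres, uniform slabs, a two-thickness slab (a base with a thicker
ridge, giving the bimodal local-thickness signature used to gate wrinkle
and base subpopulations), free-floating spheres, disjoint strain blocks
and i.i.d. random mixtures. Reporter fields (constant, exponential decay
from the surface or the substratum, linear gradients) use the same
distance transform as the cytometry, so recovery tests have exact closed
forms; Gaussian and Poisson noise are seeded and every output is a pure
function of (spec, seed) with no global RNG leakage.

What the generator deliberately does not emulate: the microscope PSF and
optical sectioning anisotropy, depth-dependent attenuation, shot-noise
calibration and deconvolution artifacts. Passing tests on these volumes
therefore validate the measurement machinery (geometry, statistics,
conservation, estimator recovery), not segmentation robustness on
difficult real images — for those, import an externally validated mask.

Default test problem sizes are deliberately modest (volumes of roughly
$10^4$–$10^6$ voxels, grids of tens to hundreds of cubes, 20–50 random
instances per oracle comparison); they were chosen so the whole
verification cycle runs in seconds while still exercising truncation,
anisotropy and degenerate cases.

## Known limitations

* Face-counting surface area carries the ~1.5x digitization bias
  discussed above; compare areas only between identically processed
  volumes. No mesh-based area is provided.
* Texture parameters are undefined (NaN) for cubes below 8 foreground
  voxels; at near-single-cell cube sizes most texture columns will be
  NaN.
* Tracking assumes a fixed field of view with rigid xy drift; deformable
  motion, z drift and merge/split classification are out of scope.
* Only TIFF I/O is supported; convert proprietary formats externally.
* The GUI-style interactive thresholding of the original workflow is
  replaced by the provenance JSON (chosen level per frame) plus mask
  export for visual inspection.
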