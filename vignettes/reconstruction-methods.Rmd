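---
title: "Blockface-anchored 3D reconstruction of serial-section histology: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blockface-anchored 3D reconstruction of serial-section histology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A serially sectioned specimen yields hundreds of 2D microscopy sections,
each processed with one of several stains, each independently and
nonlinearly distorted by cutting, staining, and mounting. Stacking the
sections does not reproduce the 3D specimen: every section must first be
warped back to where its tissue was before sectioning. The one geometric
record of that state is the blockface photograph taken of the frozen block
before each cut. `histostack` reconstructs multi-contrast 3D volumes by
deformably registering every section to the blockface stack and to its
already-registered neighbors, then assembling, harmonizing, and
interpolating the registered sections into per-stain volumes on the common
200-µm blockface grid, optionally aligning a quantitative MRI volume into
the same space.

All geometry uses one convention throughout: rasters are `[x, y(, z)]`
arrays, coordinates are 1-based and voxel-centered, and every transform is
a pull-back map taking output-grid coordinates to input-image coordinates,
represented as an affine composed with a dense displacement field
(`out(p) = in(A(p + u(p)))`).

## The registration engine

`register_pair()` maximizes a weighted sum of similarity terms over a set
of fixed targets, coarse-to-fine over a dyadic scale schedule (default six
scales from a factor of 64, truncated so the coarsest level keeps at least
8 pixels per axis, with a full-resolution level always run last).

*Similarity.* Intensity channels are compared by joint-histogram mutual
information (equal-width bins over the observed range, 32 bins at full
resolution, fewer at coarse levels where samples are scarce). MI is the
only practical choice here because the stains, the blockface, and MRI are
related by unknown, often non-monotone intensity lookups. Two auxiliary
channel types are *calibrated* rather than of unknown contrast, and use
Pearson correlation instead: boundary bands (Gaussian-of-distance maps of
the tissue contour) and softened tissue masks. MI on such sparse calibrated
maps is actively misleading — any warp that overlaps the bands scores well,
including degenerate ones — while correlation penalizes band distortion.

*Optimization.* An affine stage first runs an exhaustive integer
translation search at a coarse level and Nelder-Mead refinements (rigid,
then full 6-dof) at a finer level; rotations beyond ±20° and strong
shears are rejected, since mounted sections sit nearly upright and round
tissue outlines otherwise admit spurious rotated optima. The deformable
stage is a demons-style ascent: at each iteration every intensity target is
remapped into the moving image's intensity space through the conditional
mean of the current joint histogram, and the resulting residuals drive
normalized gradient forces, accumulated over targets with their weights,
smoothed (fluid), integrated into the field, and smoothed again
(diffusion). Residuals below the within-bin quantization scale are shrunk
to zero so that a perfectly aligned pair stays stationary. At coarse levels
a discrete local-offset search (block matching on the remapped residual)
precedes the iterations; it is kept only when it improves the metric, and
supplies the long-range capture that gradient forces lack. The
best-scoring field per level is archived and carried forward.

Boundary-band channels deserve a note: a distance-based band warped from
the distorted section is *not* the band of the warped contour, because
deformation distorts distances. The moving side therefore carries the
binary tissue mask, and the band is rebuilt from the warped mask at every
iteration, so the residual genuinely vanishes at alignment. Bands act only
at fine levels (their capture range is the band width) and at reduced
force gain, because contour information is gauge-free tangentially.

Defaults (30 iterations per level, fluid σ 2 px, diffusion σ 1.5 px, step
1.8) were fixed once by recovery experiments on the synthetic phantom.

## Stack orchestration

`run_reconstruction()` implements the iterated forward-backward scheme.
Each section's target set is: the blockface image of its slice (weight 1,
with ventricle-scale holes excluded from the metric support), the nearest
previously-coregistered same-stain section and its boundary map (weight
1/2 each), and the two nearest previously-coregistered sections of any
stain and their boundary maps (weight 1/4 each); "previously coregistered"
respects the sweep direction and a sliding window of three slices, with
distance ties resolved toward the most recently refreshed section. By
default the blockface anchor also contributes its tissue mask and boundary
band at weight 1/2 (`anchor_features`); the mask term provides
contrast-free capture for stains whose intensity relation to the blockface
is strongly non-monotone, and can be disabled to obtain the strict
image-plus-neighbor target set.

Sweeps run rostral→caudal then caudal→rostral; each registered section
immediately refreshes its resampled image and feature maps, so later
sections in the same sweep see current geometry (the Markov-chain
dependency). After every sweep each section reverts to its archived best
result; the archive score is the blockface MI plus a boundary-agreement
correlation, because MI alone can reward degenerate warps that collapse a
stain's classes onto few levels. Three forward-backward cycles are run by
default; from the second cycle, sections whose archived score trails the
field (bottom 40%) are restarted from a fresh affine stage under a more
exploratory iteration schedule — their neighbors are well registered by
then, and the archive keeps whichever result scores best.

The blockface anchor is what prevents the "banana effect": with the anchor
weight set to zero the same pipeline, seeded with a sinusoidal bending,
amplifies the bending severalfold, which `inject_bending()` and
`centroid_deviation()` demonstrate directly.

## Volume assembly

Each measured section is resampled exactly once, through its final
composed transform, onto the blockface grid. Per channel, slices are then
intensity-matched by chained least-squares gain/offset fits against the
already-matched predecessor (linear on purpose: histogram or nonlinear
matching would distort the staining intensities; the first slice anchors
the chain so the dynamic range is preserved, at the cost of a small
residual drift). Per-stain sampling gaps are filled by guided nonlocal
means: a missing pixel is the weight-normalized average of the same pixel
in measured slices within the search depth, weighted by
`exp(-D/h²)` where `D` is the patch-mean squared difference in the guide
volume (the blockface by default) — contrast is inferred across stains
from shared geometry. Defaults: patch radius 2 px, search depth 3 slices
(matching the densest 1:3 sampling), `h = 0.2 ×` the guide range, fixed by
phantom experiments. Slices beyond the search depth are filled from the
nearest measured slice and flagged `"missing"`; all interpolated slices are
flagged in the provenance map.

## MRI alignment

`register_volume()` resamples the (400-µm) MRI onto the 200-µm blockface
grid, initializes with an exhaustive translation search, and runs three
deformable stages with strictly decreasing field smoothing (default σ 6,
3, 1.5 voxels), each initialized from the previous — direct low-
regularization registration is unreliable across these contrasts, while
the staged schedule is. The same conditional-mean demons force is used in
3D, with an optional exclusion mask zeroing unreliable regions such as
ventricles (implemented as the large interior holes of the blockface
mask). A practical limit worth stating: with piecewise-constant contrasts
the method recovers deformations whose correlation length is at the block
(centimeter) scale; fields much rougher than ~2.5 mm at 3-voxel amplitude
exceed the default schedule's capture, because tissue interiors carry no
intensity gradient to follow.

## QC and microstructure maps

Reconstruction quality is summarized by interslice distances: the
symmetric mean contour distance (average nearest-point distance between
two boundary contours, both directions, in µm; Hausdorff is carried as a
secondary column) and the mean distance of greedily matched vessel
centroids, computed for consecutive same-stain pairs and for nearest
cross-stain pairs. Blockface features are excluded from QC, since
background separation on real blockface images is the least reliable step.
Records above a threshold (default 2 mm) are flagged; that is the regime
of genuinely missing structure (torn or lost tissue) rather than
misregistration. Because no external reference values exist for these
distances, the package's checks are recovery-based on the phantom rather
than comparisons against published numbers.

Orientation mapping interprets the "shape tensor" as the classical 2D
structure tensor: Gaussian-derivative gradients (σ 1 px), outer product,
window smoothing (σ 3 px). The reported orientation is the angle *along*
oriented structure — the minor eigenvector of the gradient tensor — in
degrees modulo 180, with anisotropy `1 − λ₂/λ₁`; pixels with negligible
gradient energy are flagged undefined. Aggregation to the blockface grid
averages anisotropy-weighted unit tensors (never angles, avoiding the
0/180 wrap), after reorientation by the local Jacobian of each section's
transform. Vessel density accumulates warped vessel masks across all
stains of a slice, divides by the contributing-section count, and smooths
with a mass-preserving Gaussian; values are volume fractions in [0, 1].

## The phantom

`build_phantom_dataset()` generates the study conditions every test runs
against: a 128×128×60 volume at 200 µm isotropic; an approximately convex
"brain" (a perturbed ellipsoid, elongated along the cutting axis so that
the outline changes by well under a voxel across one or two sampling
intervals, as within a coronal block of a hemisphere); four tissue classes
from thresholded band-limited noise; eight non-intersecting vessel tubes
(radius 2–4 px) running along z with bounded wander, kept strictly
interior to the tissue; five stains with distinct class-to-intensity
profiles at interleaved sampling (the densest at 1:3, four more at 1:6
with staggered offsets, so every slice carries at least one stain); a
sixth, different profile for the undistorted blockface; tissue noise (SD
5, ~5% of the class contrast); a linear intensity drift of 0.5 per slice;
and per-section distortions of mean magnitude 10 px (2 mm) from
Gaussian-smoothed noise (σ 24 px, chosen so that such amplitudes remain
invertible; the generator rescales and warns if a draw would fold) plus
affine jitter (±2°, ±3 px). Damaged slices, when listed, are omitted from
the stains but kept in the blockface.

What the phantom does *not* model — cellular-scale texture, staining
inhomogeneity within a section, tears and folds, freezing artifacts, true
anatomy — bounds what passing tests show: they demonstrate that the
pipeline recovers known geometry under realistic sampling, contrast, noise
and distortion statistics, not that it handles every pathology of real
material. Determinism is strict: a spec plus seed reproduces the dataset
bit-for-bit, and the package never disturbs the caller's RNG stream.

## Problem sizes used by the test and acceptance runs

Unit tests run on 48–64 px phantoms with about ten slices. The end-to-end
recovery checks use the default phantom above (60 sections, three
forward-backward cycles), a 64×64×30 single-stain phantom for the
banana-effect experiment, and 48×48×24 volumes for the MRI stage — sizes
chosen so the full suite completes on a single CPU in well under half an
hour while still exercising every stage at realistic ratios of distortion
to structure.
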