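---
title: "Methods: automated midbrain nuclei segmentation from NM-MRI and QSM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated midbrain nuclei segmentation from NM-MRI and QSM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The substantia nigra pars compacta (SNpc) loses neuromelanin (NM) early in
Parkinson disease while iron accumulates in the substantia nigra (SN) as a
whole; the red nucleus (RN) and subthalamic nucleus (STN) are further
iron-rich midbrain nuclei of clinical interest (the STN is the usual deep
brain stimulation target). A magnetization-transfer multi-echo GRE
acquisition yields, from a single scan, an NM-sensitive magnitude image
(short echo) and the phase data from which a quantitative susceptibility
map (QSM) is reconstructed (second echo). NM-bright tissue comprises SNpc
plus the ventral tegmental area (VTA); the iron-rich SN comprises SNpc plus
pars reticulata (SNpr). Their overlap, after subtracting the VTA,
identifies the SNpc:

SNpc = (NM \\ VTA) ∩ SN_iron.

`midbrainseg` implements a fully automatic pipeline: QSM reconstruction,
deformable-template mapping of midbrain structure boundaries into a new
subject, threshold preparation, and a dynamic-programming active-contour
("DPA") refinement that locks the mapped boundaries onto the individual's
own NM and iron features. No manual tracing is involved at segmentation
time; manual input enters only when a template bundle is built from real
data (template boundaries are operator tracings there; on synthetic
cohorts they are ground truth).

## QSM reconstruction

The chain is `unwrap_phase()` → `sharp_filter()` → `iterative_tkd()`.

* **Phase unwrapping** is quality-guided region growing: voxels are
  committed in decreasing order of a local quality measure (negated sum of
  squared wrapped second differences) and each voxel is unwrapped
  congruently against the committed neighbour that reached it first, so
  the output always equals the input modulo 2π voxelwise. A Laplacian
  unwrapper would be faster but violates that congruence guarantee, which
  the rest of the chain (and our tests) rely on.
* **SHARP background removal** uses spherical-mean-value filtering
  (spherical kernel, radius 6 voxels) followed by truncated deconvolution
  of `(1 - FFT(kernel))` at threshold 0.05, valid on the mask eroded by
  the kernel radius. Harmonic fields sourced outside the head obey the
  mean-value property and are annihilated. The discrete mean-value
  identity only holds well for fields that are smooth at the kernel
  scale; a point source a voxel or two from the mask is not removed
  cleanly, while realistic extended background sources at ≥ 2 kernel
  radii are suppressed to well below 1% RMS.
* **Dipole inversion** divides the local-field spectrum by the unit dipole
  response `D(k) = 1/3 - k_z'^2/|k|^2` where `|D| >= 0.1` and by
  `sign(D) * 0.1` elsewhere (TKD). The iterative refinement (4 iterations)
  re-estimates the ill-conditioned cone `|D| < 0.1` from the forward model
  of the current map thresholded at 10% of its maximum, keeping the
  measured, well-conditioned spectrum fixed; on a 100 ppb sphere phantom
  this lifts interior recovery from ~90 ppb to ~100 ppb and removes most
  streaking variance. Radians convert to ppb through
  `chi = phase / (gamma * B0 * TE)` with defaults γ = 2.675e8 rad/s/T,
  B0 = 3 T, TE = 15 ms; SHARP output stays in radians and the scaling is
  applied once, at inversion.

Skull stripping is out of scope: the brain mask is an input.

## Template construction and mapping

A designated best case defines the reference frame. Each further subject is
mapped to it globally (over the central 50 slices), the volume is cropped
to 16 slices around the midbrain, zoomed ×4 in-plane, and locally deformed
onto the best case's zoomed crop; the aligned NM and QSM blocks are
voxelwise averaged. The average acts as a probability map whose edges are
sharper than any single subject's. Boundaries live on the 0.167 mm
isotropic grid obtained by 12-fold slice interpolation of the 2 mm crop
(192 slices); `template_isotropic()` materializes that volume on demand.

The crop placement for a new subject uses the red nucleus anchor: the
reference RN slice span is carried through the global transform; if the
mapped RN occupies two slices the lower becomes crop slice 10, if three
the middle one. Boundary mapping carries every template contour through
the local transform, down to original resolution, and onto the nearest
subject slice, each structure only within its contrast's slice window.
The slice windows are stored per bundle and computed from the boundary
content (for 2 mm acquisitions the NM window is conventionally around
slices 44-98 of 192 and the QSM window around 44-126).

**Registration backend.** Registration numerics are deliberately pluggable
behind `registration_backend()`; they are not this package's contribution.
The reference backend fits an in-plane affine (rotation, anisotropic
log-scale, shear, translation) plus a through-plane translation by
Nelder-Mead on a sum-of-squared-differences metric at two sampling levels
(an integer slice-shift scan provides the z initialisation), then a
diffusion-regularized demons stage estimates a dense in-plane displacement
field (default 40 iterations, Gaussian σ 2.5 px, 1 px/iteration step cap,
light 1-2-1 mixing across slices). We chose a dense demons field over a
B-spline control grid because it is simpler to implement exactly and its
inverse (fixed-point iteration) satisfies the same sub-quarter-pixel
round-trip contract. The local stage runs at half the display zoom (×2)
and is conjugated to ×4 coordinates — the DPA, not the registration, is
responsible for the final edge-locking, so sub-pixel registration accuracy
at full zoom buys nothing.

## Threshold preparation

* NM: the background mean and SD are measured in background ROIs mapped
  from the template; the floor is `mean + 4 * SD` (the SD may be a
  cohort-calibrated constant; otherwise the subject's own). Signal below
  the floor is zeroed. NM contrast is expressed as
  `100 * (S - bg_mean)/bg_mean` (%), the normalization under which the
  5/7/8% gates are defined.
* QSM: negative susceptibilities inside a mapped boundary are zeroed, an
  Otsu threshold (256 bins, between-class variance; argmax plateaus
  resolved at their midpoint) is computed from the ROI and capped at
  30 ppb, sub-threshold pixels are zeroed, and the boundary is shrunk to
  the largest connected component of the surviving support.
* Gating (`gate_structure()`) retains pixels above a contrast or
  susceptibility gate and reports `volume_loss = 1 - V_gated/V_ungated`,
  which is non-decreasing in the gate by construction.

## The dynamic-programming boundary refinement

Each refinement iteration: (a) zero sub-floor pixels and add a constant
offset (default 1000) to the surviving signal — the offset makes the step
against zeroed background dominate any interior texture, so a small, safe
search radius suffices and the contour cannot leak far; (b) rasterize the
current boundary and thin the enclosed supra-floor region to its
centerline (Zhang-Suen, run to convergence, idempotent); (c) erect one
profile per boundary vertex along the outward normal of the current
boundary, the outward sign anchored on the centerline, with
`2 * search_radius + 1` candidates at 1 px steps (search radius 6 at ×4
zoom); (d) solve a cyclic shortest path over the candidates.

Costs: the node cost is the negated per-profile-normalized outward
directional gradient magnitude, sampled with a one-pixel aperture
(`g(o) = v(o + 1/2) - v(o - 1/2)`), which peaks exactly at an ideal step
edge; the transition cost is `|Δoffset|/search_radius` plus `alpha` times
a dimensionless curvature — the ratio of a 5 px reference radius to the
circumradius of the candidate vertex triple. Profiles whose whole search
segment is featureless (zeroed background beyond a concave edge) receive
a gentle inward drift so the boundary can creep across gaps over the
iterations; on a globally constant image all node costs are equal.

The solver enumerates every start offset and runs a forward DP; with
curvature terms the DP state is the candidate pair of two consecutive
profiles. One of the two wrap-around curvature terms would require fixing
two start offsets (an extra factor K in runtime) and is omitted; the
solver is therefore exact for pairwise-cost graphs — verified against
exhaustive enumeration — and near-optimal with curvature. Ties break
toward the smaller absolute offset, then the smaller candidate index.
After the DP, each vertex is refined to sub-pixel precision by a parabolic
fit to the gradient peak (clamped to ±0.5 px).

Two details matter for exact area recovery on the noise-free rectangle
phantom (35 × 40 px, area 1,400): profiles keep their identity across
iterations (the previous solution's vertices are the next anchors, making
a converged boundary a fixed point — re-resampling each pass lets corners
drift), and profile spacing is ~1 px (`n_profiles = max(64, perimeter)`;
at 2 px spacing the polygon chronically cuts one pixel per right-angle
corner). At CNR 7:1 the recovered area is within a few tenths of a percent
of truth across seeds. The crescent ("moon") phantom converges in 15
iterations but not 5 — wide featureless spans across its concavity are
crossed only by the per-iteration inward creep — mirroring the published
behaviour of the method on that shape; the adaptive-Otsu option
re-estimates the floor each pass for the same purpose.

The curvature weight α is compared across values the way the original
figures do: from a common converged boundary, one refinement pass per α.
Mean absolute discrete curvature of the resulting DP vertex chain is
non-increasing over α ∈ {0.05, 0.10, 0.15, 0.20}. (Curvature of the
subpixel-refined polygon at 1 px vertex spacing measures sub-pixel jitter,
an order of magnitude above the structural curvature, and is insensitive
to α; the DP chain is the object the constraint governs.)

## Fully automatic segmentation

`segment_subject()` runs: global map → RN-anchored crop → ×4 zoom → local
map → boundary mapping → background statistics and NM floor → per
structure, per hemisphere, per slice refinement. The RN is refined first
and its interior blanked when the SN is refined — with the template
boundary this prevents the SN leaking into the abutting RN; the refined SN
(and RN) are blanked for the STN. The VTA is carried as a mapped
anatomical prior, not refined (its boundary has no NM or iron edge to lock
onto), and enters the SNpc derivation. A structure whose support collapses
under thresholding (e.g. all-zero susceptibility data) is reported as a
per-structure error; the remaining structures, including NM, are still
segmented.

## Synthetic cohorts: what they emulate and what they do not

`make_midbrain_phantom()` builds a 64×64×64 voxel (0.67×0.67×2 mm) subject:
crescent SN (χ ~ N(125, 20) ppb over 5 slices), ovoid RN (N(100, 15), 2-3
slices), small STN (N(110, 15), 2 slices above the RN top), an NM-bright
blob at 5-10% contrast over a 1,000 a.u. background covering the anterior
SN and medial VTA territory, background boxes, and Gaussian noise (10 a.u.
on NM — i.e. NM CNR ≈ 5-10 — and 10 ppb on QSM). The nominal means anchor
to reported healthy-control values (SN ≈ 125 ppb). Per-subject anatomy is
a smooth random warp (≈2.5° rotation SD, 2.5% scale SD, 1.5 px shifts,
±0.7 px sinusoidal displacement, ±1 slice shift) applied analytically to
the boundary polygons, so the ground truth is exact. Per-hemisphere truth
volumes (NM ≈ 256, SN ≈ 350, RN ≈ 120, STN ≈ 61 mm³) sit in the range of
reported adult values. An optional low-susceptibility notch inside the SN
emulates a nigrosome-like gap.

The phantoms do **not** emulate: partial-volume and through-plane blur,
bias fields, anatomy-dependent background texture, vessels, the true
inter-digitated SNpc/SNpr boundary, or inter-subject variability beyond
smooth warps. Passing the cohort criteria therefore demonstrates that the
pipeline's machinery (mapping, anchoring, thresholding, refinement,
bookkeeping) is correct under controlled conditions, not that real-data
accuracy matches the published cohort values, which require the original
MRI data.

## Problem sizes and numerical choices

Test and validation problem sizes were chosen so the whole suite runs
comfortably on a laptop core: 64³ QSM phantoms, 64-slice cohorts with
five template and ten held-out subjects, 10-20 noise seeds for stochastic
checks. Degenerate inputs are contracts, not silent fallbacks: empty
masks, constant inputs to Otsu, collapsing structures, non-invertible
crops all raise typed errors naming the structure and stage. All
randomness flows from explicit seeds; every generator is reproducible
bit-for-bit for a fixed seed.

## Known limitations

* The DPA is strictly 2D per slice; no through-plane surface coherence.
* The cyclic solver is exact only for pairwise costs; with curvature one
  wrap seam term is approximated.
* SHARP uses a fixed kernel with eroded validity (no variable-kernel
  treatment near the mask edge).
* The reference registration backend is SSD-based and assumes
  single-modality alignment of NM images; swap in a stronger backend via
  `registration_backend()`'s contract for real multi-site data.
* The STN/SN anterior interface is resolved by the mapped template
  boundary alone, as in the source method; no extra logic is invented.
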