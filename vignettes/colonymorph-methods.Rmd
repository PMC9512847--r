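---
title: "Methods: morphometric trajectory analysis of laterally confined colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometric trajectory analysis of laterally confined colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological setting and what the package computes

When fibroblasts are grown on small adhesive rectangles (29 µm × 116 µm,
about 3300 µm²), lateral confinement forces each colony to grow upward into
a spheroid rather than spreading out. Over roughly ten days these colonies
undergo a cell-state transition: nuclei soften and shrink, heterochromatin
decondenses, lineage markers (Vimentin, Lamin A/C) fall while
pluripotency-associated markers (Oct4, H3K9 acetylation, alkaline
phosphatase) rise. Not every colony makes it: some arrest proliferation
mid-way, and the population bifurcates into successful and transient
(arrested) outcomes.

`colonymorph` implements the complete image-derived analysis of such an
experiment:

1. **3D segmentation** of the colony envelope (actin channel, Gaussian blur
   + Otsu) and of individual nuclei (DNA channel, anisotropy-aware Euclidean
   distance transform + h-maxima seeded 3D watershed).
2. **Morphometry**: volume, surface area, sphericity, bounding-ellipsoid
   elongation and flatness, Feret diameters, distance-to-surface statistics,
   projected area/circularity/aspect ratio; per-nucleus heterochromatin
   volume (mean + 1.5 SD threshold) and Haralick co-occurrence textures.
3. **Composite indices**: the Colony Growth Index (CGI; PCA → LDA) and the
   Chromatin Reorganization Index (CRI; same recipe on nuclear features).
4. **Trajectory inference**: a diffusion map over colony morphology,
   pseudotime in [0, 1] from a day-0 root, three-branch detection by
   k-means in diffusion space, and Nyström projection of held-out colonies.
5. **Phenotype assays**: EdU-based proliferation calls (a colony is
   proliferating if at least one nucleus is EdU-positive) and brightfield
   alkaline-phosphatase quantification by colour deconvolution against the
   stain vector (0.65, 0.40, 0.64), positive above mean activity 0.5.
6. A **synthetic colony generator** that renders full multi-channel 3D
   stacks with planted ground truth, so every stage above can be validated
   end to end.

## The synthetic study: what is planted, and why

Because no imaging data are publicly deposited for this experimental
system, the package ships a generator that emulates the study. Its
defaults are the study conditions; they were chosen once, on biological
grounds, and the validation suite runs against them.

**Progression coordinate.** Each colony carries a latent progression
`s ∈ [0, 1]`. Success-fate colonies advance linearly (`s = day/10`);
transient-fate colonies arrest growth at the day-4 state but keep a slow
residual chromatin/marker drift (0.015 per day), and pre-decision-fate
colonies pause earliest (0.008 per day after day 2). Arrest of
proliferation does not freeze chromatin remodeling entirely, which is why
the residual drift exists; it also keeps the planted progression strictly
ordered in time within every branch.

**Fates and expressed branches.** Fates are drawn i.i.d. with
probabilities (pre-decision 0.10, transient 0.22, success 0.68). These
follow from two observations in the source system: about 32% of colonies
are quiescent by day 8, and quiescence maps onto the non-success branches.
Separately from the fate, each record carries the branch *expressed* by
the colony's morphological state: `s < 0.35` is pre-decision (small
elongated, pattern-bound), `0.35 ≤ s < 0.55` is transient (small
spherical), and `s ≥ 0.55` is success (large spherical). A success-fate
colony therefore passes *through* the transient state around day 4 — which
reproduces the mixed day-4 branch composition of the real system, and
makes the expressed branch the right ground truth for branch-recovery
scoring: it is the only label the morphology can carry.

**Envelope geometry.** The morphological trajectory passes through the
three archetypes via two fairly sharp transitions: around `s = 0.35` the
colony releases the elongated micropattern footprint and contracts into a
round, still-flat colony; past `s = 0.55` it grows vertically into a domed
spheroid whose volume is three times the summed nuclear volume (nuclei
occupy about a third of a compact colony). Within each archetype a gentle
drift keeps the within-state ordering resolvable. The sharpness of the
transitions is what gives the population its three-cluster structure; the
within-state drift is what lets a single linear index still rank colonies
in time.

**Nuclei.** Nucleus shape interpolates from a flat, elongated fibroblast
nucleus (2.5 × 9 × 2 µm semi-axes) to a rounder, smaller one
(3.2 × 3.2 × 2.8 µm). Placement is rejection sampling with a
direction-dependent tangency constraint (0.95 of the summed ellipsoid
radii along the separation direction, with full restarts before any
relaxation), so nuclei pack near-tangentially with slight overlap — enough
to exercise the watershed split without making the planted counts
unrecoverable. In elongated colonies the nuclei align with the colony long
axis, as they do in confined elongated cells. The DNA stain is rendered in
a 0.90-scaled core of the nuclear ellipsoid: chromatin stops short of the
nuclear envelope, which is also what produces the faint boundary between
stacked nuclei in real stacks. Heterochromatin is planted as 2–6 bright
blobs per nucleus whose total volume is `(0.18 − 0.12 s)` of the nuclear
volume, strictly decreasing with progression.

**Proteins.** Planted colony means are exactly affine in `s`:
`baseline + slope · s + branch offset`. Oct4 and H3K9Ac rise, Vimentin and
Lamin A/C fall; E-cadherin and pMLC carry their contrasts through branch
offsets (transient keeps higher E-cadherin and pMLC than success). Oct4 is
additionally heterogeneous across nuclei with a branch-specific planted
coefficient of variation (success colonies are the most homogeneous). All
channels receive Gaussian read noise (SD 120 intensity units on a
baseline scale of thousands).

**What the phantom does not model.** No optics: no point-spread function,
photobleaching, or spectral bleed-through; protein channels are piecewise
constant plus noise rather than textured; colony shapes are convex
ellipsoids/boxes. Passing the recovery suite therefore demonstrates the
correctness of the measurement chain on geometrically faithful inputs, not
robustness to the full optical complexity of real microscopy.

## Numerical and methodological choices

**Sphericity.** Implemented as `(36 π V²)^{1/3} / SA`, the form for which
an ideal sphere scores exactly 1 (the commonly printed variant
`((4π V²)/(9 SA³))^{1/3}` evaluates to `81^{-1/3}` for a sphere and is
available behind a flag for comparability).

**Surface area.** Estimated by the coarea formula — the integral of the
gradient magnitude of the Gaussian-smoothed binary mask, with gradients in
physical units. This is exactly scale-equivariant, accurate to about 2% on
digital balls, and avoids any meshing dependency. Distance-to-surface
statistics use boundary voxels (6-connectivity border).

**"Moments 1–5".** Interpreted as the mean, SD and standardized moments
3–5 of the distance-from-centroid distribution of foreground voxels. This
is an interpretation (the original feature list does not define them) and
is documented as such.

**Feret diameters.** Support-function widths of the voxel-corner cloud
over a 600-direction Fibonacci lattice; the Feret diameter is the largest
width, the minimum Feret the smallest. For a rectangle this reproduces the
diagonal to sub-voxel accuracy.

**Nuclei segmentation.** The distance transform of flattened nuclei is
capped at their half-thickness, so the saddle between laterally touching
nuclei can be shallow; the h-maxima prominence default is therefore
0.5 µm, and seed components closer than 4 µm (well below a nucleus
diameter) are merged to suppress spurious splits from ragged boundaries.
The Otsu-thresholded-EDT seeding variant is available via `seed_mode`.
Objects below 50 µm³ are discarded as debris.

**Texture.** Grey-level co-occurrence matrices use 64 levels (min–max
binned within the nucleus), the four in-plane unit offsets (the z spacing
is several-fold coarser than xy), symmetric accumulation restricted to
voxel pairs inside the nucleus, and report IDM, entropy (bits),
correlation and contrast. Equality with a literal double-loop oracle to
1e-10 is part of the test suite.

**CGI/CRI.** Features are z-scored, reduced to the first three principal
components, and collapsed by LDA. The class labels are an early/late
median split of the day range rather than individual days: with per-day
classes, the near-noiseless day-0 class dominates the first discriminant
and the index stops tracking progression; the two-stage split keeps the
(then unique) discriminant on the progression axis. Per-day classes remain
available (`lda_classes = "day"`). The sign is fixed so the index
increases from day 0 to the latest day. CRI applies the identical recipe
to nuclear morphology and chromatin features and averages nuclei within a
colony.

**Per-replicate normalization** is min–max to [0, 1] within each
biological replicate (matching how heatmap panels are normalized);
constant columns map to 0.5 with a warning.

**Diffusion map.** Features are z-scored and reduced to the first 10
principal components, which keep their natural variance ordering
(rescaling them to unit variance would inflate pure-noise components and
drown the manifold). The Gaussian kernel (default width 0.8, the
literature value; the pipeline uses the median-distance heuristic since
0.8 lives on an unknown data scale) is density-normalized (α = 1) and the
symmetric normalized operator eigendecomposed. Pseudotime is diffusion
distance from the root (components weighted by λ/(1−λ)), min-max scaled to
[0, 1]; the automatic root is the colony nearest the day-0 centroid.
Branches are k-means (50 restarts, fixed seed) on the first three
nontrivial components, named deterministically: highest day-0 fraction →
pre-decision; of the rest, larger mean volume → success. Day-10 and
treated colonies are Nyström-projected rather than refitted, so the
embedding is a fixed reference frame; re-projecting a fitted colony
reproduces its coordinates to numerical precision.

**Regression.** `protein ~ CGI + day` by least squares on a seeded 70/30
split, with the coefficient of determination and Pearson correlation
reported on the held-out split only.

**Day-10 clustering.** Features with pairwise |r| > 0.9 are reduced
(first-of-pair kept, deterministic column order), then Ward linkage on
Euclidean distances of z-scored features, cut at k = 3.

**AP assay.** The brightfield chain is grayscale → CLAHE → local variance
filter → Gaussian smoothing → Otsu → hole filling → small-object removal.
The variance map is taken to the standard-deviation scale before
thresholding: on the variance scale edge strength grows with the square of
contrast, and a global Otsu cut silently drops faintly stained
(AP-negative) spheroids, which would make the positive fraction
unrecoverable. Colour deconvolution completes the single stain vector to
an orthonormal basis, computes per-pixel optical density against the
reference white with a 1/255 offset, and divides the stain-channel
concentration by a saturation OD of 1.0 so the 0.5 positivity cut is
dimensionless.

**EdU.** Per-nucleus mean EdU intensities are thresholded by a
*batch-level* Otsu across all colonies processed together; a
single-nucleus or constant batch falls back to a fixed absolute threshold
and the fallback is flagged in the output.

## Problem sizes used by the validation suite

The shipped tests and the acceptance script simulate 300 colonies (50 per
day across days 0–10) at a reduced-resolution canvas (0.6 × 0.6 × 1.2 µm
voxels; the generator's default spacing of 0.3 × 0.3 × 1.0 µm reproduces
the full 192 × 448 × 40 canvas). Branch recovery is additionally checked
across five independent simulation seeds at the feature level, where the
geometry is computed in closed form from the planted envelopes — orders of
magnitude faster than rendering voxels and statistically equivalent for
the trajectory modules.

## Known limitations

- Desk-scale colonies reach ~32 nuclei by day 10, versus hundreds in the
  real system; absolute volumes and their dynamic range are compressed
  accordingly, and the day-0 spread cell is volumetrically comparable to
  mid-course colonies (in the real system late spheroids dwarf single
  cells).
- The headline real-data figures of the source system (e.g. the ~60%
  AP-positive fraction at day 10, the published regression R² values, the
  n = 68 day-10 clustering) depend on unreleased imaging data and are not
  reproduced here; the package validates the machinery on planted truth
  instead.
- The watershed requires a faint intensity boundary between touching
  nuclei (present in real data and in the phantom); fully merged
  homogeneous objects cannot be split by any EDT-based method.
- LDA-based indices are linear; when a morphological trajectory curves
  strongly, the diffusion pseudotime (nonlinear) tracks progression better
  than the CGI, and the two are complementary outputs, not substitutes.
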