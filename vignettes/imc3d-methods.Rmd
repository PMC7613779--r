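---
title: "Methods: 3D single-cell analysis of serial-section imaging mass cytometry"
author: "imc3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D single-cell analysis of serial-section imaging mass cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Imaging mass cytometry (IMC) rasters a tissue section with a laser at
roughly 1 µm pixel pitch and quantifies 30–40 metal-isotope-tagged
antibodies per pixel by time-of-flight mass spectrometry. Cutting a block
into a ladder of consecutive 2 µm sections and imaging every section yields
an anisotropic multichannel volume (1 × 1 × 2 µm voxels) from which
individual cells can be reconstructed in three dimensions. `imc3d`
implements the computational half of that experiment: slice alignment, 3D
nuclear segmentation, single-cell quantification, phenotype clustering and
3D-versus-2D spatial statistics, plus a synthetic tissue phantom that makes
every stage testable without measured data.

This vignette records the models, the parameter choices and their
rationale, the numerical decisions, and what the phantom does and does not
emulate.

# Registration

Serial sections land on the slide with arbitrary in-plane offsets and small
rotations; cutting compression also changes apparent scale by a few
percent. We model the per-slice distortion as a 2D **similarity transform**
(rotation θ, isotropic scale s, translation t) — rigid enough to preserve
cell-level geometry, flexible enough to absorb mounting scale changes.
Deformable registration is deliberately out of scope.

Per slice pair, the estimate proceeds in four steps:

1. **Per-slice histogram equalization** of the reference channel (a
   structural stain such as smooth muscle actin). Equalization is monotone,
   so it normalises acquisition-gain differences without reordering pixels.
2. **Blob keypoints**: difference-of-Gaussian extrema over a small scale
   pyramid (σ = 1.6·2^(k/2)), sub-pixel refined, with orientation-normalised
   4 × 4 × 8 gradient-histogram descriptors. Matches are accepted by the
   ratio-of-distances rule (rod = 0.86).
3. **RANSAC** with a rigid two-point hypothesis, inlier residual
   `max_epsilon` (default 10 px; a sweep utility selects it by maximising
   the mean correlation of consecutive aligned nuclear-channel slices over a
   centred ROI covering 25% of each dimension; ties go to the smallest,
   least permissive candidate). The final transform is a least-squares
   similarity fit to the consensus set.
4. **Correlation polish and guided re-matching**: a Nelder–Mead
   maximisation of the overlap Pearson correlation of the warped moving
   slice against the fixed slice re-seats the estimate (its achieved
   correlation is retained as the estimate's quality score); the final
   parameters then come from a least-squares refit on *guided* matches —
   with a transform in hand, every keypoint pair landing within 2 px is a
   correspondence regardless of descriptor ambiguity, which typically
   triples the correspondence count on blob-like imagery and sharply
   reduces fit noise.

## Chain adjustment

Composing 19 pairwise transforms random-walks small per-pair errors into a
visible drift of the far slices. `register_stack()` therefore also measures
next-nearest (skip-2) pairs — initialised from the composed adjacent
estimates and re-optimised by correlation against the *direct* slice pair —
and solves the whole chain by least squares: rotation/scale in complex-log
space (where composition is addition), then translations (linear once
rotations are fixed), with the first slice pinned to the identity.

Robustness is layered: (i) an adjacent pair whose feature matching finds no
consensus is retried with a relaxed ratio test and then by a coarse ±20°
rotation sweep refined by correlation, accepted only if the result actually
correlates; (ii) an adjacent estimate whose quality score falls far below
the stack median (a false feature consensus, typically with only 3 inliers)
is re-estimated by a ±24° rotation sweep around it; (iii) skip-2
measurements enter the least-squares adjustment only when their overlap
correlation is credible relative to the adjacent pairs, which cleanly
separates good skip estimates (correlation ≈ 0.4–0.5) from false consensus
(≈ 0.1–0.2). On phantoms corrupted with |θ| ≤ 10°, |t| ≤ 15 px and scale
0.97–1.03 this recovers every slice within 0.5° and 1.5 px.

All channels are then warped with the same per-slice transforms (bilinear
for intensities, nearest-neighbour for masks) onto the union canvas, and
downstream analysis is restricted to the maximal axis-aligned box inside
the intersection of all warped footprints (a manual override box is
accepted, matching practice on real data where the crop is chosen by eye).

# Nuclear segmentation

Segmentation uses only the iridium DNA intercalator, which keeps the
pipeline independent of the antibody panel. The recipe:

1. **Artificial mean slices.** Between each pair of consecutive 2 µm
   sections an artificial plane equal to their voxelwise mean is inserted,
   giving ~1 µm isotropic voxels (n real slices → 2n−1 planes). Artificial
   planes are used for segmentation only and are dropped before any
   measurement.
2. **Clip + sqrt-histogram equalization.** Raw counts are clipped at 50 to
   remove bright outliers, then equalized with a cumulative mapping built on
   the *square roots* of the histogram counts (with the top 0.3% of pixel
   mass saturated). The square root is a compromise between classical
   equalization (which over-amplifies background) and none. One histogram is
   built for the whole stack so slices keep their relative brightness.
3. **Background cutoff.** Equalization amplifies background noise, so
   pixels below a cutoff are zeroed. The cutoff is *dataset-specific and has
   no default*: it must be chosen by inspecting the equalized image. For the
   default phantom we use 31500 — chosen once from the equalized histogram,
   where raw counts ≤ 2 (background and marker bleed-through) map below
   ~30700 and genuine nuclear signal maps above ~31800.
4. **CLAHE + local contrast normalisation.** Contrast-limited adaptive
   histogram equalization (tile 29 px, slope 10, 256 bins) followed by a
   local mean/s.d. normalisation (block radius 10 px, ±3 s.d. mapped to the
   16-bit range) makes the watershed input insensitive to residual
   slice-to-slice staining variation; perfectly flat neighbourhoods are
   passed through unchanged so blank regions stay blank.
5. **3D median (3³) + 3D Gaussian (σ = 1),** then a per-slice
   **difference of Gaussians** (σ 2 − σ 3), the classic blob enhancer at
   nuclear scale. Negative responses are clamped to zero — 16-bit image
   arithmetic clamps at zero, and without clamping the background would sit
   mid-range, making a small background threshold meaningless — and the
   volume is rescaled so its maximum hits 65535, keeping the watershed
   parameters on a defined scale.
6. **Hierarchical watershed.** Seeds are regional maxima surviving
   h-maxima suppression (dynamics ≥ h; default 5% of the 16-bit range — the
   plugin this emulates does not document a value, so h is an explicit
   parameter) and exceeding the background threshold (500). Flooding
   assigns every above-background voxel to a seed basin (6-connectivity,
   priority flood); each basin is then cut at
   L = p − 0.9·(p − 500), p the seed peak — one concrete reading of a "90%
   flooding" rule, also exposed as a parameter. The implementation is
   validated voxel-for-voxel against an independent brute-force oracle
   (max–min-path seed dynamics by fixpoint relaxation; frontier flood).
7. **Post-processing**, in order, after dropping artificial planes:
   (1) objects ≤ 10 voxels removed; (2) objects disconnected in-plane keep
   only the largest component per slice; (3) all labels expanded by 1 px
   in-plane into background (Euclidean distance 1 → the 4-neighbourhood;
   collisions go to the nearest label, ties to the lower id — the tie rule
   is our choice, the sources do not state one); (4) objects < 21 voxels
   removed; (5) objects with mean *raw* iridium < 1 count removed. Finally
   the overlap crop is applied and labels are renumbered from 1.

The expansion step means the pipeline delineates **cells** (nucleus plus a
pixel of cytoplasm), not bare nuclei — which is also why the phantom's
object-recovery ground truth is the whole-cell partition (below).

Internal quantisation is 16-bit throughout (the alternative, 8-bit
histograms inside the equalization steps, is not used).

# Single-cell measurement

Hot pixels — isolated staining/detection artifacts — are suppressed per
channel before measurement: a pixel exceeding the maximum of its 8
neighbours (centre excluded; borders use available neighbours) by more than
50 counts is set to that maximum. The operation is idempotent and never
increases a pixel.

Per cell and channel the mean raw ion count over the cell's voxels is
recorded, along with the centroid (physical µm, z at 2 µm spacing), voxel
volume, and the mean major/minor second-moment axis lengths in the x–y and
x–z planes (an isotropy diagnostic: spheres should score similarly in
both).

**Spillover compensation** operates on the per-cell means (not pixels),
solving x·S = o per cell by non-negative least squares, where S is the
supplied channel-crosstalk matrix. NNLS rather than plain inversion keeps
compensated means non-negative — they feed percentile normalisation and
marker cutoffs downstream, where negative values would be meaningless.
Whether the original workflow used constrained or unconstrained inversion
is not documented; for well-conditioned matrices and interior solutions the
two coincide (the round-trip test requires 1e-6 relative accuracy).

# Phenotyping

Marker expression is range-normalised per channel to the 99th percentile
over all cells (a type-1, order-statistic percentile, which makes the
normalisation exactly idempotent; values are clipped at 1, an unclipped
variant is a flag), so every marker weighs equally. Cells are clustered on
the k-nearest-neighbour graph (k = 10, Manhattan distance) with edges
weighted by the Jaccard overlap of neighbour sets, by Louvain modularity
maximisation under a fixed seed.

The Louvain **resolution** deserves care. A k-NN graph whose k is far
below the phenotype sizes always carries local neighbourhood substructure,
and at resolution 1 modularity maximisation provably prefers splitting a
planted phenotype (on a two-blob benchmark the split partition scores
modularity 0.74 against 0.50 for the true one). At the catalogue sizes this
package targets (hundreds to thousands of cells per phenotype, k = 10) a
fixed resolution therefore over-partitions. By default the resolution is
selected from a fixed grid (0.01–1) by the mean silhouette width of the
resulting partition on the same Manhattan distances, ties to the coarser
partition — an automatic, label-free criterion; passing a numeric
resolution pins it instead. Cells in singleton communities are labelled −1
(outliers). The nuclear channel is excluded from clustering by default in
the pipeline configuration; channel selection is always explicit, since
which channels the original analysis excluded is not fully documented.

# Spatial statistics

**Vessel masks.** The summed endothelial channels are min-max normalised
per slice, blurred (σ = 1) and thresholded by maximising Rényi entropy. We
port the three-estimate procedure of Sahoo et al. (1997) — entropic
thresholds at orders 0.5, 1 and 2 combined by the published weighting —
because that is the algorithm behind the ImageJ implementation the field
uses; a pure Kapur (order-1) mode is available. Thresholds are computed on
a 256-bin histogram. Blank slices yield empty mask planes rather than
errors.

**Distances.** 3D: Euclidean distance from the 3D centroid to the nearest
mask voxel. 2D: per slice the cell occupies, distance from that slice's
footprint centroid to the nearest same-slice mask pixel, minimised over the
cell's slices; slices with empty mask planes are excluded (all excluded →
missing). Physical spacing (dz = 2 µm) is applied by default; a voxel-unit
mode reproduces pixel-index geometry since the original analysis does not
state whether z was scaled. 2D distances can only overestimate: the 3D
minimiser is available to every cell, so per-group mean 3D ≤ mean 2D.

**Direct neighbours.** The region adjacency graph uses face connectivity
(6 in 3D, 4 in-plane), background never counts. Entry (a, b) of the
proportion matrix is the fraction of cluster-a cells' touching neighbours
that belong to cluster b; rows with ≥ 1 neighbour sum to 1. In 2D mode,
adjacency is evaluated on every slice plane of the same 3D mask and counts
are accumulated over slices before normalising — so a pair in contact over
many slices is counted once per slice. That is exactly the mechanism by
which slice-wise analysis inflates homotypic contact: elongated same-type
neighbours stay in contact across many planes. The 3D−2D difference matrix
makes the comparison explicit.

**Microenvironment queries** return all non-query cells whose centroid
lies within a fixed radius (inclusive) of any query-cell centroid, with the
per-cluster composition; a query cell is never its own neighbour. Whether
the 50-unit radius of the motivating analysis was meant in pixels or
micrometres is ambiguous in the sources; the spacing applied to centroids
is therefore a parameter. Marker gating (`normalised expression > cutoff`,
strictly) provides machine support for manual curation steps.

# The phantom

The generator emulates the *structure* of serial-section IMC data:

- ellipsoidal nuclei (axis anisotropy ≤ ~1.4, axis-aligned) of four cell
  types with breast-carcinoma-like frequencies and marker signatures; all
  types share the iridium signal; markers occupy the nucleus plus a 1.5 µm
  cytoplasmic halo so membrane-type markers are non-trivial;
- tubular vessels emitting in the endothelial and smooth-muscle channels;
- integration of the 1 µm voxel volume into 2 µm sections as the mean of
  the two constituent planes — the simplest model consistent with full
  ablation of the section;
- per-slice multiplicative gain jitter (0.85–1.15), per-slice similarity
  misalignment (off by default; enabled in registration tests), adjacent-
  isotope spillover (4%/1%), Poisson counting noise, and optional hot
  pixels.

The default volume is 150 × 150 × 44 µm (22 sections) with 700 nuclei — a
confluent-tissue density (nuclear volume fraction ≈ 11%) at which
neighbouring cells actually touch. Density matters: the watershed
parameters and the direct-neighbour statistics both presuppose abutting
cells, and a sparse phantom would exercise neither realistically.

Ground truth includes the nucleus label volume, the **whole-cell
partition** (nucleus + halo, contested halo voxels to the nearest nucleus)
— the right reference for a pipeline that deliberately dilates masks into
cytoplasm — the per-cell table, true alignment transforms, and the vessel
mask. Object recovery is scored by greedy IoU matching (recall, precision,
mean IoU, split/merge counts) at IoU ≥ 0.3.

What the phantom does **not** emulate: detector physics (dead time,
isotopic impurity spectra), tissue deformation and tearing, section-loss
artifacts, autofluorescence-like background structure, nuclear texture
(chromatin), and irregular cell shapes. Passing tests on the phantom
therefore demonstrate the pipeline's internal correctness and its
robustness to the modelled corruptions — not segmentation accuracy on real
tissue, which the original work assessed visually.

# Problem sizes and seeds

The test-suite and acceptance-script problem sizes are chosen as the
smallest that still exercise each property meaningfully: 100 random 16³
landscapes for the watershed oracle, a 20-slice misaligned phantom for
registration recovery, the 700-cell default phantom for segmentation and
spatial statistics, 2000 cells for clustering recovery, and a 230-cell
phantom for the end-to-end determinism check. Every stochastic step runs
behind a single seed; the acceptance script derives all of its seeds from
its `--seed` argument.

# Known limitations

- Feature descriptors are weak on images whose only texture is a few
  equally-shaped blobs; the rescue sweep and chain adjustment compensate,
  but stacks with almost no structural reference signal may still fail to
  register.
- The flooding-restriction formula is one reading of an undocumented
  plugin behaviour; a different reading changes object sizes (not counts).
- NNLS compensation is per-cell-mean only; pixel-level compensation is out
  of scope.
- 2D neighbour proportions depend on slice-wise accumulation; alternative
  per-slice averaging schemes would give slightly different matrices.
- The sectioning model ignores partial-volume asymmetry and section-to-
  section thickness variation.
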