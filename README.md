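# imc3d — three-dimensional imaging mass cytometry analysis

Imaging mass cytometry (IMC) quantifies 30–40 metal-isotope-tagged
antibodies per ~1 µm pixel by laser ablation and time-of-flight mass
spectrometry. Imaging a ladder of consecutive 2 µm sections of one tissue
block yields an anisotropic multichannel volume from which individual
cells can be reconstructed in 3D. `imc3d` is an R implementation of that
computational workflow, for labs building 3D single-cell tissue models
from serial-section IMC (or comparable multiplexed imaging) data:

- **Registration** — per-slice 2D similarity transforms
  (q = s·R(θ)·p + t) estimated from blob-keypoint correspondences
  (ratio-of-distances matching, RANSAC, least-squares fit, correlation
  polish), with the alignment-error tolerance selected by
  cross-correlating consecutive aligned nuclear-channel slices, and a
  least-squares chain adjustment over adjacent and skip-2 slice pairs that
  damps composition drift.
- **3D nuclear segmentation** — artificial mean slices to ~1 µm isotropic
  voxels; clipping + sqrt-histogram equalization; explicit background
  cutoff; CLAHE + local contrast normalisation; 3D median + Gaussian;
  per-slice difference of Gaussians; hierarchical (h-) watershed
  (seed dynamics h, background 500, 90% basin flooding); five-rule mask
  post-processing (size ≥ 21 voxels, in-plane connectivity, 1 px
  expansion, raw nuclear mean ≥ 1) and overlap cropping.
- **Single-cell measurement** — hot-pixel suppression (Δ > 50 over the
  8-neighbour maximum), per-cell channel means, centroids, volumes, axis
  lengths; spillover compensation of the means by non-negative least
  squares (x·S = o).
- **Phenotyping** — 99th-percentile range normalisation; k-NN (k = 10,
  Manhattan) Jaccard graph; Louvain clustering; z-scored cluster profiles.
- **Spatial statistics, 3D versus 2D** — Rényi-entropy vessel masks;
  centroid-to-vessel distances in 3D and slice-wise 2D; region-adjacency
  direct-neighbour proportions and their 3D−2D difference;
  radius-based microenvironment queries; marker gating.
- **Tissue phantom** — a synthetic serial-section generator (ellipsoidal
  nuclei of four cell types, vessel tubes, gain jitter, misalignment,
  spillover, Poisson noise, hot pixels) with full ground truth, so every
  stage is testable without measured data.

## Worked example

Generate a phantom, segment it, and compare against ground truth:

```r
library(imc3d)

ph <- generate_phantom(phantom_spec(), seed = 7)
ph$stack
#> ImageStack: 6 channel(s) x 22 slice(s) (22 real, 0 artificial, 0 missing)
#>   size: up to 150 x 150 px, spacing (1, 1, 2) um
#>   channels: Ir191, SMA, vWF, panCK, CD45, CD68

labels <- segment_nuclei(ph$stack$data$Ir191,
                         preprocess_params(background_cutoff = 31500),
                         watershed_params())
max(labels)
#> [1] 699

m <- match_objects(ph$truth$cell_labels_sections, labels, iou_threshold = 0.3)
unlist(m$metrics[c("recall", "precision", "mean_iou")])
#>    recall precision  mean_iou
#> 0.9985714 1.0000000 0.7364393
```

699 of the 700 planted cells are recovered (recall 0.999) with no spurious
objects (precision 1.0); the mean intersection-over-union of matched
objects is 0.74. From here, `measure_cells()` + `compensate_spillover()`
build the per-cell catalog, `normalize_p99()` + `cluster_cells()` assign
phenotypes, and `distance_to_structure()` / `neighbor_proportions()`
produce the 3D-versus-2D spatial statistics; `run_pipeline()` chains all
stages from one configuration with provenance capture
(`inst/cli/imc3d.R` wraps the phantom generator and the pipeline for shell
use).

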