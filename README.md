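# colonymorph

Image-derived analysis of **laterally confined fibroblast growth**: when
single fibroblasts are seeded on small adhesive rectangles (29 µm × 116 µm,
≈3300 µm²), confinement forces the growing colony upward into a spheroid and
drives a cell-state transition over ~10 days — nuclei soften, heterochromatin
decondenses, Oct4 and H3K9Ac rise while Vimentin and Lamin A/C fall. The
population bifurcates along the way: some colonies progress ("success"),
some arrest proliferation ("transient"), and early colonies sit in a shared
"pre-decision" state.

`colonymorph` is an R package for quantifying that process from 3D confocal
stacks, plus a synthetic colony generator with planted ground truth so the
entire chain can be validated end to end. It provides:

- **3D segmentation** — colony envelopes by Gaussian smoothing + Otsu
  thresholding of the cytoskeletal channel; individual nuclei by an
  anisotropy-aware Euclidean distance transform with h-maxima seeds and a
  seeded 3D watershed (all physical-unit aware, written in Rcpp).
- **Morphometry** — volume; surface area; sphericity
  `(36πV²)^{1/3}/SA` (exactly 1 for a sphere); bounding-ellipsoid
  elongation `b/a` and flatness `c/a`; Feret and minimum Feret diameters;
  distance-to-surface statistics; projected area, circularity, aspect
  ratio; per-nucleus heterochromatin volume above the
  `mean + 1.5·SD` threshold; Haralick co-occurrence textures (IDM,
  entropy, correlation, contrast); per-channel protein summaries and
  Voronoi proxy-cell volumes.
- **Composite state indices** — the Colony Growth Index (CGI: z-score →
  PCA → first 3 components → LDA → oriented first discriminant) and the
  Chromatin Reorganization Index (CRI: same recipe over nuclear features),
  per-replicate min–max normalization, protein ~ CGI + day regression with
  held-out R², and Ward clustering of day-10 colonies after a
  correlation filter.
- **Trajectory inference** — a density-normalized diffusion map on the
  first 10 principal components of colony morphology, pseudotime in [0, 1]
  from a day-0 root, three-branch detection by k-means in diffusion space
  with deterministic naming (pre-decision / transient / success), branch
  composition tables, and Nyström projection of held-out colonies.
- **Phenotype assays** — EdU proliferation calls (a colony proliferates if
  at least one nucleus is EdU-positive, batch-level Otsu threshold) and
  brightfield alkaline-phosphatase quantification by colour deconvolution
  against the stain vector (0.65, 0.40, 0.64), positive above mean
  activity 0.5.
- **A synthetic study generator** — multi-channel 3D stacks (DNA, actin,
  six protein channels, EdU) across a 0–10-day time course with planted
  branches, progression, protein trends, heterochromatin blobs and
  proliferation flags; brightfield AP phantoms; lossless 16-bit TIFF + CSV
  + manifest export.

## Worked example

Simulate one day-8 success-branch colony at a reduced-resolution canvas and
measure it:

```r
library(colonymorph)

cfg <- generator_config(voxel_spacing = c(0.6, 0.6, 1.2))
col <- generate_colony(cfg, day = 8, branch = "success", seed = 42)
fx  <- extract_colony_features(col$image)

fx$colony[, c("n_nuclei", "volume", "sphericity", "elongation",
              "feret", "min_feret")]
#>   n_nuclei   volume sphericity elongation  feret min_feret
#> 1       16 8735.472       1.01      0.996 27.225    25.625

col$truth$n_nuclei        # 16   (all 16 planted nuclei recovered)
col$truth$planted_oct4    # 4700 (planted colony-mean Oct4)
fx$colony$mean_oct4       # 4701.5 (measured from the rendered stack)
```

A day-8 success colony is a near-spherical spheroid (sphericity ≈ 1,
elongation ≈ 1, Feret ≈ diameter); the measured Oct4 mean recovers the
planted value to noise precision.

The full pipeline — simulate, segment, features, indices, trajectory, AP
assay, report — runs from a single config:

```r
cfg <- pipeline_config(out_dir = "run", seed = 1,
                       generator = list(voxel_spacing = c(0.6, 0.6, 1.2),
                                        n_colonies_per_day = 50),
                       trajectory = list(kernel_sigma = "auto"))
res <- run_pipeline(cfg)
res$metrics   # segmentation IoU, count accuracy, CGI/pseudotime
              # correlations, branch ARI, assay fractions vs planted truth
```

A thin command-line wrapper is installed at `inst/cli/colonymorph.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/colonymorph.R", package = "colonymorph"))')" \
  --config cfg.yaml --seed 1 --out run/
```

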