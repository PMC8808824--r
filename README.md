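# cartiquant

Automated quantitative analysis of knee articular cartilage from 3D MRI,
for imaging scientists running longitudinal cartilage studies (e.g.
osteoarthritis progression or cartilage-repair monitoring). Starting from
bone and bulk-cartilage segmentation masks plus a T2 relaxation map,
the package automates the whole downstream chain:

* **anatomy** — partition of the cartilage mask into the standard 21
  subregions (6 patellar, 6 tibial, 9 femoral) and stratification into
  three depth layers — deep, transitional, superficial — as equal thirds of
  the normalized depth `f = d_BCI / (d_BCI + d_surf)` along the axis from
  the bone–cartilage interface (BCI) to the articular surface, computed
  with exact anisotropy-aware Euclidean distance transforms in mm;
* **registration** — 12-DOF affine coregistration of the coarser T2 map
  onto the morphological grid by normalized mutual information under a
  seeded (1+1) evolutionary optimizer with pyramid and sub-voxel polish,
  plus a windowed similarity-index map as quality marker;
* **quantification** — per (subregion × layer): voxel count, volume
  (mm³), distance-transform thickness `t = d_surf + d_BCI − s̄` (mm), and
  mean T2 within the physical window [5, 150] ms;
* **texture** — the 7 cartilage GLCM features (autocorrelation, contrast,
  correlation, dissimilarity, energy, entropy, homogeneity) from flattened
  ROIs: 16 gray levels, offset 1 parallel to the cartilage surface,
  symmetric matrix, averaged across slices;
* **statistics** — Dice `2|A∩M|/(|A|+|M|)` and Jaccard `|A∩M|/|A∪M|`
  segmentation agreement, test–retest reliability `SEM = SD(d)/√2`,
  `SDC = 1.96·√2·SEM`, layer-wise agreement tables, and pooled-variance
  t comparison of lesional vs lesion-free segments;
* **phantoms** — a synthetic knee generator (slabs, analytic
  curved shells, a three-compartment knee; laminar T2 profiles, focal
  low-grade lesions, test-retest replicates, boundary-perturbed masks)
  with bit-reproducible seeds and full ground truth, so every stage is
  validated by parameter recovery.

Volumes and label maps are read and written as NIfTI (via RNifti), feature
tables as CSV, configuration sidecars as YAML.

## Worked example

A 4.5 mm cartilage slab on a bone substrate, painted with the healthy
laminar T2 profile (deep 22.3, transitional 26.8, superficial 33.9 ms)
plus 1 ms noise, then pushed through depth-field, layer and T2 extraction:

```r
library(cartiquant)

spec  <- phantom_spec(shape = c(20, 20, 16), spacing = 0.5,
                      cartilage_thickness_mm = 4.5, bone_thickness_mm = 1)
ph    <- make_slab(spec)
depth <- compute_depth_field(ph$labels$values == 2L,
                             ph$labels$values == 1L, spacing = spec$spacing)
layers <- assign_layers(depth)
region <- label_map(array(as.integer(ph$labels$values == 2L),
                          dim(ph$labels$values)),
                    c(cartilage = 1L), spacing = spec$spacing)
t2 <- paint_t2_laminar(ph$labels, depth, t2_profile("layers"),
                       noise_sigma = 1, seed = 7)
region_mean_t2(threshold_t2(t2), region, layers)
#>   subregion        layer n_voxels mean_t2_ms
#> 1 cartilage         bulk     3600      27.68
#> 2 cartilage         deep     1200      22.30
#> 3 cartilage transitional     1200      26.81
#> 4 cartilage  superficial     1200      33.93
```

The three layers hold exactly a third of the cartilage each, and the
extracted layer means recover the painted 22.3 / 26.8 / 33.9 ms to within
the noise. Thickness and segmentation agreement behave the same way:

```r
thickness_map(depth)
#> <thickness_map> mean 4.5 mm (range 4.5 .. 4.5)

dice_jaccard(ph$labels, perturb_mask(ph$labels, 0.2, seed = 1))
#>   region jaccard  dice
#> 1    all    0.91 0.953
```

And a 13-subject test–retest vector yields the reliability pair used
throughout:

```r
set.seed(2)
v1 <- rnorm(13, 27.7, 2.7); v2 <- v1 + rnorm(13, 0, 1.2)
sem_sdc(v1, v2)[c("sem", "sdc")]
#> $sem  1.32...   $sdc  3.67...   # SDC = 1.96·√2·SEM exactly
```

The full pipeline (`run_pipeline(pipeline_config(...))`) chains phantom →
registration → partition → extraction → reliability for a whole cohort and
writes per-visit feature tables, a reliability report and a run manifest.

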