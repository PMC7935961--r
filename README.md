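# tmeprofiler

Automated 3D profiling of the tumour microenvironment in cleared whole
organs, for groups doing light-sheet fluorescence microscopy (LSFM) of
optically cleared tissue bearing fluorescently labelled metastatic cancer
cells and microenvironment markers (α-SMA vessels, VEGFR3 lymphatics, Iba1
macrophages, CD42c platelets). The package turns multi-channel 16-bit
volumes into quantitative spatial statistics without manual intensity
thresholds, and ships a synthetic phantom generator with voxel-level ground
truth so every stage can be validated on a desk machine.

## What it computes

1. **Pixel classification.** A bank of Gaussian-derivative filter responses
   — Gaussian smoothing at σ ∈ {0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10} px, and
   Laplacian of Gaussian, Gaussian gradient magnitude, difference of
   Gaussians, structure-tensor eigenvalues and Hessian eigenvalues at
   σ ∈ {0.7, …, 10} px (61 features in 3D) — feeds a random forest trained
   on sparse voxel annotations of four classes: *signal*, *Z-axis signal
   leakage*, *autofluorescence*, and *background*. The forest returns a
   per-voxel probability vector `P(c | x)`, binarized at `P(signal) ≥ 0.5`
   (or by arg max).
2. **Object extraction.** 3D connected components (26-connectivity by
   default) of the binary mask; per colony the centre of gravity
   `c = mean(v · s)` over member voxels `v` with spacing `s` (μm), the voxel
   count, and the physical volume `n · s_z s_y s_x` (μm³).
3. **Spatial statistics.** Per-object minimal 3D Euclidean distance to a
   target structure (kd-tree nearest-neighbour query, exact), the ECDF
   `F(x) = #{d ≤ x}/n`, Gaussian kernel density curves with Scott's-rule
   bandwidth and mode detection, distance-band fractions
   `#{lo < d ≤ hi}/n`, and the 20 μm co-localization rule: a source object
   is co-localized when its centroid lies within 20 μm of a target centroid.
4. **Segmentation validation.** Sørensen–Dice `2|A∩B|/(|A|+|B|)`, Jaccard
   `|A∩B|/|A∪B|`, and Szymkiewicz–Simpson `|A∩B|/min(|A|,|B|)` between an
   automated and a reference mask.
5. **Estimation statistics.** Percentile bootstrap 95% CI of the mean
   difference between two groups (Gardner–Altman style) and the unpaired
   t-test with Welch's correction.

## Worked example

```r
library(tmeprofiler)

# a 64 x 128 x 128 phantom at 10 x 6.5 x 6.5 um: 20 colonies, 2 vessel
# trees, 30 puncta, axial leakage under half the colonies, 2 autofluorescent
# tubes, Poisson + Gaussian noise
ph  <- generate_phantom(phantom_spec(), seed = 11)
fs  <- compute_feature_stack(ph$channels$cancer)      # 61 features
ann <- sample_annotations(ph$truth, "cancer", 200, seed = 12)
mod <- train_pixel_classifier(fs, ann, seed = 13)
pm  <- predict_probabilities(mod, fs)
mask <- binarize_probability(pm, "signal", 0.5)

evaluate_segmentation(mask, binary_mask(ph$truth$labels$cancer == 1,
                                        ph$truth$spacing))
#> <overlap_scores> dice = 0.9665, jaccard = 0.9351, overlap = 0.9979
#>   (|A| = 4459, |B| = 4187, |A&B| = 4178)

tab <- extract_objects(label_components(mask))
summarize_objects(tab, "cancer")
#> <colony_summary> [cancer] count = 20, total volume = 1883927.5 um^3

vessel <- binary_mask(ph$truth$labels$vessel == 1, ph$truth$spacing)
ds <- min_distance_to_mask(tab, vessel)
fraction_within(ds, 100)        # fraction of colonies within 100 um
#> [1] 0.35
```

The overlap scores say the learned signal mask agrees with the ground-truth
colony voxels to Dice 0.96; the colony count recovers the 20 simulated
colonies; the distance fraction is the per-colony minimal-distance statistic
used to relate metastases to vessels.

The same run is available as one call from a config:

```r
cfg <- pipeline_config(
  input = list(phantom = phantom_spec()),
  analysis = list(distance_pairs = list(
    list(source = "cancer", target = "vessel", mode = "to_mask"))),
  out_dir = "run1", seed = 17)
man <- run_pipeline(cfg)   # writes masks, tables, CSVs, results.json, manifest
```

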