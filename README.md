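# syncytrack

Quantitative analysis of nuclei in 3D time-lapse microscopy of syncytial
embryos.

In the early fly embryo, nuclei divide synchronously in a common cytoplasm;
histone-GFP time-lapse recordings of this stage are the standard way to
study division defects, karyotype changes and nuclear size control. Turning
such recordings into numbers takes a pipeline: 3D nuclear segmentation,
post-processing that separates touching nuclei, frame-to-frame tracking
with lineage reconstruction, and per-frame / per-track statistics.
`syncytrack` implements that pipeline downstream of any primary segmenter,
for researchers who need reproducible nuclear densities, growth rates,
ploidy calls and collision statistics from cortical nuclei — and a
synthetic benchmark to validate all of it without microscope data.

The core pieces:

* **Geometry** — nuclei as stacks of planar contours; one shared
  rasterization rule (voxel centres, even-odd) defines volume
  (µm³), centroids, silhouettes and intensity features under anisotropic
  voxels such as 0.1×0.1×0.44 µm.
* **Shape-split** — merged nuclei are cut along the shortest chord between
  two contour vertices satisfying three constraints (input area ≥ 700 px²,
  smaller-piece perimeter ≥ 70 px, cut/perimeter ratio ≤ 0.3), recursively;
  3D objects are rebuilt by ≥ 50% inter-plane overlap. Composite
  segmentation layers with provenance-tracked editing combine outputs of
  different segmentation runs.
* **Tracking** — bilateral nearest-neighbour assignment of ROI centroids,
  a lineage graph with degree-capped division (1→2) and collision (2→1)
  nodes, manual-edit support, automatic event detection with a volume
  consistency check, and recall/precision scoring against ground truth.
* **Quantification** — nuclear density ND = nuclei per 1000 µm² of the
  convex hull of their centroids; volume-to-hull ratio VHR = ΣV / hull
  area; two-phase growth regression (10 + 30 frames after anaphase, slopes
  in µm³/min, R², deceleration g1/g2); ploidy from mitotic volume; per-cycle
  reporter-intensity change; t-based and Wilson summary statistics.
* **Synthetic embryos** — a seeded generator of ground-truth scenes
  (synchronous cycles, anchored jitter with 1.41 µm mean displacement,
  anaphase jumps up to 15 µm, 4.5%-per-cycle mitotic collisions at a 25/75
  metaphase/anaphase mix, elimination, ploidy-proportional volumes,
  pool-limited two-phase growth with a VHR ceiling of 5.3, 29.5% per-cycle
  reporter gain) plus an ellipsoid renderer producing noisy image stacks.

## Worked example

Simulate a two-cycle embryo at the benchmark scale, track it, and quantify:

```r
library(syncytrack)

p <- sim_params(seed = 11, mbt_frames = 92)     # 122 frames, 121 pairs
scene <- simulate_scene(p)
scene
#> <sim_scene> 122 frames, 23325 nucleus-frames, 193 nuclei at last frame
#>   events: collision 2, division 190, elimination 59

frames <- lapply(seq_len(scene$n_frames), function(f) scene_frame(scene, f))
pred <- track_series(frames)                     # bilateral NN, all pairs
evaluate_tracking(pred, scene$links)
#> <tracking_metrics> TP 22920, FN 343, FP 42 | recall 98.5%, precision 99.8%
#>   displacement: mean 1.39 um, sd 0.72, median 1.29

fa <- scene$anaphase_frames[2]                   # last synchronized mitosis
nuclear_density(scene_frame(scene, fa + 6), frame = fa + 6, t_min = 5.5)
#>   frame   n hull_area       nd      vhr t_min
#> 1    36 251  9956.039 25.21083 2.049008   5.5

id <- scene_frame(scene, scene$n_frames)$id[1]
tr <- scene$nuclei[scene$nuclei$id == id, ]
growth_fit(c(rep(NA, fa), tr$volume[order(tr$frame)]),
           anaphase_index = fa, track_id = id)
#> <growth_fit> track 195: g1 12.00 um^3/min (R^2 1.000), g2 2.74 um^3/min (R^2 0.959), deceleration 4.4

summary_stats(k = 22, n = 26)                    # a proportion with Wilson CI
#> <stat_summary> 22 / 26 = 84.6%, 95% Wilson CI [66.5%, 93.8%]
```

Reading the numbers: the tracker misses links almost only at the two
synchronous divisions (a mother has two daughters but a nearest-neighbour
pair can hold one); 5.5 min after the last anaphase the density is ~25
nuclei/1000 µm²; the fitted track grows at 12 µm³/min early and 2.7 µm³/min
late (deceleration 4.4), the signature of rapid DNA-driven assembly
followed by competition for a finite maternal factor pool.

Image-based stages work the same way on rendered or real stacks:
`threshold_segment()` → `split_layer()` → `bilateral_nn()` /
`build_lineage()` → `detect_events()`. A thin command-line front end with
`simulate`, `segment`, `split`, `track`, `evaluate` and `quantify`
subcommands lives in `inst/cli/syncytrack.R`.

The methods vignette (`vignettes/syncytrack-methods.Rmd`) documents the
models, parameter choices and limitations in detail.

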