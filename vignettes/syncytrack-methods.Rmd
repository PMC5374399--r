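---
title: "Methods: nuclear tracking and quantification in syncytial embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclear tracking and quantification in syncytial embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(syncytrack)
```

# Scope

`syncytrack` quantifies the dynamics of cortical nuclei in 3D time-lapse
fluorescence recordings of syncytial embryos: it post-processes a primary
nuclear segmentation (separating touching nuclei), tracks nuclei across
frames, detects divisions and mitotic chromosome collisions, and derives
population statistics — nuclear density, the volume-to-hull ratio, two-phase
interphase growth rates and per-cycle reporter-intensity changes. Because
suitable public recordings of this kind do not exist, the package ships a
synthetic embryo generator that produces ground-truth scenes and renders
them as image stacks, so every stage can be benchmarked quantitatively.

# Geometric conventions

A nucleus is a `roi3d`: a stack of planar contours (`polygon2d`) on
consecutive focal planes plus derived features. All measurements share one
rasterization rule: a voxel belongs to an ROI when its centre — at physical
position $((i-\tfrac12)s_x,(j-\tfrac12)s_y,(k-\tfrac12)s_z)$ for voxel
index $(i,j,k)$ and voxel size $(s_x,s_y,s_z)$, e.g. $0.1\times0.1\times
0.44\ \mu m$ — lies inside a plane polygon under the even-odd rule, with
boundary-touching centres counted as inside. Volume is the enclosed-voxel
count times the voxel volume; the centroid is the mean physical position of
the enclosed voxel centres; intensity features (sum, mean, population sd)
are computed over the same voxel set. Contours extracted from binary masks
are rectilinear outlines of the pixel cells, so rasterizing a traced contour
recovers its pixel set exactly — volumes are identical whether computed from
voxels or from the saved contour files.

The paper-level definition of volume (voxel counting versus per-plane area
integration) was genuinely open; we fixed voxel counting because it gives a
single reproducible rule shared by segmentation, overlap tests and
intensity extraction. A merged pair of touching nuclei is one 26-connected
component and is kept as one ROI; on planes where its lobes are disjoint it
carries more than one contour. Interior holes of a cross-section are not
represented.

# Shape-split post-processing

Under-segmentation (two nuclei in one ROI) is corrected by a 2D shape-split
applied to every plane contour of ROIs within a volume range (default
10–1000 $\mu m^3$). The algorithm cuts along the **shortest chord between
two non-adjacent contour vertices** that (1) lies strictly inside the
polygon, (2) leaves the smaller output piece with perimeter at least 70 px
(7 $\mu m$ at 0.1 $\mu m$ pixels, chord included), and (3) has length at
most 0.3 times that perimeter; the input polygon must have area at least
700 px². Splitting recurses on both pieces, applying all three constraints
at every level, until no piece admits a cut. Equal-length chords are broken
by the lexicographically smallest vertex-index pair; "shortest" is
Euclidean pixel distance. Restricting chord endpoints to contour vertices
keeps the search finite and matches the contour representation; requiring
strict interiority (the chord may not touch the boundary) is our resolution
of the concave-polygon ambiguity. The implementation prefilters candidate
chords with closed-form piece areas/perimeters from cumulative sums and
verifies interiority only for survivors; a test suite checks it against an
independent exhaustive chord-search oracle on random ≤16-vertex polygons.

Cut pieces are reassembled into 3D objects by joining polygons on
consecutive planes whose rasterized overlap is at least 50% of the smaller
polygon; connected components of the join graph become ROIs. Joins are
applied in decreasing overlap order and a join that would give one ROI two
polygons on a plane is skipped, so reconstructed (split) objects are
single-lobed by construction.

Composite segmentation is represented by `layer_set`: named ROI layers per
frame plus a curated composite initialised from one layer; `substitute_roi`
removes objects and pulls replacements from other layers, recording
provenance and rejecting additions that overlap an existing composite
object by more than half of the smaller silhouette.

# Tracking and event detection

Frame-to-frame assignment is a **bilateral nearest-neighbour search** on 3D
centroids (Euclidean distance in microns, z included): a link is kept only
when each endpoint is the other's nearest neighbour. The default distance
gate is infinite, mirroring the interactive workflow; ties go to the lower
ROI id. The lineage graph caps in-degree and out-degree at 2 (collision and
division); automated links can be corrected by an explicit edit log, and an
auto-merge rule links an unmatched predecessor to a successor whose
silhouette contains its centroid — the metaphase-fusion signature.
Anaphase-fusion links, which the original workflow created manually, are
supplied as edits.

Divisions are out-degree-2 nodes. In-degree-2 nodes are accepted as
chromosome collisions only when the child volume matches the summed parent
volumes within 35% — chosen to accommodate the volume change between
condensed mitotic figures and reforming telophase nuclei while rejecting
segmentation merges of interphase nuclei, whose summed volume is far larger;
failures are flagged as suspect merges. Each collision is annotated
metaphase (fused node itself in metaphase) or anaphase (parents in
anaphase). The per-cycle collision fraction counts two involved nuclei per
event among the nuclei *entering* that cycle; a metaphase-fused figure is a
mid-cycle stand-in for its parents and is not an entrant, whereas an
anaphase-fused nucleus is an entrant of the next cycle. Tracking accuracy
is scored against ground-truth links as recall and precision, with every
parent–daughter link of a division counted separately.

# Population statistics

*Nuclear density* (ND) is the number of gate-passing nuclei (volume
10–1000 $\mu m^3$, centroid depth 0–25 $\mu m$ below the shallowest plane)
per 1000 $\mu m^2$ of the convex hull of their x-y centroids; all
gate-passing ROIs of a frame are used, not only tracked ones. The
*volume-to-hull ratio* (VHR) divides the summed gate-passing volume by the
same hull area — a tracking-free proxy for the nuclear-to-cytoplasmic
ratio. Time series are aligned to the last synchronized mitosis, detected
as the last frame whose division events (±2 frames) affect at least 80% of
the nuclei present; density at mid-blastula transition is read 5.5 minutes
after that anaphase.

*Growth* is quantified by ordinary least squares of volume on time in two
consecutive windows after anaphase — 10 frames (9.1 min at 55 s) and the
following 30 frames — giving slopes $g_1$, $g_2$ in $\mu m^3/min$, per-window
$R^2$ and the deceleration $g_1/g_2$. The early-window length was described
both as 7 min and as 10 frames in the source material; we default to 10
frames and expose it as a parameter. *Ploidy* is classified from mitotic
volume as the rounded ratio to a haploid reference (the mode of the
metaphase volume distribution, robust to karyotype mixtures); ratios with
fractional part in (0.35, 0.65) are flagged low-confidence. *Reporter
accumulation* is measured as the percent change, between consecutive
cycles, of the mean intensity over frames 3–8 after each anaphase.
`summary_stats` reports sample means with t-based 95% confidence intervals
and one-sample t-tests, and proportions with Wilson score intervals
(sample sd uses $n-1$; voxel intensity sd uses $n$).

# The synthetic embryo generator

`sim_params()` / `simulate_scene()` emulate the cortical layer of a
syncytial embryo recorded at 55 s intervals. Defaults, and what they
emulate:

* **Field and density** — a 100×100 $\mu m$ field with 64 nuclei dividing
  synchronously twice (15 frames per cycle, then 44 interphase frames),
  ending near 26 nuclei/1000 $\mu m^2$, the density regime of the observed
  embryos. Nuclei are clamped to the field: the cortical layer fills the
  imaged view, which is also why the hull is stable across a division.
* **Motion** — nuclei jitter about fixed anchors (cortically tethered
  nuclei do not diffuse), with per-axis sd $1.41/\sqrt{\pi}\ \mu m$ so the
  frame-to-frame displacement magnitude has mean 1.41 $\mu m$. A Gaussian
  step cannot simultaneously match the reported median of 0.9 $\mu m$; we
  match the mean. After each division the anchors relax by a short
  deterministic repulsion (rest length $0.95\sqrt{A/n}$), emulating the
  regular packing produced by aster-mediated spacing.
* **Division** — daughters are displaced from the mother along a random
  axis by 15–50% of the 15 $\mu m$ anaphase cap, so anaphase jumps reach up
  to 15 $\mu m$ per frame. The last three frames of each cycle are
  prophase, metaphase and anaphase; mitotic figures have volume
  $20\,\mu m^3 \times$ ploidy and are rendered condensed and twice as
  bright.
* **Collisions** — per cycle, a Binomial($n$, 0.045) draw (rounded to the
  nearest even count with a fair coin) marks the involved nuclei; half of
  them seed an event with their nearest free neighbour, never a sibling of
  the same mitosis, and each event is anaphase with probability 0.75.
  Metaphase events fuse the two figures into one that divides with summed
  ploidy; anaphase events fuse one daughter of each mother at the
  ploidy-weighted midpoint. Only pairwise fusions are generated (observed
  triple fusions are not modelled). Interphase nuclei never fuse.
* **Growth** — interphase volume starts at $25\,\mu m^3 \times$ ploidy and
  grows at $g_1 = 12\,\mu m^3/min$ per ploidy unit for the first 9 minutes
  (DNA-content-driven assembly). Afterwards growth draws on a shared
  maternal nuclear-assembly-factor pool: total uptake per minute is 0.075
  times the unexhausted pool, $5.3 \times \text{hull area} - \sum V$,
  allocated in proportion to ploidy and never exceeding the phase-1 rate.
  A strictly bilinear phase 2 with a hard VHR cap cannot reproduce the
  observed convergence of VHR to ~5.3 from densities between 12 and 42
  nuclei/1000 $\mu m^2$ within the hour of cellularization; the
  pool-depletion form converges from any density, keeps late growth
  proportional to ploidy, and remains near-linear within the 30-frame
  fitting window (matching the imperfect phase-2 linearity of real tracks).
  At the default density the fitted deceleration is ≈4, inside the
  observed 2.9–9.6 range.
* **Elimination and intensity** — after the last division each nucleus is
  removed with probability 0.003 per frame (the observed gradual loss of
  cortical nuclei), and the reporter intensity rises by the factor 1.295
  per nuclear cycle.

`render_stack()` draws each nucleus as a volume-matched oblate ellipsoid
(overlaps resolved by maximum), adds a constant background and Gaussian
noise. It does **not** model the point-spread function, photobleaching,
depth attenuation or cellularization membranes; nuclei centred on the field
edge are clipped, as in a real field of view. Consequently, passing
benchmarks demonstrates the correctness and calibration of the analysis
machinery under realistic geometry, motion and event statistics — not
robustness to optical artefacts of a particular microscope.

All randomness flows from one mandatory seed through R's global stream, so
scenes, renders and all written files are bit-reproducible.

# Numerical choices and edge cases

Degenerate polygons (<3 vertices, zero area), empty ROIs, hulls with fewer
than 3 eligible or non-collinear points, growth windows extending past a
track and intensity requests for missing channels raise errors naming the
offending object. Writers emit fixed 6-decimal numbers and `\n` endings, so
identical inputs give byte-identical files. Orientation tests snap cross
products below $10^{-9}$ to zero so collinear grid points are handled
exactly. The collision volume tolerance (0.35), the auto-merge silhouette
rule and the nearest-neighbour tie-break (lower id) are fixed, documented
defaults rather than tuned values.

# Problem sizes

The shipped tests and the acceptance script run, on one CPU in a few
minutes: a 122-frame tracking benchmark (~23,000 ground-truth links, the
scale of the original validation set); ~16 three-cycle collision scenes
(~17,000 nucleus-cycles, ~400 events); and rendered end-to-end checks on
small fields (≤60 $\mu m$, voxel $0.25\times0.25\times0.5\ \mu m$) where
exact volume recovery is verifiable. Full-resolution rendering
($0.1\,\mu m$ pixels over hundreds of microns) is supported but not
exercised in tests for time reasons.

# Known limitations

* One ROI may carry several contours on a plane only as a *merged-object*
  representation; reconstruction after splitting enforces one per plane.
* The bilateral NN tracker has the expected failure modes at divisions
  (one daughter per mother) and position swaps; the edit log exists for
  exactly that reason.
* Anaphase fusions are not auto-detected from images alone (their
  in-degree-2 signature requires a manual or truth-derived link), matching
  the original interactive workflow.
* The generator's displacement distribution matches the reported mean, not
  the heavy-tailed median/mean ratio of real embryos.
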