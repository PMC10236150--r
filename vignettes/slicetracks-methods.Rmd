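---
title: "Quantifying immune-cell migration in tumor slices and Matrigel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immune-cell migration in tumor slices and Matrigel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicetracks)
```

# The problem

Solid tumors such as triple-negative breast cancer are organised into
tumor-cell islets embedded in a fibronectin-rich extracellular matrix
(ECM). Whether cytotoxic lymphocytes (for example Vδ2⁺ γδ T cells)
reach the tumor cells depends on how they migrate through these two
compartments, which is studied by plating dye-labelled cells on living
tumor slices and recording multichannel confocal time-lapse stacks:
a cell-tracker channel for the immune cells, a fibronectin stain
marking the ECM, and an EpCAM stain marking tumor islets. A
complementary 3D assay embeds the cells in Matrigel and records a
single nuclei-stained Z-stack to measure how far they invade.

`slicetracks` implements the complete quantification chain for both
assays plus the closed-form cytotoxicity and caliper-volume formulas
used alongside them, and — because raw imaging data of this kind is
rarely deposited — a synthetic-scene generator that renders movies with
exact ground truth so that every stage can be validated end to end.

# The slice pipeline

The stages run in a fixed order; the provenance JSON written by
`run_slice_pipeline()` records every effective parameter.

1. **Drift correction** (`estimate_drift()`, `apply_drift()`). Bulk
   specimen motion is estimated from the ECM channel (maximum-projected
   over Z), which is static up to drift. Local intensity maxima of a
   lightly smoothed frame are matched to the next frame by nearest
   neighbour; the frame-to-frame translation is then refined *jointly*
   over all matched feature patches by minimising an interpolated
   sum-of-squared-differences on a coarse-to-fine subpixel grid
   (0.5 px, then 0.125 px, then a parabolic fit). The joint refinement
   matters: independent per-feature parabola fits exhibit "pixel
   locking" — a systematic shrinkage of fractional shifts toward
   integers — which accumulates over a movie; the joint estimator keeps
   the cumulative error below about 0.6 px over 40 frames at default
   noise where the per-feature version drifted by several pixels.
   Frames with too few matched features fall back to phase correlation.
   The transform family is pure translation (the slice rests on a
   static insert); a rotation column exists in the model for
   forward compatibility but is always zero. Out-of-field pixels after
   resampling become `NA`, never zero, and all later stages ignore
   them.

2. **Region masks** (`derive_region_masks()`, `load_region_masks()`).
   The reference workflow drew ECM regions by hand from the
   fibronectin staining, plane by plane; manual masks are therefore
   first-class inputs. When absent, masks are derived automatically:
   per plane, the ECM channel is median-projected over time
   (time-invariant regions, as in the manual workflow), thresholded
   with Otsu's method, morphologically closed, and cleaned of specks
   and holes smaller than `min_area` (default 25 µm²). Tumor is defined
   as the fibronectin-negative complement, so the two masks always
   partition the field — an invariant enforced by the constructor.
   Masks are derived *after* drift correction so they live in the
   corrected frame.

3. **Cell-channel preprocessing** (`correct_cell_channel()`). The ECM
   stain bleeds into the cell-tracker channel; the corrected image is
   `median_filter(max(cell − β·ecm − background, 0))` with a 3×3 median
   filter by default. The bleed coefficient β is estimated once per
   acquisition as the median pixelwise ratio of background-subtracted
   cell to ECM intensity over ECM-bright pixels — the median makes the
   estimate insensitive to the minority of pixels containing actual
   cells (recovery within ±0.02 of the generator's true coefficient in
   tests). The background is a robust per-frame floor (median of the
   lowest-intensity quartile), clamped non-negative because a
   background is an intensity.

4. **Detection** (`segment_frame()`, `filter_by_size()`,
   `collapse_z()`). Cells are segmented by intensity (Otsu default,
   fixed threshold optional) as 8-connected components, with binary
   centroids by default so positions are exactly testable. Components
   outside `[0.25, 2.5] ×` the nominal cell area (πr², r the nominal
   cell radius) are discarded as noise specks or clumps — the
   reference workflow removes clumps by size rather than splitting
   them. Cells apparent in more than one optical plane are collapsed
   to the plane of maximal area: detections of one frame in adjacent
   planes within one cell radius are grouped transitively and only the
   largest survives, ties broken deterministically by lower plane,
   then higher summed intensity.

5. **Tracking** (`link_tracks()`, `merge_tracks()`,
   `filter_min_length()`). Linking minimises total squared
   displacement per frame transition, solved exactly with the
   Hungarian algorithm, with links beyond `max_disp` forbidden
   (default 3× the expected step length) and a gap memory of 1 frame.
   Afterwards, two tracks are merged when the earlier track's final
   point and the later track's initial point are **less than 10 µm and
   less than 2 frames apart** — read strictly, so a start at
   end-frame + 1 merges and end-frame + 2 does not; boundary tests pin
   this. When several candidates compete the nearest pair in space
   wins and merging repeats to a fixpoint; observation count is
   conserved and the procedure agrees exactly with a brute-force
   oracle in tests. Merging runs *before* the length filter (otherwise
   mergeable 3+3 fragments would be discarded, defeating the rule's
   purpose); only tracks with **at least 6 observations** are kept.

6. **Metrics** (`momentary_speed()`, `classify_localization()`,
   `dwell_and_entry()`, `summarize_acquisition()`). Momentary speed is
   the distance between successive observations of one cell divided by
   the elapsed time (gaps use the actual elapsed time). A cell
   localises to tumor in a frame only when *no pixel* of its segmented
   footprint overlaps the ECM mask of its own plane — one overlapping
   pixel makes it ECM. Dwell fraction is the share of observed frames
   in tumor; `high_dwell` uses the inclusive reading (≥ 50 %, so 5 of
   10 frames qualifies) — the source material states both "at least
   50%" and "over 50%" in different places, and the inclusive reading
   is implemented and pinned by a boundary test. Each speed step is
   attributed to the compartment of its first observation (the source
   is silent on this; the generator uses the same convention, making
   recovery exact in expectation). Because it is ambiguous whether
   published compartment speeds pool momentary speeds or per-track
   means, the summary emits both.

# The Matrigel pipeline

`segment_nuclei_3d()` thresholds the Z-stack globally (Otsu default),
separates touching nuclei with a 3D watershed flooded from local
maxima of the anisotropic Euclidean distance transform (seeds closer
than one nucleus radius are pruned, strongest first — no canonical
seeding rule exists, so this one is documented and tested), and
`invasion_distances()` takes per-label centroids with
`z = plane_index × z_step` measured from the bottom plane (default
step 2 µm). The per-image baseline is the **10th percentile** of all
centroid z values, computed by linear interpolation between order
statistics (the common "type 7" convention; the convention is pinned
by a hand-computed example: z = 0, 10, …, 90 µm gives baseline 9.0).
Invasion distance is `max(z − baseline, 0)`, and `fraction_beyond()`
reports the fraction of cells strictly beyond each threshold
(default 10 and 100 µm, matching "further than"). By construction
roughly 10 % of cells get distance 0. The percentile is computed per
image, not pooled per well.

# Assay formulas

`specific_lysis()` normalises a test signal to the window spanned by
the spontaneous- and maximum-release controls. The two modalities
point in opposite directions — live target cells *emit* light
(bioluminescence: `100·(spont − test)/(spont − max)`) whereas lysed
cells *release* ⁵¹Cr (`100·(test − spont)/(max − spont)`) — and both
forms return 0 % at the spontaneous control and 100 % at the maximum
control, the anchors that fix the interpretation of the formulas.
Results outside [−25, 125] % are kept but flagged. `tumor_volume()` is
the sphere formula `V = 4/3·π·r³`; calipers measure diameter, so
`caliper_volume()` halves it first.

An outlier policy approximating the proprietary ROUT procedure
(Q = 2 %) is available in `summarize_acquisition()` as a robust MAD
z-score at the matched nominal rate; it is clearly an approximation,
not a replication, and is **off by default**.

# The synthetic world

`generate_slice_scene()` renders what the slice assay acquires: nine
optical planes spanning 63 µm (7.875 µm spacing), one frame every
30 s, three channels. Everything the acquisition protocol does not pin
down is fixed once at testable values and not tuned thereafter:

| parameter | default | rationale |
|---|---|---|
| field | 160×160 px at 1 µm/px | small enough for fast tests, large enough for islets |
| cells | 30, radius 4 µm | lymphocyte-sized, moderate density |
| speeds | 4 (tumor) / 2 (ECM) µm/min | the faster-in-tumor regime under study |
| persistence | 0.7 | persistent random walk, heading noise sd = (1−p)·π |
| islets | 2 discs, radius 30–50 µm | two-compartment geometry |
| drift | (0.5, 0.3) px/frame | subpixel, cumulative |
| bleed | 0.2 of ECM into cell channel | forces the correction stage to work |
| noise | Poisson (scale 1) + Gaussian σ = 10 | blobs ≳ 3σ above background so Otsu separates |

Cells keep a fixed step length `speed·Δt` with the speed chosen by the
compartment at the step's start, so emitted mean step lengths converge
exactly to `speed·Δt` (law-of-large-numbers test at 5 % with ≥ 500
steps); cells reflect at the field margin, which slightly bends paths
but leaves step lengths intact. Cells live on a single plane each (an
option renders dimmer "ghosts" in adjacent planes to exercise the
Z-collapse rule). Drift is applied to the image channels only; ground
truth stays in specimen (frame-1) coordinates, so the pipeline's drift
correction must map detections back into that frame to match.
The ECM channel carries a smooth multiplicative texture (clipped to
[0.5, 1.5]) — enough structure for feature matching while keeping the
full ECM mask above the Otsu threshold, so mask derivation is exact on
noise-free scenes. `generate_matrigel_stack()` renders 3D Gaussian
nuclei with explicit or random placement and a minimum-separation
option that errors out when infeasible.

**What a green test does and does not establish.** The generator
emulates geometry, motion statistics, drift, bleed-through and
counting noise; it does not model photobleaching, the optical PSF,
cell division or death, z-motion, or non-rigid tissue deformation.
Passing tests therefore demonstrate that the computational chain
recovers what it claims from data matching its assumptions — not that
those assumptions hold for any particular microscope.

# Numerical choices and degenerate inputs

* Pixel centers sit at `(index + 0.5)·pixel_size` (0-based indices);
  this convention is used by the renderer, the detectors and the mask
  lookup alike.
* Otsu thresholding uses 256 bins and ignores `NA` pixels; a constant
  image yields its minimum, so blank frames segment to nothing rather
  than erroring.
* The Euclidean distance transform uses a separable parabola-envelope
  scan with per-axis spacings (so the 2 µm z-step is honoured) and a
  large finite sentinel instead of infinity to keep the envelope
  arithmetic NaN-free.
* The watershed floods from seeds in increasing priority (−distance)
  with FIFO tie-breaking, making label assignment deterministic.
* Linking pads the cost matrix so that any feasible link (≤ max_disp)
  is always preferred over leaving both endpoints unmatched; Hungarian
  ties resolve deterministically in label order.
* All randomness in the generator flows from one integer seed, and the
  caller's RNG state is saved and restored.
* TIFF I/O is a deliberately minimal baseline codec (uncompressed
  greyscale multi-page, 8/16-bit unsigned and 32/64-bit float, both
  byte orders) because the target R stack ships no TIFF package; it
  interoperates with `tifffile` in both directions. Stack metadata
  (axis order TZYXC, calibration, channel roles) travels as JSON in
  the ImageDescription tag rather than OME-XML — the full OME schema
  would add much surface for no analytical gain here. Fancier TIFFs
  are rejected with clear errors rather than misread.

# Known limitations

* Fused cells are removed by the size filter, not split; very dense
  scenes will lose detections (and the tests use separated scenes for
  exactly that reason).
* Drift is translational; rotational or non-rigid specimen motion is
  out of scope.
* The localization rule is conservative near islet boundaries: a cell
  whose centre is inside tumor but whose footprint touches ECM counts
  as ECM, which slightly mixes fast tumor steps into the ECM speed
  pool on synthetic scenes (visible as a small upward bias of the
  recovered ECM mean, within the 10 % acceptance band).
* The MAD-based outlier option shares only the nominal Q with ROUT;
  results with it enabled are not comparable to Prism's.
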