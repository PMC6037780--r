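---
title: "Classifying fictive motor patterns from segmental calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying fictive motor patterns from segmental calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fictivemotor)
```

## The problem

An isolated larval *Drosophila* central nervous system keeps producing the
motor programs of crawling — "fictive locomotion". Calcium imaging of
segmental motoneurons along the ventral nerve cord (hemineuromeres T2-A7,
left and right, 18 ROIs) shows a small repertoire of recurring
spatiotemporal patterns:

* **FW** — forward waves, activity propagating posterior to anterior;
* **BW** — backward waves, anterior to posterior;
* **AT** — anterior bursts, often left/right-asymmetric, turn-related;
* **PT** — posterior bursts in the most posterior neuromeres;
* **QS** — quiescence; **UL** — anything else.

Scoring these patterns by hand is slow and subjective. `fictivemotor`
implements a data-driven classifier: short windows of the multi-ROI trace
are rendered as images, embedded with pooled deep-convolutional features,
clustered without supervision, and the clusters are mapped to motor
patterns from their average window images. A voxel-wise correlation
mapper then locates cells whose activity follows each pattern, and a
synthetic generator provides ground-truthed data so the whole pipeline is
testable without recordings.

## Preprocessing

Raw fluorescence `F(t)` per ROI is converted to a rectified, running-
baseline dF/F:

$$
\Delta F/F(t) \;=\; \Big(\tfrac{F(t)}{F_{base}(t)} - 1\Big)\,
\mathcal H\!\Big(\tfrac{F(t)}{F_{base}(t)} - 1\Big),
\qquad
F_{base}(t) = \tfrac1{16}\sum_{i=1}^{16} F(t-i),
$$

with $\mathcal H$ the Heaviside step. Only rising calcium signal is kept
(spiking coincides with the rising phase of the indicator), and the
16-frame running baseline absorbs slow drift and photobleaching. The
first 16 frames have no baseline and are dropped: a 2048-frame recording
keeps 2032 valid frames. Values above a cap (default 2, the value used
for motoneuron drivers, where dF/F occasionally explodes) are clipped.

The matrix is then min-max scaled to `[0, 1]` *globally* — one minimum
and maximum for the whole recording, not per ROI — so that relative
intensity between segments survives normalization; the burst-zone rules
below depend on it. A recording with no dynamic range at all maps to
zeros. Finally the 18 hemisegmental traces are compressed to 9 segmental
traces by the left/right maximum, so a pattern is detected on whichever
body side expresses it.

## Windows and images

The 9-trace series is cut into windows of 8 frames (centers `t` cover
`t-4 .. t+3`; centers run `4 .. T-5`, giving `T - 8` windows — 2024 for
2032 valid frames, leaving the trailing frame uncovered). Each `[9 x 8]`
window becomes a 72x72 8-bit image: values map to `floor(v * 255)`, rows
are time (each frame replicated 9 pixels), columns are segments anterior
to posterior (each replicated 8 pixels), and the gray image is copied to
3 channels. Integer block replication avoids any interpolation
ambiguity, and the encoding is monotone and invertible to within 1/255.

## Features

Each window image is embedded by a convolutional backbone tapped at
VGG-16's Conv4_3 layer: at 72-pixel input the tap produces 512 channels
on a 9x9 grid (three 2x poolings precede it), and global average pooling
over the 81 positions yields one 512-vector per window.

ImageNet-pretrained weights cannot be redistributed with this package,
and none of its computations may depend on a network connection, so the
default backbone is `vgg16-random`: the same architecture with
seed-deterministic He-initialized weights, implemented from scratch in
compiled code (im2col + single-precision GEMM). Random convolutional
features retain the spatial statistics this task needs — controlled
experiments with clean single-pattern windows separate forward from
backward waves perfectly — and make the whole pipeline bit-reproducible
from a seed. Users with a weights file can load it via
`build_backbone("vgg16-pretrained", weights_path = ...)`; a `blockmean`
backbone (mean over 8x8 pixel blocks, 81 dimensions) is a fast baseline
for smoke tests. Input preprocessing defaults to subtracting the
ImageNet channel means; a `raw` mode feeds 0..255 unchanged. Results are
independent of the forward-pass batch size.

## Clustering and labeling

Windows are clustered by Ward's minimum-variance linkage on Euclidean
distances and the tree is cut at 25 flat clusters (the analysis protocol
this follows inspected the first 20-30 clusters; 25 is the middle and is
exposed in the configuration). One design choice proved necessary here:
feature rows are scaled to unit length before the linkage. Pooled
convolutional activations scale with total image intensity, so without
normalization Ward stratifies windows by activation mass — wave windows
of opposite directions but similar intensity end up in the same cluster.
On the unit sphere the linkage groups windows by pattern shape instead;
quiescent windows still form tight clusters because a near-constant
image has a consistent feature direction. This is the one place the
package deviates from plain "Ward on pooled features", and it is
switchable (`cluster_windows(..., normalize = FALSE)`).

Each cluster is then summarized by the arithmetic mean of its raw
`[9 x 8]` windows, and the mean image is mapped to a label by rules that
mirror how an analyst reads such images, applied in order:

1. mean intensity below `theta_qs` → **QS**;
2. the intensity center of mass (in segment index), regressed on time
   with per-frame intensity weights, has |slope| above `theta_wave`
   *and* a weighted R² of at least `theta_r2` → **FW** if the flow runs
   toward anterior, **BW** otherwise;
3. a burst call requires genuinely burst-like activity: effective
   spatial width (participation ratio over segments) at least
   `theta_width`, mean intensity at least `theta_burst` — bursts are
   *high* intensity flooding their zone, and the faint, narrow remnant
   of a wave entering or leaving the recording must not qualify — and
   within-cluster coherence (energy of the mean window relative to the
   members' mean energy, a scale-free measure of how aligned the
   members are) of at least `theta_coherence_at` / `theta_coherence_pt`,
   because a low-coherence mean is a smeared mixture, not a burst. Then
   anterior-zone (T2-A4) mass fraction above `theta_at` → **AT**;
   posterior-zone (A4-A7) fraction above `theta_pt` → **PT** (A4 sits in
   both zones; if both rules fire the larger mass wins);
4. otherwise **UL**.

The R² gate exists because of a real failure mode: the repertoire's
strongest couplings are back-to-back transitions BW→AT and FW→PT, and a
window straddling such a junction shows intensity jumping between
distant body regions — which regresses to a steep center-of-mass slope
and would masquerade as the *opposite* wave. A genuine wave moves the
center of mass nearly linearly; a hand-off fits a line poorly. The
weights keep near-silent frames from steering the slope.

A cluster that stays **UL** at the flat cut is usually a *mixture* whose
mean image is mush, not content that defies classification. The
pipeline therefore refines such clusters (`refine_unlabeled()`):
members of each UL cluster are bisected by a local Ward linkage on
their features, the sub-cluster means are labeled with the same rules,
and the process recurses while a part stays unlabeled (bounded depth
and size). Windows still unlabeled at the bottom remain UL.

Thresholds were calibrated on the synthetic generator's default
conditions and checked on independent simulation seeds
(`theta_qs` 0.03, `theta_wave` 0.35, `theta_r2` 0.9, `theta_at` and
`theta_pt` 0.9, `theta_width` 3, `theta_burst` 0.08,
`theta_coherence_at` 0.8, `theta_coherence_pt` 0.55); all live in the
configuration. Cluster labeling remains a judgment call at heart, so
`manual_label_clusters()` lets an analyst override any cluster after
inspecting the mean images, which is how the original protocol was
executed.

## From windows to events

The per-window labels become a per-frame series: frame `t` takes the
label of the window centered on it, and the 4 frames at each end — which
carry no window center — copy the nearest window's label, restoring the
full valid-frame length (2024 labels → 2032 frames). Maximal runs of one
label are events ("consecutive frames of the same label are one
activity"); QS and UL runs are kept as events, with UL excluded from the
downstream statistics that enumerate the named patterns. Event tables
store 0-based half-open frame spans in original-recording coordinates.

Predictions are scored against ground truth at the event level: a truth
event is a hit if a single same-class predicted event covers at least
half of it (`overlap_threshold = 0.5`), and a predicted event is a false
alarm if it overlaps no same-class truth event at all. Classes with no
truth events report an undefined (missing) hit rate rather than zero.

## Behavioral statistics

`event_frequency()` (events per minute), `event_intensity()` (maximum
normalized dF/F during the event), and the per-frame `asymmetry_index()`
— |max left − max right| / max overall, 0 symmetric, 1 one-sided,
undefined on silent frames — quantify the repertoire. Transition
structure is summarized as an event-level Markov chain over the five
named states: UL events are removed first (concatenating their
neighbors, which is also how same-state transitions such as QS→QS
arise), ordered pairs of consecutive events are counted, and rows are
normalized. `aligned_average()` anchors normalized traces at each
event's end point and averages per class (4 s before to 2 s after by
default; segments truncated by the recording edges are excluded),
reporting mean ± sd durations alongside.

## Correlation mapping

For volumetric movies (registered, `[t, z, y, x]`), `voxel_dff()`
applies the same rectified running-baseline transform per voxel.
`behavior_map()` computes each voxel's Pearson correlation with the
binary indicator of a pattern's frames; `dominant_map()` assigns each
voxel the pattern with the highest r where that maximum exceeds 0.1
(the display threshold), ties resolved by a fixed pattern order;
`roi_map()` correlates voxels against a seed region's summed-F dF/F and
refines the ROI to the voxels with r ≥ 0.05, whose summed raw F(t) is
the refined trace (single pass by default; an `iterate` argument repeats
refinement for exploration). Zero-variance voxels yield missing r — they
can never slip into a map silently. Rectified (not signed) dF/F is used
throughout, matching the trace pipeline.

## The synthetic generator

`sim_config()` + `simulate_events()` + `render_roi_traces()` /
`render_volume_movie()` emulate the study conditions end to end:

* a semi-Markov state process over {AT, BW, FW, PT, QS} whose transition
  bias makes BW→AT and FW→PT the strongest couplings, with quiescence
  interleaved; dwell times are lognormal with means at the observed
  pattern durations (AT 2.2, BW 2.8, FW 2.3, PT 1.5 s);
* quiescent gaps average 10 s with a heavy tail (sdlog 0.8). Short
  "QS episodes" reported by a frame classifier are run lengths, not
  generative gaps — recordings show multi-second to tens-of-seconds
  inter-bout quiescence — so the generator models the gap process and
  lets classified QS run lengths fall where they may;
* 0.2 s per volume, the faster end of the 0.18-0.42 s volume intervals
  used in such recordings. This matters: the 8-frame analysis window
  spans 1.6 s, and the method's premise is that a window sits inside a
  single pattern, which holds when patterns last 8-14 frames;
* waves are Gaussian bumps (s.d. 0.8 segments) traveling the full cord
  over the event; AT is a plateau over T2-A4 with one body side
  attenuated by a uniform 0.2-0.6 factor; PT a plateau over A4-A7;
* exponential photobleaching (tau 600 s), multiplicative on a baseline
  of 100 a.u., with Gaussian noise of 2 a.u.; an optional
  indicator-decay term (instant rise, exponential relaxation) exists but
  is off by default — the rectified running-baseline dF/F transform
  already absorbs most of the falling phase, and tails smear pattern
  boundaries;
* movies place 18 ellipsoidal hemisegment units on a small lattice
  (2 x 32 x 64 voxels by default, kept small so correlation-map tests
  run in seconds) plus one midline unit active only during BW — a
  stand-in for the backward-specific interneurons such mapping is meant
  to discover.

What the generator does *not* model: realistic optics or PSFs, motion
artifacts (inputs are assumed registered), nonlinear indicator
saturation, segment-to-segment amplitude heterogeneity, or gradual
preparation rundown beyond monotone bleaching. Passing tests on this
generator therefore demonstrate the pipeline's mechanics and its
behavior under the stated statistical structure — not performance on any
particular real recording.

## Numerical choices and degenerate inputs

* Frame spans are 0-based half-open everywhere on disk.
* The min-max of a constant matrix returns zeros rather than NaN.
* A series exactly one window long yields zero windows (the count is
  `T - 8` by the data-flow convention, not `T - 7`).
* 8-bit encoding floors (`floor(v*255)`), the standard uint8 cast.
* Ward requires Euclidean distances; `hclust(method = "ward.D2")` is the
  implementation.
* Empty clusters are excluded from labeling with a warning; clusters the
  label map misses default to UL.
* Transition-matrix rows with no outgoing events are NaN and flagged,
  never silently zero.
* All simulator randomness flows from one integer seed (internally
  offset per stage); repeated runs are bitwise identical, including the
  compiled feature path.

## Problem sizes

The bundled tests and the acceptance script run the full pipeline on
2048-frame simulations (the size of the reference data-flow example),
transition recovery on sequences of about 1000 events, and correlation
mapping on a 500-frame, 2 x 24 x 48-voxel movie; these sizes exercise
every code path while keeping a complete run to a few minutes of CPU.

## Known limitations

* Random-weight convolutional features are weaker than pretrained ones:
  they separate the pattern archetypes cleanly but blur harder boundary
  cases (windows straddling event junctions), which is where most
  residual misclassification lives.
* Cluster auto-labeling reads the *mean* window of each cluster; a
  cluster that mixes classes has a mush mean, and no threshold setting
  can label it correctly for all members. The manual override exists for
  exactly this case.
* Event-level scoring with a 50% single-event overlap is strict for
  short patterns (a posterior burst spans only ~8 frames), so fragmented
  detections count as misses even when most frames are right.
* The Markov statistics are event-level by design; frame-level chains
  would be dominated by self-transitions.
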