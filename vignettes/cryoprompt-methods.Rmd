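---
title: "Prompt-based particle segmentation in tomograms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompt-based particle segmentation in tomograms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cryo-electron tomography reconstructs a 3D density volume (a *tomogram*)
of a frozen-hydrated specimen. Locating every copy of a macromolecule in
that volume — *particle picking* — normally requires either template
matching or a model trained on many annotations. `cryoprompt` implements a
training-free alternative: the user clicks a handful of particles (in the
limit, a single one), and the pipeline segments the prompted particles in
3D, learns a feature-space description of the category from those masks,
and finds all remaining instances of the same category in the whole volume.

The pipeline has two algorithmic halves, both operating on top of two
pluggable 2D backends: a *promptable segmenter* (a model that turns a point
or mask prompt on an image into a segmentation mask plus a confidence map)
and a *slice encoder* (a model that turns an image into a grid of feature
vectors). In production use these would be 2D foundation models; the
package ships deterministic mock backends so that every stage is testable
on synthetic volumes with no downloads or weights.

# Cross-plane self-prompting (point to 3D instance mask)

Given a voxel prompt $(z_i, y_i, x_i)$, the three orthogonal planes through
it (YX, ZX, ZY) are segmented with the point prompt. Each plane yields a
mask $M$, a confidence map $C$, and the confidence peak $Q = \arg\max C$.
For each of the six axis directions, the adjacent slice is then segmented
using the previous slice's $(Q, M)$ as point-plus-mask prompt, recursively.
Propagation in a direction stops when

* the IoU between the new mask and the previous one drops below
  $\tau_{\mathrm{IoU}}$ (default 0.5) — the new, inconsistent mask is
  discarded, not kept;
* the new mask is empty; or
* the volume boundary is reached.

The 3D instance mask is the voxel union of the three initial plane masks
and all accepted propagated masks. The six directional recursions are
independent; a plane whose initial mask is empty simply skips its two
directions. IoU is always compared between *consecutive* masks (adjacent
slices), not against the initial mask, and the empty/empty IoU is defined
as 0 so degenerate cases terminate cleanly.

# Hierarchical feature matching (one mask to all instances)

Every slice along each axis is encoded; the per-slice feature maps are
bilinearly upsampled (align-corners, in-plane only — there is no
interpolation across the stacking axis) back to the slice's pixel grid, and
the three stacked view blocks are concatenated channel-wise into the
feature volume $F \in \mathbb{R}^{D\times H\times W\times 3C}$.

The query feature is the masked average pool (MAP) over the prompted
instance masks: the sum of feature vectors over all mask voxels divided by
the total count, a voxel contributing once per mask that covers it.

Matching proceeds coarse to fine on a pyramid $\{F_r\}$,
$r \in \{16, 8, 4\}$ by default, built by $r^3$ block-averaging of $F$
(partial edge blocks average their actual extent — this preserves the
volume-weighted mean feature exactly at every level, a property the test
suite checks). At the coarsest level the cosine similarity
$S_r = \cos(F_Q, F_r)$ is evaluated at every cell; the keep-mask
$K_r = S_r \ge \tau_{\mathrm{sim}}$ (default 0.5) is upsampled
nearest-neighbor to gate evaluation at the next finer level; and so on. If
a keep-mask ever comes out empty, the single best cell is kept instead (and
a warning is raised), so a proposal chain always survives. After the finest
level, greedy non-maximum suppression over the kept cells (descending
score, ties by ascending cell coordinate) returns up to $K = 512$ point
proposals; each proposal is then fed back through cross-plane
self-prompting, proposals whose instance mask comes out empty are dropped,
and the semantic mask is the union of all prompted and retained proposal
instances.

Two properties of this scheme are asserted in the acceptance tests rather
than taken on faith: with filtering disabled ($\tau_{\mathrm{sim}} = -1$)
the finest level is *exactly* the full evaluation (and with ratio list
`(1)` exactly the naive voxel-wise matcher), and on the reference synthetic
scene the number of cosine evaluations is under 20% of what the naive
finest-level evaluation would cost (typically 7–14%).

# Parameters

| parameter | default | meaning |
|---|---|---|
| `tau_iou` | 0.5 | adjacent-slice IoU below which propagation stops |
| `tau_sim` | 0.5 | cosine threshold defining the keep-mask at every level |
| `top_k` | 512 | maximum number of proposed prompts |
| `ratios` | 16, 8, 4 | pyramid downsampling ratios, coarse to fine |
| `nms_radius` | auto | suppression radius (voxels); `auto` = mean bounding-box diameter (mean of the three bbox extents) of the prompted instance masks |
| `normalize_percentiles` | 1, 99 | clip range for slice normalization |

All in-R coordinates are 1-based `(z, y, x)`; all file formats (CSV, CLI
prompts) are 0-based, which is the convention external picking tools
expect. This split is deliberate: a half-open 0-based convention inside R
fights the language; the interchange format is what must be portable.

# The mock backends

The mock segmenter thresholds a slice at median + 3 MAD and region-grows
(4-connectivity) from the prompt; confidence is the normalized
distance-to-boundary inside the mask, and peak ties break
lexicographically so results are reproducible to the byte. A pixel-wise
robust threshold alone, however, cannot segment a noisy particle at
3-sigma contrast: about half of the interior pixels fall below the
threshold, and site percolation on the 4-connected lattice (threshold
$p_c \approx 0.593$) guarantees the above-threshold set shatters into
fragments. The support is therefore the union of the raw threshold and the
same robust threshold applied to a 3x3 median-filtered copy of the slice.
Median filtering preserves flat regions and straight edges, so on clean
synthetic fixtures (where MAD is 0 and the branch is skipped) masks remain
pixel-exact, while on noisy slices connectivity is restored.

The mock encoder computes per-patch statistics at stride 4: patch mean,
standard deviation, mean gradient magnitude, and a band-pass bank realized
patch-locally as lag-1/2/3 absolute-difference responses reduced to two
signed band *contrasts* (lag1 − lag3, lag2 − lag3). On white noise all
bands respond equally and the contrasts center on zero; fine textures push
them positive, coarse textures negative. Channels are robust z-scores
across the image's cells, so featureless background maps to near-zero
vectors, and are scaled by fixed weights (0.25, 0.5, 0.5, 2, 2). The
weighting reflects a requirement of cosine matching: brightness and energy
statistics are *shared* by every bright particle regardless of class, so
they must not dominate the texture channels that actually carry class
identity. Without this, every bright or noisy region aligns with any
particle query and the keep-masks stop filtering.

Slices fed to the encoder are normalized on a *volume-wide* percentile
scale (1–99 by default, computed once per tomogram). Per-slice percentile
bounds are content-dependent: a slice that merely grazes a particle near
the volume boundary contains almost no bright pixels, its 99th percentile
sits at the noise level, the particle cap saturates, and its features
collapse. The segmentation path keeps per-slice normalization, to which
the mock segmenter is affine-invariant.

# The synthetic scene generator

`generate_scene()` emulates what the pipeline needs from a tomogram:
bright, roughly spherical particles of two distinguishable classes in
Gaussian background noise, with exact ground-truth centers, radii and
voxel masks. The reference `"standard"` preset is a 96^3 volume with 12
class-A spheres (radius 6–8, multiplicative sinusoidal texture of period
3) and 8 class-B spheres (radius 10–12, texture period 12), both at peak
contrast 3 over unit noise, minimum center separation 24, seed 0. The
texture amplitude (0.5 relative) and the two periods were chosen once so
that the classes are distinguishable by local frequency content — which is
precisely the property the mock encoder's band contrasts measure — while
remaining segmentable. Each particle's radial profile is 1 in the core and
falls linearly to 0 at its radius over a soft inner edge of width 1.5, so
particle support (and hence the ground-truth mask) ends exactly at the
nominal radius. Scenes are generated on a private RNG stream: the caller's
`.Random.seed` is untouched and a `(params, seed)` pair is bit-reproducible.

What the generator does *not* emulate: the missing wedge, CTF modulation,
tilt artifacts, crowding, non-spherical shapes, or intensity polarity of
real cryo-ET (particles there are dark; a polarity flag inverts the scene).
Passing tests on these phantoms therefore demonstrates the *algorithmic*
correctness of propagation, matching and evaluation — not picking
performance on real tomograms, which depends on the quality of the plugged
foundation backends.

# Evaluation

Picking is scored per proposed prompt: greedy one-to-one matching of
predictions (descending score) to the nearest unmatched ground-truth
center within a tolerance, defaulting to the mean truth radius. Matched
predictions are TP, the rest FP, unmatched truths FN; precision, recall
and F1 follow, with fixed degenerate conventions (precision 0 with no
predictions; recall 1 when both sides are empty, 0 when predictions exist
but truth is empty). Greedy matching equals optimal assignment whenever
predictions are mutually farther apart than twice the tolerance — which
NMS guarantees in practice — and the suite property-tests this against a
brute-force assignment oracle.

# Numerical and design notes

* **Determinism.** The pipeline contains no randomness; two runs with the
  same config produce byte-identical mask MRC and proposal CSV files. All
  mock-backend tie-breaks (peak selection, NMS ordering) are lexicographic.
* **Problem sizes.** The shipped tests run the full pipeline on 96^3
  (reference preset) and 48^3 (fast two-class scene) volumes, and the
  matching equivalence checks on random fields up to 64^3; a full
  one-prompt semantic run on 96^3 takes on the order of ten seconds with
  the mock backends.
* **Memory.** The full-resolution feature volume for 96^3 with the default
  mock encoder is 96^3 x 15 doubles (~100 MB); the pyramid adds a few
  percent on top.
* **Edge behavior.** Upsampling uses align-corners interpolation; pyramid
  cell centers map to `(i-1)*r + floor(r/2) + 1`, clipped to the volume;
  zero feature vectors score cosine 0 by convention (background slabs are
  legitimately featureless); a keep-mask that empties falls back to its
  best single cell.
* **Known limitations.** Single-prompt queries are noisier than averaged
  multi-prompt queries; in unfavorable scene realizations, class-B regions
  can score just above `tau_sim` against a weak one-prompt class-A query
  (picking more prompts fixes this, and the reference conditions are
  clean). Because `tau_sim` also gates the finest level, particles whose
  fine-scale cells score marginally below 0.5 under noise are dropped;
  across scene seeds the one-prompt class-A recall on the reference preset
  ranges from about 0.75 to 1.0, with precision at or above 0.92.
* **Foundation adapters.** The `foundation_segmenter()` /
  `foundation_encoder()` constructors define the adapter contract (prompt
  in, mask-plus-confidence out; normalized slice in, strided feature grid
  out) but ship no weights and are not exercised by the tests. A
  multi-hypothesis segmenter adapter should return its single
  highest-scoring mask.
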