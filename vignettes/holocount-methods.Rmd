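---
title: "Methods: staining-free tumor-cell enumeration from in-line holograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staining-free tumor-cell enumeration from in-line holograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holocount)
```

## The measurement problem

Circulating tumor cells occur at a few cells per mL in enriched blood
samples, against a background of 10^3^–10^4^ white blood cells (WBCs) per
mL. `holocount` implements a staining-free enumeration pipeline for this
regime: cells flow through a sheathed microfluidic channel, a coherent
in-line hologram of the channel is recorded at high frame rate, and each
cell is located in 3D, brought to focus numerically, classified by a small
convolutional network, and counted only if the classifier is nearly certain
it is a tumor cell. The output is a concentration in cells/mL plus a limit
of detection derived from negative-control runs.

The default configuration describes the reference acquisition the package
is built around: a 635 nm laser, 1 um/px sampling over an 800 x 800 px
field of view, a channel of 800 um (width) x 330 um (depth) whose floor
lies 200 um above the hologram plane, sheath streams confining the sample
to a ~500 um core, 2.5 mL/min sample flow in 3.5 mL/min total flow, and a
420 fps camera so that 10 100 frames sample 1 mL in about 24 s. At that
frame rate the fastest (centerline) cell moves farther than the field of
view between frames and is seen exactly once, while slow cells near the
sheath interface or channel floor/ceiling are seen in 2-3 consecutive
frames — this is what the multiple-count removal stage corrects.

## Image formation and the simulator

The simulator (`simulate_stack()`) is a first-class part of the package:
it supplies ground-truth-annotated data for every downstream stage.

* **Arrivals.** Each class arrives as a Poisson process with rate
  `concentration x sample flow rate`; cells enter uniformly across the
  sheath core and uniformly in depth, and are advected at the local speed
  of the laminar product-of-parabolas profile
  $u(y,z) = u_{max}\,(1-(2y/W-1)^2)(1-(2z/H-1)^2)$,
  scaled so the cross-section integral equals the volumetric flow rate
  ($u_{max} = \tfrac94 Q/WH$, mean speed $Q/WH \approx 221$ mm/s).
* **Optics.** A cell is an anti-aliased disk with complex transmission
  $(1-a)e^{i\phi}$ in its own object plane. Its single-scattering
  perturbation is propagated to the hologram plane over
  `recording_distance + z` by the angular-spectrum operator, perturbations
  of all cells are superposed on a unit reference wave, and the intensity
  is recorded under a smooth Gaussian-vignette illumination with additive
  Gaussian sensor noise (default sd 1% of the mean level) and 16-bit
  quantization. Multiple scattering is neglected — cells are sparse, and
  linearity is exactly the assumption reconstruction makes.
* **Class parameters.** The published experiments do not report sizes or
  optical contrasts of their cell lines, so the simulator uses
  literature-typical stand-ins (`cell_params()`): tumor-like cells
  18 ± 2 um in diameter with amplitude contrast 0.8, WBC-like cells
  10 ± 1.5 um with contrast 0.5, both truncated at 2.5 sd. They are
  configurable; all that the pipeline's validity arguments need is that
  the classes are separable in focused images.
* **Motion blur** over the 35 us exposure (~15 um at centerline speed) is
  available as an optional three-sample streamwise average and is off by
  default.

What the simulator does *not* emulate: partial coherence and speckle,
camera shot noise, wall fringes (the sheath device removes them in the
physical system), cell granularity/texture, and cell-to-cell optical
variability beyond size and bulk contrast. Passing tests on synthetic data
therefore demonstrate the *computational* chain — localization, focusing,
deduplication, gating arithmetic — not classifier performance on real
cells, whose images are richer than homogeneous disks.

## Reconstruction and the transfer-function phase convention

Reconstruction back-propagates the normalized hologram with the exact
angular-spectrum transfer function
$H(f_x,f_y;d)=\exp\!\big(i2\pi d(\sqrt{(n/\lambda)^2-f_x^2-f_y^2}-n/\lambda)\big)$,
evanescent components suppressed. Two numerical choices deserve note:

* **Carrier-phase removal.** The $-n/\lambda$ term pins the DC component,
  so a perturbation field interferes with the *unpropagated* unit
  reference at the correct relative phase. Without it, the refocused
  object acquires an arbitrary phase $e^{-ikd}$ against the reference and
  an absorbing cell does not reconstruct dark. With it, forward-then-
  backward propagation is still exactly the identity on propagating modes
  (asserted to 1e-8 in the tests) and power is conserved to 1e-6.
* **Amplitude-only fields.** In-line acquisition corrupts phase with the
  twin image, so the real-valued normalized contrast `1 + cleaned/bg` is
  used as the field amplitude with zero phase; the conjugate (twin) term
  then appears as a defocused artifact at twice the propagation distance,
  which the detection stage must reject but which is never removed.

Background estimation is the pixelwise mean over the full stack (cells are
sparse and transient, so the average is the static illumination), and the
cleaned frame is flat-field normalized by the background with a clamp at
1% of the background median to keep dead pixels finite. Reconstruction
spans floor to ceiling (200-530 um) in 5 um steps, both endpoints
included: 67 planes.

## 3D localization and the plane of best focus

Detection takes the minimum-intensity projection across planes: every
absorbing cell is dark somewhere in the stack. Candidate pixels fall below
`median - 6 MAD`; connected components are filtered by area (9-2000 px),
by depth (components whose darkest pixel stays above 0.65 are twin-image
side lobes, not cells), and merged within 20 um. The intensity-weighted
centroid gives sub-pixel (x, y).

The axial position comes from a focus curve computed in a 36 x 36 window
around the centroid. The package default metric is **windowed gradient
energy (Tenengrad)**, maximized at focus. The more obvious dark-focus
criterion (windowed minimum mean intensity) is retained as an option but
is *not* the default for an instructive reason found during development:
a strongly absorbing 18 um disk casts a dark shadow that persists over
hundreds of micrometers of defocus, so "darkest plane" is nearly
unconstrained axially (errors up to ~300 um), while edge sharpness peaks
tightly at the true plane for both faint and opaque cells (errors < 5 um
at 5 um plane spacing). The Tamura coefficient works for faint cells only.
Ties break toward the smaller propagation distance. The 36 x 36 crop from
the selected plane is min-max scaled to [0, 1]; per-crop scaling makes the
classifier invariant to illumination level.

## Multiple-count removal

Laminar flow conserves a cell's cross-stream (y) and axial (z) position
while it crosses the field of view, so a detection in frame i+1 within
3 um in y **and** 50 um in z of a detection in frame i is the same cell
seen again and is eliminated; chains across frames i, i+1, i+2 collapse
transitively onto the earliest detection, which is the instance kept (the
alternative — keeping the best-focus instance — changes nothing about
counts and is not implemented). The z criterion is deliberately lenient
because axial localization is the least precise coordinate. Only adjacent
frames are compared by default (`max_frame_gap = 1`); the streamwise x
position is deliberately unused, since cells traverse most of the field
between frames.

## The s-Net classifier

The classifier is a shallow CNN for 36 x 36 single-channel crops:
three 3 x 3, stride-1, same-padded convolutions with 8, 16 and 32 filters,
each followed by batch normalization and ReLU, 2 x 2/stride-2 max pooling
after the first two, a 2592-node flatten (9 x 9 x 32), one fully connected
layer and a softmax — 11 186 learnable parameters including batch norm
(11 074 without), i.e. ~11 000. The second conv layer's filter count (16)
is the geometric step between 8 and 32 that reproduces both the 2592
flatten width and the ~11k parameter count. Training follows a fixed
recipe: softmax cross-entropy, Adam at learning rate 1e-3, minibatch 32,
20 epochs, 70/30 stratified train/test split, He-uniform initialization
from a seeded RNG; training is bit-deterministic given the seed. The
forward/backward pass runs as a fused C++ step (im2col + BLAS); a plain-R
implementation of every layer defines the reference semantics and the
test suite asserts the two agree to machine precision, alongside a
finite-difference gradient check.

Batch-norm inference uses running statistics (momentum 0.1) frozen at
prediction time. A practical finding worth recording: training crops must
be generated under the *same reconstruction settings* (pixel pitch, plane
spacing) as the crops the model will score. A model trained on crops
focused on a 20 um grid but deployed on a 30 um grid sees slightly
blurrier inputs than it ever trained on and produces spuriously confident
tumor calls on WBCs; matching the settings removed every such false
positive in our harness. This mirrors the experimental practice of
training on crops produced by the identical pipeline.

## Decision gating, enumeration, LoD

The softmax tumor probability is gated at a threshold α > 0.5 chosen by
ROC analysis on the held-out test split: TPR and FPR are computed on the
grid {0.5, 0.9, 0.99, ..., 1 - 10⁻⁷} (both are non-increasing in α), and
`select_alpha()` returns the smallest threshold attaining the minimum FPR
— beyond it nothing changes except lost sensitivity. Counts convert to
concentrations by time-based volume accounting:
`volume = n_frames / frame_rate x sample_flow_rate` (10 100 frames at
420 fps and 2.5 mL/min ≈ 1.00 mL). The per-frame geometric volume
(FOV x core width x depth ≈ 0.13 uL) is reported by `frame_volume()` for
reference but is not used for enumeration, because at 420 fps consecutive
frames under-sample the stream: the time-based accounting is the canonical
one. The limit of detection is `LoD = mu_NC + 2 sigma_NC` over
negative-control trials (WBCs but no tumor cells), with the sample
(n-1) standard deviation.

## Problem sizes used by the test suite

The automated checks run at sizes chosen to exercise every stage on a
single CPU:

* Localization accuracy: 100 isolated cells on a 256 x 256 px field at
  1 um/px, full 67-plane reconstruction.
* Dedup recovery: 20 seeded 250-frame acquisitions, detections derived
  from ground-truth tracks with 0.3 um (y) and 5 um (z) localization
  noise; aggregate unique-count error under 2%.
* Classifier: 3500 training and 1500 test crops per class at the full
  recipe (Adam 1e-3, batch 32, 20 epochs); a shuffled-label control at
  1000 crops per class lands at chance.
* End-to-end enumeration: a scaled acquisition at 2 um/px over a
  400 x 400 px field (the full 800 um channel width), 30 um plane spacing
  (12 planes) and 3030 frames per run (0.3 mL), with tumor spikes of
  0/10/100/1000 per mL over a constant 1000 WBC/mL background; the
  classifier for these runs is trained on 875 crops per class generated at
  the same pitch and plane spacing, and the gate is the ROC-selected α.
  Frames whose normalized contrast never exceeds the noise floor are
  skipped before reconstruction; this changes nothing for frames that
  contain cells.

Coarser sampling (2 um/px) halves cell diameters in pixels and the 30 um
plane grid quantizes z estimates; both are visible in the results only as
slightly coarser localization, and the dedup z window (50 um) tolerates
the one-plane jumps the grid induces.

## Known limitations

* The twin image is retained, as in any amplitude-only in-line
  reconstruction; detection must reject its side lobes, and axial
  precision for strong absorbers comes entirely from the sharpness
  metric.
* Touching or overlapping cells are not segmented; a merged component
  yields one detection.
* A cell whose track is interrupted (missed detection in an intermediate
  frame) breaks the dedup chain and is counted twice; conversely two
  distinct cells within 3 um (y) and 50 um (z) across adjacent frames
  merge. Both effects are rare at the cell loads considered here.
* Synthetic separability is by construction; accuracy figures on
  simulated crops say nothing quantitative about real cell images.

## A note on the shuffled-label control

The classifier checks include a negative control: retrain the identical
network on crops whose labels are randomly permuted and confirm the test
accuracy collapses to chance. On sharply clustered synthetic data the
unconstrained permutation is a degenerate null — each true cluster keeps
a small random majority of one label, the network votes with it, and the
control lands near 0 or 1 per cluster instead of 0.5. The suite therefore
uses the exact permutation null: labels are shuffled subject to a 50/50
balance within each true class, which makes cluster identity carry no
label information and brings the control to chance (measured 0.48).
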