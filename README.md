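# holocount

Staining-free enumeration of rare tumor cells in flow, from in-line
digital holographic microscopy (DHM) video.

Label-free enrichment of circulating tumor cells leaves a few target cells
per mL in a background of 10^3–10^4 white blood cells (WBCs) per mL, and
immunostaining — the standard way to identify them — kills the cells.
`holocount` implements the computational side of a staining-free
alternative: cells flowing through a sheathed microchannel scatter a
coherent beam; the interference of the scattered and unscattered waves is
recorded as in-line holograms at 420 fps; and everything after the camera
is numerical. The package is aimed at researchers building or evaluating
DHM + machine-learning cell screens, and at anyone who needs a fully
simulated, ground-truth-annotated testbed for such a pipeline.

## The pipeline

For each acquisition (10 100 frames ≈ 1 mL of sample at 2.5 mL/min):

1. **Background subtraction** — the object-free background is the mean of
   all raw holograms; each frame is cleaned by subtraction and flat-field
   normalized: `contrast = 1 + (frame − bg)/bg`.
2. **Volume reconstruction** — the angular-spectrum operator
   `H(f; d) = exp(i2πd(√((n/λ)² − |f|²) − n/λ))` back-propagates each
   cleaned hologram to 67 planes spanning the 330 µm channel depth in
   5 µm steps (recording distance 200 µm → 200–530 µm).
3. **3D localization** — cells are dark in the minimum-intensity
   projection; connected components give lateral centroids, and the plane
   of best focus (PoBF) maximizes windowed gradient energy along z. A
   36 × 36 crop is taken at the PoBF and scaled to [0, 1].
4. **Multiple-count removal** — a detection in frame *i*+1 with
   |Δy| ≤ 3 µm and |Δz| ≤ 50 µm of one in frame *i* is the same cell seen
   again (laminar flow conserves y and z) and is eliminated.
5. **s-Net classification** — a shallow CNN (3 conv layers with 8/16/32
   3 × 3 filters, batch norm, ReLU, two 2 × 2 max-pools, a 2592-node
   flatten, softmax; ≈11 000 learnable parameters) scores each crop,
   trained with Adam (lr 10⁻³), minibatch 32, 20 epochs on a 70/30 split.
6. **Decision gating and enumeration** — a crop counts as a tumor cell
   only if `P(tumor) > α`, with α chosen by ROC analysis as the smallest
   threshold attaining the minimum false-positive rate. Counts become
   concentrations via `volume = n_frames/frame_rate × sample_flow_rate`,
   and the assay's limit of detection is `LoD = μ_NC + 2σ_NC` over
   negative-control trials.

A physics-based simulator (`simulate_stack()`, `simulate_pobf_crops()`)
generates hologram stacks and labeled training crops with full ground
truth (3D tracks, class labels), so every stage is testable without
laboratory data.

## Worked example

A scaled-down acquisition (2 µm/px over a 512 µm field, 120 frames) with
tumor-like cells spiked at 3000/mL into 5000 WBC/mL:

```r
library(holocount)

optics <- optical_config(pixel_pitch = 2, fov_px = c(256L, 256L),
                         channel_width = 512, sample_core_width = 320,
                         plane_spacing = 30)
flow <- flow_config(n_frames = 120L)

# labeled training crops, generated at the same reconstruction settings
pool  <- simulate_pobf_crops(250, seed = 2,
                             optics = optical_config(fov_px = c(64L, 64L),
                                                     pixel_pitch = 2,
                                                     plane_spacing = 30))
model <- snet(pool$crops, pool$labels, epochs = 8, seed = 3)

stack  <- simulate_stack(optics, flow, c(TUMOR = 3000, WBC = 5000), seed = 7)
result <- run_pipeline(stack, model, alpha = 0.999)
result
```

```
Holographic enumeration pipeline
  frames: 120 (57 reconstructed) -> detections: 67 -> unique: 55 -> gated: 20
Enumeration: 20 of 55 unique cells gated positive at alpha = 0.999
  imaged volume 0.012 mL -> 1680.00 cells/mL
```

Reading the numbers: 104 cells were simulated but only 75 enter the field
of view while a frame fires (at this reduced field, cells can cross
between frames — the full 800 µm field at 420 fps does not have this
gap); 67 detections collapse to 55 unique cells after multiple-count
removal, and 20 pass the strict gate, giving 1680 tumor cells/mL over the
0.012 mL imaged. The limit of detection from three negative-control
trials with counts (1, 1, 2) per mL:

```r
limit_of_detection(c(1, 1, 2))
#> LoD = mu + 2 sigma = 2.49 cells/mL (mu = 1.33, sigma = 0.58, 3 trials)
```

A thin command-line front-end (`inst/scripts/holocount`) exposes
`simulate`, `run` and `lod` subcommands over the same functions, with
multi-page TIFF stacks and CSV detection tables as the exchange formats.
See the methods vignette (`vignettes/holocount-methods.Rmd`) for the
model, the numerical choices and their rationale.

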