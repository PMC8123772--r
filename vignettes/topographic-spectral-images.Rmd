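---
title: "Topographic spectral images from multichannel EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic spectral images from multichannel EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topospectra)
```

## The problem and the pipeline

Emotional distress leaves measurable traces in the brain's oscillatory
activity, and gamma-band power in particular is elevated under negative
stimuli, most visibly over frontal sites. `topospectra` implements a
pipeline that turns 32-channel EEG trials into topographic *images* of
spectral power so that a convolutional classifier can exploit all scalp
locations simultaneously, rather than treating each channel as an isolated
feature:

1. **Labeling.** Trials carry valence/arousal self-ratings on a 1–9 scale.
   Distress is valence < 3 with arousal > 5; calm is valence in [4, 6]
   with arousal < 4; everything else is excluded. The two regions are
   disjoint by construction.
2. **Preprocessing.** Downsampling to 128 Hz, average re-referencing,
   zero-phase band-pass filtering between 3 and 45 Hz, selection of the
   trailing 30 s, and splitting into six non-overlapping 5 s epochs.
3. **Spectral analysis.** Welch's periodogram per channel (2 s Hamming
   windows, 50% overlap, 256-point transform, hence a 0.5 Hz grid), then
   total power over 4–45 Hz and theta/alpha/beta/gamma fractions
   normalized by the total.
4. **Mapping.** Per-band channel values become 227×227 images under three
   schemes — DMD (direct 9×4 matrix of cells), DMDi (the same nodes,
   biharmonic-spline interpolated over the whole surface), and AEP
   (azimuthal equidistant projection of electrode positions, interpolated
   inside the head disc) — rendered through a 256-level jet colormap, or
   stacked into 227×227×5 cubes over the five bands.
5. **Classification.** An AlexNet-shaped network (five convolutional +
   three fully connected layers) in 2-D or 3-D form, trained with SGD
   (momentum 0.9, constant learning rate 0.001, L2 decay 0.001 on
   convolutional weights, mini-batches of 12), evaluated over repeated
   80/20 per-class hold-out cycles with sensitivity, specificity and
   accuracy (distress positive).

## Band definitions and the half-open partition

The four sub-band sums as conventionally printed share their endpoints
(8, 13 and 30 Hz would each be counted twice). We instead integrate over
the half-open partition theta [4, 8), alpha [8, 13), beta [13, 30), gamma
[30, 45], so the four normalized fractions sum to exactly 1 on any
spectrum — a property the test suite asserts to 1e-9 on random spectra. On
the 0.5 Hz analysis grid the bands contain 8, 10, 34 and 31 bins of the 83
bins covering 4–45 Hz, so a flat spectrum yields fractions 8/83, 10/83,
34/83, 31/83.

Welch estimates use density scaling (power per Hz) with window power
compensation. The normalized fractions are invariant to this choice; the
absolute total `pt` is not, and is reported in µV²/Hz-bin units (the plain
sum of PSD bins over 4–45 Hz). No detrending is applied beyond the
filtering already in the chain.

## Electrode geometry

The paper-style montage table ships as
`inst/extdata/montage_deap32.csv`: an idealized, equidistant construction
of the 10-10 positions on the unit sphere (outer ring at 72° inclination
in 18° azimuthal steps, midline at 18/36/54/72°, intermediate sites by
spherical interpolation along coronal arcs). Left/right homologues are
exact mirrors, which makes the mirror-symmetry properties of the rendered
maps exact rather than approximate. Angles are stored in degrees and
converted to radians in computation; the head radius is normalized to 1.

The azimuthal equidistant projection sends an electrode at elevation *e*
and azimuth *a* to planar radius ρ = (90 − e)·π/180 along direction *a*:
arc distance and direction from the vertex (Cz) are preserved, Cz maps to
the origin, and the planar ordering of vertex distances equals the
spherical one.

The default 9×4 DMD grid is constructed to satisfy every textual
constraint of the scheme: all 36 cells filled, rows running anterior to
posterior, mirror-symmetric columns, and the four midline channels (Fz,
Cz, Pz, Oz) duplicated across the two central columns. The published
figure defining the exact grid is not recoverable from text alone, so the
packaged grid is an equivalent-by-constraints default, and
`read_dmd_layout()` accepts a user override which `validate_layout()`
checks invariant by invariant.

## Interpolation and rendering choices

Scattered-data interpolation uses the biharmonic Green's function
G(r) = r²(ln r − 1): coefficients are solved so the interpolant passes
exactly through the data sites, with values mean-centered before the solve
for constant reproduction. Coincident nodes (within 1e-9) are collapsed to
their mean before solving; a singular system raises an error carrying the
reciprocal condition number.

Rendering decisions that the text left open:

- **Colormap scope.** Min-max normalization is per image; a dataset-wide
  scope would make images comparable in absolute level but ties the
  rendering to the dataset, so per-image is the default. A consequence
  worth noting: rendered RGB is invariant under positive affine rescaling
  of the channel values, so only the *spatial pattern* of a band reaches
  the classifier.
- **Constant maps** (min = max) render uniformly at mid-palette with a
  warning rather than erroring.
- **DMD cell boundaries** are `round(i·227/9)` × `round(j·227/4)`, giving
  25–26 px tall, 56–57 px wide cells that tile all 227 px exactly; a
  strict mode uses uniform 25×56 cells with the remainder merged into the
  last row/column.
- **DMDi nodes** sit at the integer pixel nearest each cell center — the
  only coordinates the matrix scheme defines — so node exactness holds at
  actual pixels.
- **AEP framing** maps electrode coordinates affinely (equal x/y scale,
  5% margin around the electrode bounding circle) with axis offsets
  rounded separately per axis, which keeps homologue pixels exactly
  mirrored. Pixels outside the circle circumscribing the electrodes are
  masked to the in-disc minimum rather than extrapolated, because the
  biharmonic interpolant diverges away from its nodes.
- **Cubes** stack the five min-max-normalized scalar maps (order: total,
  theta, alpha, beta, gamma), not the RGB renderings: a 227×227×5 cube has
  one scalar plane per band.

## The classifier

No deep-learning framework is assumed: the package carries a native
convolutional engine (im2col gathers + BLAS matrix products, with
precomputed patch index tables per layer) implementing convolution, local
response normalization, max pooling, dropout (rate 0.5), fully connected
layers, softmax cross-entropy, and SGD with momentum, verified against
numerical differentiation in the test suite. Strides and padding follow
the classic published topology (stride 4 for the first 11×11 convolution,
pooling 3×3 stride 2, and so on); the figure naming only kernel counts and
sizes leaves those values to the canonical architecture.

The 3-D variant extends kernels and pooling in depth. Nominal kernel
depths (11, 5, 3) exceed the 5-deep cube, so depth is clipped to the
available extent with same-padding — an interpretation recorded here
because the source is silent on it. A width multiplier scales filter
counts and fully connected sizes so that desk-scale networks (width 0.1)
train on one CPU in minutes; multiplier 1.0 reproduces the full 96/256/
384/384/256 + 4096/4096/2 shape. Iterations per epoch derive as
`floor(n_train / batch)` — 103 for the canonical 1244-image training set —
and a configured value wins over the derived one with a warning.
Transfer-learning initialization is supported only as an external
checkpoint path (`save_net()`/`load_net()` with a spec fingerprint); no
weights ship with the package, and every test trains from random
initialization. How original 2-D weights would be stacked into the 3-D
network is under-specified at the source, so no default adapter is
guessed.

## The synthetic generator — what it emulates and what it does not

`synthetic_spec()` describes two-class datasets of 32-channel, one-minute
trials at 512 Hz (defaults). Each channel is a sum of band-limited
Gaussian components — white noise masked to each band in the frequency
domain, a zero-phase operation that keeps the in-band spectrum exactly
flat — scaled so the variance fractions match per-channel targets, plus a
5% broadband noise floor. Ratings are drawn uniformly from the class
regions (calm: valence [4, 6], arousal [1, 4); distress: valence [1, 3),
arousal (5, 9]), respecting the strict inequalities of the labeling rules,
so labeling reproduces the generating class exactly.

Class structure has two levers. The band profiles set absolute levels
(calm gamma 0.15 vs distress gamma 0.45 by default). Because rendered
images are affine-invariant, a uniform gamma elevation is invisible to the
image classifier; spatial structure is therefore supplied by a per-channel
gamma gain map, by default elevating distress gamma 2.5× over frontal
sites, consistent with frontal gamma increments reported under stress.
Parameter-recovery tests use a uniform gain so estimated fractions compare
directly against configured profiles; they recover within ±0.05 after the
full chain, the residual being dominated by the systematic theta loss at
the 4 Hz band edge adjacent to the 3 Hz high-pass cut-off.

The generator makes no attempt at physiological artifacts (blinks, EMG),
volume conduction or leadfield structure, 1/f spectral slope, or
inter-subject variability. Passing tests therefore demonstrate that the
pipeline's arithmetic, geometry and learning machinery behave as
specified — not that real recordings would classify at any particular
accuracy. The headline accuracies of the reference protocol require the
restricted-access recordings and full-scale GPU training and are out of
scope here.

Artifact rejection by independent component analysis is a pass-through
hook (`artifact_hook` in `preprocess_trial()`): the component-selection
criteria are not computationally defined at the source, so the slot exists
for users to plug in a cleaner, and the default is the identity.

## Filter realization

The band-pass stage names cut-offs, not a family or order. We use
4th-order Butterworth high- and low-pass sections, each applied
forward/backward (`signal::filtfilt`), the standard zero-phase EEG
practice; the two-pass magnitude is −6 dB at the cut-offs and the order is
configurable. Rate conversion is zero-stuffing upsampling (when the ratio
requires it) followed by a zero-phase FIR anti-aliasing low-pass
normalized to exactly unit DC gain, then decimation; 512 → 128 Hz is an
exact 1/4 decimation.

## Problem sizes in the tests

The suite chooses sizes that keep every property sharp but cheap: spectral
and geometric properties run on single epochs or constructed spectra;
parameter recovery uses 30 s trials at 128 Hz (and the full 512 Hz chain
on four trials); the learning smoke test trains a width-0.1 2-D network on
204 DMD gamma images from 17 trials per class for 5 epochs, reaching
held-out accuracy above 90%, while a label-shuffled control stays at
chance. The epoch-bookkeeping check runs the full 137 + 122 trial layout
at 128 Hz. These sizes are the package's own validation choices; the
experiment protocol itself (`run_experiment()`, `cmd_experiment`) defaults
to the full-scale settings.

## Known limitations

- `pt`'s absolute scale depends on the Welch scaling convention;
  cross-package comparisons should use the normalized fractions.
- The biharmonic system is dense; it is exact but O(n³) in node count —
  irrelevant at 32–36 nodes, unsuitable for hundreds.
- The native CNN is CPU-bound R; full-width training at the reference
  protocol's 4120 iterations is possible but slow, and the package makes
  no attempt at GPU execution.
- EDF input is not supported; recordings enter as delimited matrices with
  JSON sidecars (`read_eeg_matrix()`).
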