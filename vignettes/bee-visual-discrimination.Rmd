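---
title: "Modelling honeybee pattern discrimination with lobula neurons and Kenyon cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling honeybee pattern discrimination with lobula neurons and Kenyon cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beekc)
```

## The model

Honeybees discriminate and generalize achromatic patterns with a brain of
fewer than a million neurons. `beekc` implements a minimal, biologically
inspired account of how far two fixed neural read-outs can carry such
behaviour without any learning: eight large-field orientation-sensitive
neurons of the lobula (the third optic ganglion) drive a single layer of
binary mushroom-body Kenyon cells, and behavioural choice is read off the
similarity of Kenyon-cell population codes.

The processing chain for one stimulus is:

1. **Retina / lamina.** A 150 x 150 px pattern tile is composited into a
   300 x 150 px field of view (the left half is the left eye, the right
   half the right eye; the top half is dorsal). The image is median-
   filtered, binarized on the green channel, and edges are extracted with
   Canny edge detection and Sobel gradient analysis. Edge pixels with
   Sobel magnitude at or below a configurable cut are discarded, the
   analogue of the bee's ~3 degree acuity limit.
2. **Medulla.** The retained edge pixels are histogrammed per visual-field
   quadrant `q` into 1-degree orientation bins `i` in [0, 180), giving the
   edge-length table `H(q, i)`.
3. **Lobula.** Two neuron types per quadrant (A and B, eight neurons in
   all) respond with

   `rate(x, q) = ( sum_i H(q,i) / sum_i H(q,i) * C(x, i) ) * S(sum_i H(q,i))`

   where `C(x, i)` is the orientation tuning curve of type `x` for a
   280 px reference edge and `S(L)` a sublinear scale factor in the total
   edge length `L`.
4. **Mushroom body.** 86 wiring configurations pair `nA` type-A with `nB`
   type-B synapses of opposite sign (counts in {1, 2, 3, 5, 7, 11, 13};
   primes avoid duplicated response profiles). Configurations 44--86
   mirror 1--43 with signs flipped, which pins population activation at
   ~50%. Thirty copies of each configuration per source region give
   10,320 cells in the DISTINCT variant (each cell reads one quadrant)
   and 5,160 in MERGED (each cell reads the same dorsal or ventral band
   of both eyes, with the synapse set duplicated per eye). A cell fires
   iff its signed, noise-perturbed synaptic sum is strictly positive.
5. **Read-out.** For a trial with rewarded pattern CS+, correct test
   stimulus TS^COR and incorrect test stimulus TS^INC, the Kenyon cell
   similarity ratio is

   `KCSR = 1 - E(CS+, TS_COR) / (E(CS+, TS_COR) + E(CS+, TS_INC))`

   with `E` the Euclidean distance between binary activation vectors.
   Percent-correct performance is 100 times the mean KCSR over 1000
   noisy trials.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `peak_A`, `peak_B` | 115, 250 (= 70 mod 180) deg | preferred orientations of the two lobula types |
| `hwhm` | 45 deg | half-width at half-maximum of the tuning curves; "angular half-width of about 90 degrees" read as full width at half-maximum |
| `rate_A`, `rate_B` | 36 Hz | peak rate for a 280 px edge; the type B amplitude is not reported and defaults to the type A value |
| `reference_length` | 280 px | edge length at which tuning curves are defined, `S(280) = 1` |
| `scale_exponent` | calibrated (~0.812) | exponent of `S(L) = (L/280)^alpha`; see below |
| `snr` | 30 (dB) | per-synapse noise, sd = rate x 10^(-snr/20) |
| `copies_per_config` | 30 | population copies per configuration and region |
| `binarize_threshold` | 128 | green-channel figure/ground cut |
| `magnitude_threshold` | 1.7 | weak-edge cut on the 0--255 Sobel scale |

All of these live in one `beekc_config()` object; tuning and scale curves
can also be loaded from tabulated files (`tuning_table`, `scale_table`)
to substitute digitized recordings for the parametric defaults.

### The tuning curves

The recordings behind the model were published as figures, not formulas.
The default curve is a wrapped Gaussian on the 180-degree orientation
circle, `C(theta) = peak_rate * 2^-((d/hwhm)^2)` with `d` the angular
distance to the preferred orientation, which honours every printed
constraint (peak locations, peak rate, half rate at 45 degrees from the
peak, axial periodicity). Real tuning curves are broader-shouldered and
asymmetric; the consequences are discussed under *Limitations*.

### Calibrating the length-scale exponent

The reference worked example fixes one further observable: a single
vertical bar (600 px of edge at 90 degrees plus 200 px at 0) and a
doubled pair of horizontal bars (1200 px at 0 plus 400 px at 90) drive
the type A neuron at exactly the same rate. Because the two stimuli have
identical orientation *proportions* and a 2:1 length ratio, the equality
pins `S(1600)/S(800)` to the ratio of the two proportion-weighted curve
responses, hence

`alpha = log2( (0.25 C_A(0) + 0.75 C_A(90)) / (0.75 C_A(0) + 0.25 C_A(90)) )`

which is `r round(scale_exponent(beekc_config()), 4)` under the default
curves. We therefore treat the exponent as derived rather than free; it
remains overridable through `scale_exponent`. The resulting factor is
monotone, concave and properly sublinear (`S(2L) < 2 S(L)`).

### The noise model

Synaptic noise follows the additive-white-Gaussian-noise convention with
the ratio measured in decibels against the carried rate: each synapse
transmits `rate + N(0, (rate * 10^(-snr/20))^2)`, independently per
synapse and per trial. At the default SNR of 30 this is about 1.1 Hz (1
sigma) on a 36 Hz input; reported response variations of a few hertz
on that rate are consistent with the 2--4 sigma spread of the same
rule. Because a cell only ever uses the *sum* of its synaptic draws, the
default sampler draws that sum directly from its exact Gaussian
distribution (one draw per cell per trial); `noise_mode = "synapse"`
performs the literal per-synapse draws, and `noise_mode = "shared"`
draws one perturbation per lobula neuron per trial shared by all its
synapses. A test verifies that the collapsed and literal modes agree in
distribution.

## What the stimulus generator emulates

The pattern families (`bar_set`, `quadrant_bars`, `cross`,
`sector_disc`, `spiral_disc`, `octagon`, `checkerboard`, `mirror`)
recreate the published behavioural stimuli from their *descriptions*:
the original artwork survives only as small figure reproductions, so
sector counts, spiral twist and ring widths are package choices recorded
in each recipe's provenance. The shipped suites use a 4-arm spiral with
360 degrees of twist against its mirror image, a regular octagonal ring
against its 22.5-degree rotation, a four-sector disc against its
45-degree rotation, and plus/diagonal crosses with 140 x 30 px arms.
Rasterization is hard-edged (no anti-aliasing) so binarization is exact
and edge lengths are stable.

Two semantic points matter more than any geometric parameter:

* **Left/right reversal is an eye swap, not a mirror.** The reversed
  test patterns present the same bar orientations in the opposite eyes.
  For oblique bars a pixel mirror would additionally flip every
  orientation (theta to 180 - theta) and the MERGED model would *not* be
  blind to it. The reversal experiments therefore either use axial (0/90
  degree) bars, whose mirror is exactly the eye swap, or explicit
  quadrant-assignment swaps.
* **CS+ is always centred.** Bees learn the rewarded pattern at its
  centre; only the test stimuli are offset in the sweep experiments.

What the generator does **not** emulate: viewing geometry (distances,
visual angles), luminance calibration, motion cues, and the exact
figure-level artwork of the historical stimuli. Passing tests therefore
show that the *mechanisms* (offset collapse of DISTINCT, eye-swap
blindness and location invariance of MERGED, near-chance spirals)
reproduce, not that every printed percentage is recovered — several
printed values depend on tuning-curve fits that were never tabulated.

## Numerical choices

* Orientations are binned to 180 integer degrees; the degenerate 180
  bin folds into 0. Edge orientation is the Sobel gradient direction
  plus 90 degrees, reduced mod 180.
* All retina convolutions are explicit symmetric shift-and-add sums, so
  horizontally mirroring an image yields the bit-exact mirrored edge
  map; the mirror-equivariance tests assert exact equality, not
  tolerance.
* Canny uses sigma 1, and hysteresis thresholds at 10%/20% of the
  maximum gradient magnitude; on hard black/white stimuli the result is
  insensitive to these within wide ranges.
* The weak-edge rule is applied literally per pixel (`magnitude <= 1.7`
  on the 0--255 Sobel scale); a connected-segment-length variant
  (`edge_filter = "segment"`, minimum 9 px, the 3-degree subtense of a
  150 px tile spanning roughly 48 degrees) implements the plausible
  acuity reading and is available behind the config switch.
* A Kenyon cell with summed input exactly zero stays silent (strict
  inequality). A fully degenerate similarity triple (all three codes
  identical, unreachable with noise on) scores 0.5, i.e. indifference.
* Empty quadrants respond at 0 Hz; `S(0) = 0`.

## Problem sizes

The reproduction runs use the full protocol: 1000 trials per experiment
and offset, populations of 10,320 / 5,160 cells, 17-offset sweeps for
the discrimination suite and full triplet enumeration (12 triplets) for
generalization tests. The acceptance script recomputes every reported
quantity from scratch in a few minutes on one CPU; unit tests use
smaller trial counts where only contracts, not performances, are under
test.

## Limitations

* The idealized wrapped-Gaussian curves make the two neuron types
  exact mirror images of each other 45 degrees apart. This preserves
  every mechanism but yields sharper population codes than the
  irregular biological curves: centrally presented discriminations come
  out systematically stronger than the published simulations (and the
  MERGED variant can exceed DISTINCT on strongly lateralized patterns,
  which the published model did not show). Bands tied to absolute
  percentages of specific recreated stimuli (spiral/octagon/cross
  pairs, the 67--72% simple-generalization window) should be read with
  that in mind; the chance-level and invariance results are
  parameter-free and reproduce exactly.
* Noise amplitude follows the decibel rule; if the intended noise was
  the larger end of the quoted 2--5 Hz range, all performances compress
  toward 50% proportionally.
* No learning, no sparse coding, no feedback inhibition, no motion
  processing: these are deliberate absences of the modelled circuit,
  not omissions of the implementation.
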