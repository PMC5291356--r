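# beekc — honeybee pattern discrimination from eight neurons

Honeybees discriminate and generalize complex black-and-white patterns
with a brain of under a million neurons. `beekc` is an R implementation
of a minimal, anatomically inspired account of that ability: the only
visual input is the firing of **eight large-field orientation-sensitive
lobula neurons** (types A and B, one of each per visual-field quadrant),
and the only downstream machinery is a single layer of **binary
mushroom-body Kenyon cells** with fixed ±1 synapses and no learning.
The package is for computational neuroscientists and modellers who want
to run, probe or extend the simulated-bee experiments: pattern
discrimination, robustness to horizontal stimulus offsets (location
invariance), and generalization over quadrant-wise bar orientations.

## The model in brief

For a pattern composited into a 300 × 150 px field of view (left half =
left eye, top half = dorsal), the retina stage extracts oriented edges
(median filter, green-channel binarization, Canny/Sobel analysis) and
tabulates per-quadrant edge lengths `H(q, i)` in 1° orientation bins.
Each lobula neuron responds

    rate(x, q) = ( Σ_i  H(q,i) / Σ_i H(q,i) · C(x, i) ) · S( Σ_i H(q,i) )

where `C(x, ·)` is the type-x tuning curve (wrapped Gaussian; peaks 115°
for A and 250° ≡ 70° for B, half-maximum 45° from the peak, 36 Hz peak
for a 280 px edge) and `S(L) = (L/280)^α` a sublinear length scale
factor (α ≈ 0.812, calibrated so two printed reference stimuli drive
type A identically). 86 excitatory/inhibitory wiring configurations × 30
copies per region build Kenyon-cell populations of 10,320 cells
(DISTINCT: one quadrant per cell) or 5,160 (MERGED: same dorsal/ventral
band of both eyes). Each cell fires iff its signed, noise-perturbed
(AWGN, SNR 30) synaptic sum is positive. A trial presents rewarded CS+,
correct TS^COR and incorrect TS^INC patterns and scores

    KCSR = 1 − E(CS+, TS^COR) / ( E(CS+, TS^COR) + E(CS+, TS^INC) )

with `E` the Euclidean distance between binary population codes;
percent-correct performance is 100 × mean KCSR over 1000 trials.

## Worked example

Discriminating an upright plus cross from its 45°-rotated version with
the MERGED (both-eyes) model:

```r
library(beekc)
cfg <- beekc_config()

cross <- make_pattern(pattern_recipe("cross", rotation = 0, uid = "cross_plus"))
H <- preprocess(composite_offset(cross, 0), cfg)
print(H)
#> <edge_histogram>  edge px per quadrant:
#>   dorsal_left  ventral_left  dorsal_right ventral_right
#>           192           192           192           192

losn_vector(H, cfg)
#> <losn_response 'cross_plus@+0' (Hz)>
#>   dorsal_left ventral_left dorsal_right ventral_right
#> A       15.49        16.49        16.49         15.49
#> B       17.04        16.20        16.20         17.04

pats <- list(cross_plus = pattern_recipe("cross", rotation = 0,  uid = "cross_plus"),
             cross_diag = pattern_recipe("cross", rotation = 45, uid = "cross_diag"))
sp <- experiment_spec("crosses", "cross_plus", "cross_plus", "cross_diag",
                      model = "MERGED", n_trials = 1000)
run_experiment(sp, pats, cfg, seed = 1)
#> <experiment_result 'crosses' MERGED offset +0 px: 1000 trials>
#>   KCSR mean 0.6415 (sd 0.0234, min 0.5505, max 0.7343)
#>   performance 64.1%
```

The histogram says each quadrant carries 192 px of edge; the eight
lobula rates are nearly equal because a plus cross mixes 0° and 90°
edges symmetrically, and the resulting MERGED performance (~64%) shows a
weak discrimination of the rotated cross — binocular pooling trades
central acuity for location invariance. The shipped suites
(`study_discrimination()`, `study_generalization()`, `study_crosses()`,
also installed as YAML under `inst/extdata/studies/`) reproduce the full
experiment sets; `run_study()` returns a tidy results table, and
`run_offset_sweep()` exposes the 17-step ±200 px offset protocol. A thin
command-line front end is installed at `exec/beekc` (subcommands
`generate-stimuli`, `preprocess`, `losn`, `run`, `sweep`, `report`).

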