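---
title: "Quantifying two-tone spectrotemporal interaction in calcium imaging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying two-tone spectrotemporal interaction in calcium imaging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The measurement problem

Neurons in auditory cortex do not sum their inputs linearly: the response
to two tones presented together routinely exceeds, or falls short of, the
sum of the responses to each tone alone. `stimap` quantifies this
nonlinear integration from two-photon calcium imaging. The stimulus
design crosses a frequency offset dF (−1 to +1 octave around a fixed
center tone, 0.25-oct steps) with an onset interval dT (−100 to +100 ms,
25-ms steps; negative dT = offset tone leads), giving a 9 × 9 grid of
two-tone conditions plus each component tone alone, five randomized
blocks of trials, 5-s inter-trial intervals. A shifted tone pair is also
a rudimentary frequency-modulated (FM) step: dF = 0.25 oct at dT = 100 ms
moves at 2.5 oct/s, dF = 1 oct at dT = 25 ms at 40 oct/s — the ethological
range of mouse vocalizations — which is why the package also analyzes FM
sweep responses (2.5–80 oct/s, both directions) from the same cells.

The core statistic is the linearity index

$$\mathrm{LI} = \frac{T - L}{T + L},$$

where $T$ is the mean response amplitude to the tone pair and $L$ the sum
of the component-tone amplitudes; amplitudes are clamped at zero first,
so LI ∈ [−1, 1], positive = supralinear (facilitative), negative =
sublinear (suppressive). The per-neuron 9 × 9 LI grid is the
*spectrotemporal interaction map*.

## From fluorescence to response amplitudes

Raw ROI fluorescence is corrected for neuropil contamination by
subtracting 0.9 × the mean of a ring of background pixels
(`compute_dff`); ring pixels carrying transients uncorrelated with the
cell (events ≥ 3 × the robust SD for ≥ 5 consecutive frames while
r < 0.2 with the cell trace) are excluded first
(`exclude_contaminated_pixels`), and cells less than 3% brighter than
their ring are dropped (`qc_brightness_filter`). dF/F uses a per-trial
baseline (1 s before onset) with a 20 a.u. offset in the denominator to
guard against dim baselines.

Response amplitudes are baseline-subtracted mean dF/F over
stimulus-specific windows: 1 s from onset for two-tone and component
tones, 1.2 s for 1-s pure tones, and onset to 0.3 s after offset for FM
sweeps (GCaMP6s is slow, so windows extend well past the sound). The
area under the curve is stored alongside; all downstream indices use the
mean, and the two agree exactly up to the window-duration factor.

A response is *significant* (`detect_significant_response`) only if
dF/F exceeds 3.3 × the baseline SD for at least 0.5 s of consecutive
frames (15 frames at 30 Hz) in strictly more than half of the trials,
and the trial-averaged trace does so too. Choices this criterion leaves
open, fixed here: the baseline period is the 1 s before
onset, its SD is pooled over all trials of the ROI, the same threshold is
applied to single trials and to the trial average, and "more than half"
is a strict inequality (3 of 5). On 200 simulated pure-noise cells this
dual criterion flags essentially nothing (false-positive rate ≪ 5%).

## Interaction maps and their statistics

`build_interaction_map` computes LI per grid cell from trial-mean
amplitudes, but only where the significance gate holds — the pair itself,
the center tone, or the dF tone must be significant; cells where both
$T$ and $L$ clamp to zero are undefined and stored as invalid rather
than imputed. Smoothing (`smooth_map`) uses a 2-D Gaussian of SD 0.4
grid units (0.1 oct along dF, 10 ms along dT) whose weights are
renormalized over the valid cells actually present, so map edges and
invalid cells do not drag estimates toward zero — with zero-padding a
lone supralinear cell would be diluted by fictitious zeros.

Per-cell facilitation/suppression calls (`test_nonlinearity`) compare
the five two-tone trial amplitudes against the 25 pairwise sums of the
5 × 5 component-tone trials with a two-sided Wilcoxon rank-sum test at
α = 0.1 (a deliberately permissive level given five trials per
condition), reading the direction from the sign of the mean difference (the test is
two-sided; sidedness is a package choice).
**Known limitation:** the 25 sums are built from only 10 underlying trial
values and are therefore strongly interdependent, while the rank-sum
test treats them as exchangeable with the two-tone trials. On simulated
null data (two-tone amplitudes drawn independently from the sum
distribution) the empirical type-I rate is ≈ 0.2 at α = 0.1 — about
twice nominal, robustly across noise models. The package keeps the
standard form of this trial-pairing test and reports the inflation
rather than hiding it;
interpret per-cell facilitation/suppression maps accordingly.

Timing preference (`classify_timing_preference`) compares the mean
amplitude for coincident pairs (dT = 0) against shifted pairs with a
1.5× ratio rule, each averaged over a configurable 5-dF set
({−1, −0.5, 0, 0.5, 1} oct by default; the 5 dFs × 8 shifted dTs = 40
pair count is preserved for any 5-element set). Shift-preferring cells split into
negative-/positive-dT-preferring by the same ratio, else symmetric. The
asymmetry index |(P − N)/(P + N)| contrasts summed amplitudes for
positive vs negative dT.

## FM direction selectivity and LI bias

DSI = (U − D)/(U + D) on clamped amplitudes; a cell's summary DSI
averages U and D over 10–40 oct/s *before* taking the index (not a mean
of per-rate DSIs), using only rates with a significant response in at
least one direction. The interaction map is split into an Upward region
(dF·dT > 0 quadrants) and a Downward region (dF·dT < 0); `linearity_bias`
sums positive LI (Bias_fac) and negative LI (Bias_supp) separately and
takes Upward − Downward. Two deliberate choices: the bias uses the raw,
unsmoothed map (smoothing bleeds across quadrant borders) and sums all
valid cells, not only statistically significant ones. With
this orientation, weaker suppression in the Upward region gives positive
Bias_supp and predicts positive DSI; `correlate_dsi_bias` tests the
association with Pearson's R and the t-test on n − 2 df, with per-rate
variants Bonferroni-corrected.

## Ensemble analysis

`population_vectors` concatenates all ROIs (across animals) into one
vector per condition, zero-forcing non-significant entries for
de-noising. Per (dF, dT) pair, the two-tone vector is correlated with
the linear-sum vector (center + dF single-tone vectors, zero-forced
before summation) and with each single-tone vector; curves average over
dFs, excluding dF = 0 where the "dF tone" duplicates the center tone
(8 dFs × 8 shifted dTs = 64 shifted and 8 coincident pairs).
Zero-variance pairs are skipped, not imputed. Area × timing contrasts on
pair-level correlations use two-way ANOVA with Tukey's HSD, and
`two_tone_only_fraction` reports the single-tone-silent neurons recruited
by tone pairs.

## The synthetic-data generator

No raw recordings are distributed with the package, so every stage is
validated against a forward model (`simulate_population`,
`synthesize_trial_traces`) whose ground truth is known:

* **Kernels.** Each cell owns a true LI kernel. `a2_coincident` has a
  supralinear dT = 0 column (Gaussian over dF) on a uniform sublinear
  background; `a1_asymmetric` has an off-axis supralinear cluster and a
  sublinear background whose strength differs between the Upward and
  Downward regions by a per-cell asymmetry `a`; `sublinear_uniform` and
  `linear` are controls. The cluster *replaces* the background rather
  than adding to it, and per-cell jitter preserves the template's sign
  structure, so facilitative and suppressive asymmetries are independent
  by construction — the property under test in the DSI analysis.
  Kernel values are capped at |LI| ≤ 0.95 so the inversion
  $T = L(1+\mathrm{LI})/(1-\mathrm{LI})$ stays finite.
* **Heterogeneity.** Center-tone amplitudes are lognormal (median 0.5
  dF/F), dF tuning Gaussian with variable width, and the supralinear
  peak is drawn per cell from U(0.3, 0.9). This cell-to-cell variation
  in nonlinear gain is what makes coincident two-tone ensembles diverge
  from linear-sum predictions; a homogeneous population would keep the
  two proportional and the correlation near 1 at every dT.
* **Traces.** A trial is amplitude × a unit-peak difference-of-
  exponentials transient (rise 0.2 s, decay 1.5 s — chosen as GCaMP6s-like
  values slow enough that the 0.5-s consecutive-frames criterion is
  meaningful; the indicator literature spans a range and both are
  configurable), plus lognormal multiplicative trial noise (CV 0.2) and
  Gaussian baseline noise (SD 0.05 dF/F). Trial-to-trial variability
  magnitudes are free parameters, not estimates from data.
* **Sweeps.** FM amplitudes taper with rate; the direction preference is
  `s = tanh(coupling · a + ε)`, so direction selectivity is driven by the
  suppressive-bias asymmetry when `coupling = 1` (the default) and is
  pure noise at `coupling = 0`.
* **Determinism.** One global seed expands to per-cell substreams by
  counter, so enlarging a population never reshuffles existing cells,
  and all generation is bit-reproducible.

What the generator does *not* emulate: correlated noise across trials
and neurons, response latency shifts with dT, adaptation across blocks,
motion artifacts, and spike-to-fluorescence biophysics. Passing recovery
tests therefore demonstrates correctness of the analysis arithmetic and
its gating logic under the stated noise model, not robustness to every
failure mode of real recordings.

The amplitude model places a single transient at trial onset whose size
encodes the whole pair's response; windowed means then estimate
amplitude × a known kernel-shape gain that cancels in every ratio index
(LI, DSI, asymmetry), which is why noise-free kernels are recovered to
machine precision and absolute amplitudes need the explicit
`kernel_window_gain` correction.

## Numerical and degenerate-input conventions

LI, DSI and the asymmetry index are undefined (NA) when both operands
clamp to zero; undefined map cells are excluded from smoothing, averages
and bias sums. A zero baseline SD makes the detection threshold
degenerate and raises an error unless an absolute floor is configured.
All-tied samples in the rank-sum test return "none". If every background
pixel is flagged as contaminated, the unfiltered mean is used with a
warning. Chi-square tests on fractions omit the continuity correction by
default (configurable); Bonferroni adjustment is min(1, p·m) over a
declared family.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` run 60 cells per population; the
acceptance script uses 200 cells for LI-recovery and false-positive
measurements, 500 simulations for the type-I rate, and 300 cells per
template for the population contrasts — sizes at which every recovery
property is stable while a full run stays in the minutes range on one
core. All thresholds keep their canonical defaults (3.3 SD, 0.5 s,
α = 0.1, ratio 1.5, σ = 0.4 grid units, 0.9 background coefficient,
20 a.u. offset, 1.03 brightness ratio), asserted by the test suite.
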