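---
title: "From TIRF movies to conformational kinetics: the smfretr methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From TIRF movies to conformational kinetics: the smfretr methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfretr)
```

## The measurement

smfretr analyses two-colour single-molecule FRET recordings of
surface-immobilized protein complexes, of the kind used to watch the
RodA-PBP2 peptidoglycan synthase exchange between a *closed* conformation
(donor and acceptor dyes 30–40 Å apart, FRET efficiency 0.8–1) and an
*open* conformation (70–80 Å, FRET efficiency roughly 0.2–0.5). Molecules
are excited in a repeating cycle — two frames of 532 nm (donor) excitation
followed by one frame of 641 nm (direct acceptor) excitation — at 4
frames s⁻¹ with 250 ms exposure by default; a fast mode (10 s⁻¹, 100 ms) is
available for rapidly exchanging variants. The 641 nm frames report whether
the acceptor is present and alive; the 532 nm frames carry the FRET signal.

The pipeline runs: **simulate/load → detect spots → register channels →
extract traces → correct and compute FE → truncate at photobleaching and
QC → HMM state segmentation → dwell-time kinetics and transition maps →
structural classification via the Förster equation**. Every stage is an
exported function; `run_pipeline()` wires them together from one
configuration list (`default_config()` shows every tunable with its
default).

## The simulator, and what it does (not) emulate

Because the raw study movies are external data, the package carries a
ground-truthed generator at two levels.

*Continuous level.* `simulate_state_path()` samples the conformational
chain by the Gillespie algorithm: dwells in state *i* are exponential with
the total exit rate of *i*, successors are drawn proportional to the
outgoing rates. `discretize_path()` integrates the path over each exposure
window, so a transition inside a frame produces the correct intermediate
frame FE. `emit_intensities()` applies the forward optical model; on 532 nm
frames

* donor channel: `I_tot * (1 - E)` (full `I_tot` once the acceptor has
  bleached),
* acceptor channel: `gamma * I_tot * E` + `alpha` × (donor signal) +
  `delta` × (641 nm acceptor brightness),

and on 641 nm frames the acceptor channel reports the direct acceptor
brightness while the acceptor survives. Photobleaching is irreversible and
single-step per fluorophore (exponential survival; blinking is deliberately
not modeled, since only bleaching enters the quality control).
`render_movie()` draws each molecule as a symmetric Gaussian PSF (default
sigma 1.3 px) at its position in the donor channel and at position +
`channel_shift` in the acceptor channel, then adds Poisson shot noise and
Gaussian read noise per pixel. Pixel coordinates are 0-based at pixel
centers, and the channel shift is a pure translation.

Defaults (`total_intensity` 500 photons/frame, background 20
counts/pixel, read noise 2) put a single spot at a peak signal-to-noise of
about 5, and per-frame FE scatter arises from shot noise alone; an extra
Gaussian broadening can be added via the per-state emission SDs. What the
simulator does **not** emulate: EMCCD gain statistics, optical aberrations,
stage drift, dye blinking, and acceptor photophysical dark states. Passing
tests therefore demonstrate correctness of the *analysis* under the model's
assumptions, not robustness to every artifact of real hardware.

*Frame level.* `simulate_fe_dataset()` skips imaging: hidden states follow
a discrete Markov chain at the FE-frame period with Gaussian emissions, and
trajectories truncate at an exponential bleach time. This is the generator
used to benchmark the HMM and kinetics stages at scale (hundreds of
trajectories in seconds).

## Detection and registration

Acceptor particles are picked from the average of the first five 641 nm
frames: the image is Gaussian-smoothed (sigma 1 px), a rolling-median
background is subtracted, and local maxima above median + 5×MAD survive
non-maximum suppression at 5 px. The smoothing/background/threshold
parameters are all exposed; the defaults were chosen once for the
SNR-5 regime. The donor channel is registered by exhaustive integer
translation maximizing the normalized cross-correlation, refined to
sub-pixel precision by a quadratic fit — translation only, matching how
such channel pairs are aligned in practice. By default donor positions are
obtained purely by registration of the acceptor picks; independent
donor-channel picking plus mutual-nearest-neighbour matching (tolerance
1.25 px, ties by distance then index) is available with
`pick_both = TRUE`.

Each candidate is then fit with an elliptical 2D Gaussian on a 7×7 window
and again on the window rotated 45° (bilinear interpolation about the
window center). Spots are accepted when both ellipticity scores
(long/short axis, boundaries inclusive) lie in 1–1.2; wider spots indicate
two emitters. One numerical choice deserves a note: the ellipticity of a
fit whose amplitude is below ~10× the fit's residual noise is essentially a
draw from the noise, and filtering on it would discard about a third of
genuine single emitters — typically the *donor* channel of a high-FRET
molecule, which is intrinsically dim. Such channels are treated as
unassessable rather than rejected (`min_fit_snr`), and doubly-labeled
molecules are still caught downstream by bleach-step counting.

## Traces, corrections, truncation, QC

`extract_traces()` performs aperture photometry (radius 3 px, annulus
5–7 px, annulus-median background) at the registered positions, split by
excitation label. The three-factor spectral correction is the standard
one:

```
F_A = I_A − alpha · I_D − delta · I_A(641, nearest frame)
FE  = F_A / (F_A + gamma · I_D)
```

`alpha` (donor bleedthrough) and `delta` (direct excitation) are estimated
as medians of the obvious intensity ratios over donor-only and
acceptor-only calibration molecules; `gamma` as the median ratio of the
acceptor drop to the donor rise across single acceptor-bleach steps, after
bleedthrough/direct-excitation correction of the acceptor signal (on the
corrected signal the ratio equals `gamma` exactly under the forward model;
on the raw signal it would be biased by `delta/E − alpha`). FE is never
clipped: values outside [0, 1] are kept and counted, and only histogram /
mixture fitting excludes values outside [−0.2, 1.2] as artifacts.

Photobleaching is found by binary-segmentation change-point detection — on
the 641 nm acceptor series for the acceptor, and on the state-free total
`I_D + I_A/gamma` for the donor, so truncation never depends on state
inference. A step must drop by at least half the pre-step level, persist
for 4 frames, and exceed 6× the series' frame-to-frame noise scale (the
last guard prevents post-bleach noise around zero from faking extra
steps). Trajectories truncate at the earliest bleach; more than one step
per fluorophore rejects the molecule (`multi_fluorophore`), as do a dark
641 nm channel (`no_acceptor`: median pre-truncation signal below 5× its
noise scale) and fewer than 20 usable FE frames (`too_short`, ≈7.5 s at
the default cycle).

## State inference

The ensemble HMM is maximum-likelihood Baum–Welch with Gaussian emissions:
parameters shared across molecules, each trajectory an independent
sequence. Initialization is deterministic (means at the 25/75th — or
15/50/85th — percentiles, SDs at half the pooled SD, stay probability
0.95); convergence is declared when the per-frame log-likelihood improves
by less than 1e-6 (cap 500 iterations), and the log-likelihood is asserted
non-decreasing at every step. `K` is fixed from the configuration (2 or 3,
as the ensemble plots assume a two- or three-state model); the fit is
maximum-likelihood rather than variational-Bayes, which removes
prior-specification ambiguity while preserving the role of the stage.
Component variances are floored at 1e-4 with a warning if a state
collapses. After convergence, states whose means are separated by less
than one emission SD are merged onto the higher-occupancy member (with a
warning): such states are not distinguishable conformations, and the merge
gives the sensible degenerate-case behavior when single-state data are fed
to a two-state model. `viterbi()` decodes exact maximum-probability paths.

`fe_histogram()` produces probability-density histograms (density × bin
width sums to 1) and `fit_mixture()` the K-component Gaussian ensemble
fits; both use deterministic initialization, report components sorted by
mean, and were cross-checked against an independent EM implementation.

## Kinetics and censoring

Viterbi runs become dwells (duration = run length × FE-frame period; at
the default `[532, 532, 641]` cycle the mean FE-frame spacing is 0.375 s).
The censoring rule is deliberately strict: a dwell counts as uncensored
only when **both** ends coincide with observed transitions — trajectory
start, movie end, and photobleach truncation all censor, which is slightly
stricter than requiring only freedom from photobleach censoring, because
boundary dwells have unknown true extent. A molecule with no transitions
contributes nothing to the fits. `tau` is the mean of uncensored dwells
(the exponential MLE) with the exact chi-square 95% interval
`[2n·tau/χ²(0.975, 2n), 2n·tau/χ²(0.025, 2n)]`.

Two biases are worth knowing about. First, interior (transition-bounded)
dwells are length-biased *short* when the observation window is not much
longer than the dwell time: at a mean observation of 100 s, a 12.5 s state
fits about 14% low while a 5 s state is essentially unbiased. Second, no
correction is applied for transitions faster than the frame period — fast
exchangers should be recorded in the 10 s⁻¹ mode, and their shortest events
are still missed.

Transition-density maps record, for every state change whose **new** state
persists for at least two FE frames (the minimal reading of "more than a
frame"), the mean FE of the preceding and following dwells — dwell means,
not fitted state means, make the spread of the low-FRET ensemble visible —
binned at 0.05 over [0, 1] and normalized by the total pre-truncation
observation time. `population_summary()` reports per-state occupancy,
per-state trajectory-visit fractions and the dataset transition frequency.

## Structural interpretation

`fe_from_distance()` implements `E = 1/(1 + (r/R0)^6)` and
`distance_from_fe()` its exact inverse. The Förster radius defaults to
54 Å, a typical value for the sulfo-Cy3/Cy5 pair, with orientation-factor
and refractive-index effects considered absorbed into `R0`; it is
config-overridable since the dye environment shifts it by a few Å. With
any `R0` in 50–60 Å the closed-state window (30–40 Å) maps to FE ≥ 0.8 and
the open-state window (70–80 Å) to FE ≤ 0.5, which is the consistency
check the acceptance script recomputes. `classify_states()` labels fitted
states by the FE window containing their mean; means outside all windows
are "intermediate" — the point-dipole prediction at 70–80 Å is lower than
the observed low-FRET values, consistent with the low-FRET population
containing partially open intermediates, so the two views are reported
side by side rather than forced to agree.

## Problem sizes and reproducibility

The shipped fixtures are small by design: 64×64 px movies, 90 s at
4 s⁻¹ (360 frames), 16–24 molecules; the frame-level benchmark uses 200
trajectories × up to 1200 frames. These sizes give the parameter-recovery
checks comfortable statistical margins (FE means recover to well under
0.01 at that scale) while keeping a full test run under a minute. All
stochastic stages take explicit integer seeds; identical seed + config
reproduce bit-identical movies, tables and reports.

## Known limitations

* No drift correction beyond the 1.25 px matching tolerance; no 3D or
  astigmatic localization.
* No ALEX stoichiometry, no per-molecule gamma refinement.
* Dwell fits are single-exponential with no censored-likelihood terms;
  heterogeneous kinetics would need a different estimator.
* The HMM is shared-parameter maximum likelihood; molecule-to-molecule
  parameter variability is not modeled.
* Equivalence with variational-Bayes implementations is not claimed — only
  the role of the stage (unbiased state segmentation) is preserved.
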