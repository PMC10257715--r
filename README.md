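# smfretr

Single-molecule FRET (smFRET) trajectory analysis for conformational
dynamics of surface-immobilized protein complexes — built around the
closed/open exchange of SEDS-bPBP peptidoglycan synthases such as
RodA-PBP2, where the closed conformation places the two dyes 30–40 Å apart
(FRET efficiency 0.8–1) and structural opening moves them to 70–80 Å
(low FRET).

The package takes two-channel TIRF movies (or pre-extracted intensity
tables) through the full analysis chain:

1. **Detection** — acceptor spot picking on an averaged first-frames image,
   channel registration by cross-correlation (sub-pixel), donor/acceptor
   pairing within 1.25 px, and a two-orientation 2D-Gaussian ellipticity
   filter (1–1.2) that excludes multi-fluorophore spots.
2. **Trajectories** — aperture photometry, the three-factor spectral
   correction (donor bleedthrough `alpha`, direct acceptor excitation
   `delta`, detection/quantum-yield ratio `gamma`),
   `FE = F_A / (F_A + gamma * I_D)`, change-point photobleach truncation
   and single-fluorophore quality control.
3. **State inference** — an ensemble hidden Markov model (shared Gaussian
   emissions and transition probabilities, Baum–Welch EM, exact Viterbi
   paths), plus probability-density FE histograms with K-component
   Gaussian-mixture fits.
4. **Kinetics** — dwell times with strict transition-bounded censoring,
   exponential fits with exact chi-square 95% intervals, and
   transition-density maps normalized to total observation time.
5. **Structure** — the Förster relation `E = 1/(1 + (r/R0)^6)` (default
   `R0` = 54 Å for sulfo-Cy3/Cy5) maps fitted FE states onto
   closed / open / intermediate conformations.

A ground-truthed simulator (Gillespie state paths, photophysics,
bleedthrough/direct-excitation/gamma forward model, Gaussian-PSF camera
with Poisson + read noise) generates movies and trajectory ensembles so
every stage is testable without external data.

## Worked example

Simulate a two-state ensemble at the standard acquisition settings, fit
the ensemble HMM, and extract kinetics:

```r
library(smfretr)

d <- simulate_fe_dataset(n_traj = 100, means = c(0.35, 0.82), sds = 0.08,
                         trans = c(0.98, 0.95), frame_period = 0.25,
                         movie_duration = 300, bleach_rate = 0.01, seed = 1)
hmm <- fit_hmm(d$fe, K = 2)
hmm
#> <fret_hmm> K = 2, logL = 38264.64 (5 EM iterations)
#>   state 1: FE 0.350 +- 0.080, stay prob 0.9797
#>   state 2: FE 0.820 +- 0.080, stay prob 0.9477

paths  <- lapply(d$fe, function(x) viterbi(hmm, x))
dwells <- extract_dwells(paths, frame_period_s = 0.25, fe = d$fe)
dwell_fits(dwells)
#> $`1`
#> <dwell_fit> state 1: tau = 11.077 s (95% CI 10.173-12.108, n = 507)
#> $`2`
#> <dwell_fit> state 2: tau = 4.597 s (95% CI 4.234-5.010, n = 544)

classify_states(hmm)
#>   state   mean_fe  label distance_estimate
#> 1     1 0.3501061   open          59.86425
#> 2     2 0.8195830 closed          41.96055
```

The HMM recovers the generating FE means (0.35/0.82) and per-frame stay
probabilities (0.98/0.95) essentially exactly; the mean dwell of the
low-FE state comes out at 11.1 s against a true 12.5 s (interior dwells
are slightly length-biased short when the observation window is finite —
see the methods vignette), and the high-FE state at 4.6 s against a true
5 s. The classification maps the fitted states onto the open and closed
conformations with their implied inter-dye distances in Å.

Full movie-level runs go through one call:

```r
report <- run_pipeline(list(seed = 3,
                            simulate = list(n_molecules = 20),
                            out_dir = "wt_run"))
```

which writes particle/pair/trajectory/dwell tables (CSV), model and QC
summaries (JSON) and optional plots, and returns the run report. A thin
CLI (`exec/smfret`) exposes `simulate`, `run` and `fixtures` subcommands
with `--config`, `--seed`, `--out` and `--input` flags; configurations are
YAML files merged over `default_config()`.

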