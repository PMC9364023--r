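---
title: "Determining the oligomeric state of DNA-bound proteins from quantum-dot blinking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining the oligomeric state of DNA-bound proteins from quantum-dot blinking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoblink)
```

## The problem

Single-molecule imaging of fluorescently labeled transcription factors on
suspended DNA ("tightropes") shows diffraction-limited spots bound to and
diffusing along the DNA.  A spot's intensity cannot tell you whether it is
one labeled protein or two: quantum-dot (Qdot) brightness is not additive in
any usable way.  `oligoblink` implements three independent, quantitative
routes to the monomer/dimer question:

1. **Blink statistics ("fluorescence redundancy").**  Qdots stochastically
   blink into dark states.  A complex carrying *two* independently blinking
   Qdots only goes fully dark when both are dark at once, so its complete-
   darkness *rate* is the square of a single emitter's.  Blink counts per
   fixed-duration kymograph are therefore Poisson with mean `bl` for
   monomers and mean `(bl/dur)^2 * dur` for dimers — a one-parameter link.
2. **Two-color labeling combinatorics.**  If each subunit picks one of two
   Qdot colors with equal probability, half of all dimers end up
   single-colored (AA or BB), so the observed dual-colored fraction
   *underestimates* the dimer fraction by exactly a factor of two.
3. **Bulk-phase difference spectra.**  For FRET excitation scans and
   circular dichroism (CD) scans, the sum of the component spectra predicts
   the mixture spectrum in the absence of interaction; a band-localized
   deviation of the measured mixture from that sum reports coupling
   (energy transfer, or a DNA structural change at the 281 nm band).

## The blink mixture model

For a population that is part monomer, part dimer, the probability of
observing `n` blinks in a kymograph of duration `dur` is

\[
  p_\mathrm{blink}(n) \;=\; \alpha\,\mathrm{Pois}(n;\,bl)
  \;+\; (1-\alpha)\,\mathrm{Pois}\!\left(n;\,(bl/dur)^2\,dur\right),
\]

with only two kinds of free parameter: the monomer expectation `bl`
(blinks/kymograph) and the monomer amplitude `alpha` per dataset.  The dimer
expectation is *recomputed from `bl` at every optimizer step* — it is a hard
constraint, not a fitted quantity.  When two conditions are measured with
the same Qdot preparation, `bl` is shared and fitted jointly to both
histograms, which is how `fit_dual_poisson()` operates:

```{r}
ha <- blink_histogram(simulate_blink_counts(
  mixture_sim_params(bl_mon = 10.8, duration_s = 60, alpha = 0.129,
                     n_kymographs = 50, seed = 7)), duration_s = 60)
hb <- blink_histogram(simulate_blink_counts(
  mixture_sim_params(bl_mon = 10.8, duration_s = 60, alpha = 0.542,
                     n_kymographs = 50, seed = 8)), duration_s = 60)
fit_dual_poisson(ha, hb, n_boot = 200, seed = 9)
```

### Numerical choices

* **Objective.**  Sum of squared differences between observed and model
  percentages over integer bins `0..max(observed)` (zero-padded), summed
  over both datasets.  Working on the percentage scale makes datasets of
  different sizes commensurate and mirrors how such histograms are plotted.
* **Optimizer.**  Bounded L-BFGS-B with analytic gradients, 10 starts with
  `bl` spread over `[0.5, 30]` crossed with an amplitude grid, best
  objective wins, ties broken towards the smaller `bl` (the mixture can
  have a mirror optimum at high `bl` when one dataset dominates).  A final
  polish restarts from the incumbent.  Amplitudes are *bounded* in `[0,1]`
  during optimization, never truncated afterwards.
* **Uncertainty.**  The `±` on the dimer percentages is a bootstrap
  standard error: kymographs are resampled with replacement (1,000
  replicates by default, seeded) and the model refit from the point
  estimate.  This is a deliberate, labeled definition — fit-covariance or
  profile intervals would be alternatives.
* **R².**  `1 - SSE/SST` with SST about the grand mean of all observed
  percentages across both datasets, so the statistic describes the joint
  fit.

Noise-free identifiability is exact: histograms built from the model's own
pmf return the generating parameters to ~1e-9.  At the study scale (50
kymographs per condition) the estimator is noisy but calibrated: across 100
replicate experiments the true dimer percentages fall within 2 bootstrap
SEs more than 90% of the time (this is exactly what the acceptance suite
measures).

## Kymograph analysis

Each kymograph frame (a 1D intensity profile across the DNA) is fitted with
`amplitude * exp(-(x-center)^2 / (2 sigma^2)) + offset` by
Levenberg–Marquardt.  Initialization: center at the argmax pixel, offset at
the median, amplitude at `max - median`, `sigma` at 1.5 px, with one
restart from the intensity centroid on failure.  The key empirical fact the
pipeline exploits is that this fit is *good* when an emitter is present
(R² > 0.9) and *consistently poor* on pure background (R² < 0.7), so R²
itself is the ON/OFF classifier:

* `r2 >= 0.9` → ON; `r2 < 0.7` → OFF.
* Frames in the 0.7–0.9 band inherit the nearest *preceding* resolved state
  (hysteresis).  Leading unresolved frames take the first resolved state; a
  track with no resolved frame is entirely OFF.  Only the two thresholds are
  principled; the gap rule is our design choice and is deliberately inert —
  at the default signal-to-noise the band is rarely visited.
* A **blink** is a maximal OFF run strictly inside the record.  OFF runs
  touching the first or last frame are censored (their true extent is
  unknown) and are not counted — and the simulator's ground-truth counter
  applies the identical rule, so oracle comparisons are exact.  Blinks
  separated by a single ON frame are not merged.
* A flat (zero-variance) profile gets R² = 0, hence OFF: no spot present.
* Indices are 1-based (R convention) with continuous subpixel centers;
  positions convert to nm by multiplying by `pixel_nm`.

`track_msd()` summarizes motion as a mean-squared displacement over ON-frame
positions (lags up to a quarter of the record, pairs spanning OFF frames
omitted); for a 1D random walk with diffusion coefficient `D` the expected
slope is `2 D` per unit lag.

## Two-color stoichiometry

`expected_color_distribution()` enumerates the subunit-labeling outcomes
exactly: each subunit carries a label with probability `e` (the labeling
efficiency) and, if labeled, is color A or B with probabilities
`(p_a, p_b)`.  A visible dimer is dual-colored with probability
`2 p_a p_b e^2 / (1 - (1-e)^2)`, which is 1/2 at the defaults.
`estimate_dimer_fraction()` divides the observed dual fraction by that
probability (binomial standard errors, scaled by the same factor).  Two
consequences worth noting:

* the estimand is the dimer fraction *among visible entities* — with full
  labeling efficiency that is the population dimer fraction;
* lowering `e` lowers P(dual | dimer), so ignoring incomplete labeling
  biases the estimate downward — singly colored species become
  overrepresented.  The efficiency is exposed rather than assumed.

Estimates above 1 (counts incompatible with the assumptions) are capped at
1 and flagged rather than erroring, to keep noisy small-n pipelines moving.

## Difference spectra and band scores

`sum_spectra()` and `difference_spectrum()` do exactly what they say, with
one sign convention: the difference is **mixture − sum**, so an interaction
that *enhances* the mixture appears as a positive band.  Grids must match
exactly; resampling happens only through the explicit, message-logging
`regrid_spectrum()`.

`band_enhancement()` integrates the difference over a band (trapezoid rule),
reports the in-band peak position, and standardizes the integral against
noise estimated from the out-of-band points: `z = I / (s * sqrt(sum(w^2)))`
with `w` the quadrature weights.  Because a 10 nm-step excitation scan
leaves only ~16 out-of-band points, the raw standard deviation is an
unreliable noise estimate; the scale is therefore inflated by
`sqrt(df / qchisq(0.2, df))`, a chi-square-based factor that makes the score
slightly conservative under the null (about 97% of null scores fall inside
±2 rather than the nominal 95%).  For a detection statistic, underclaiming
beats overclaiming.  Default bands: 480–520 nm for the donor
(mNeonGreen-type) excitation region of a 450–650 nm scan, and 271–291 nm
around the 281 nm DNA CD band.

## What the simulators emulate — and what they don't

The generator exists so that every stage has ground truth.  Its defaults
*are* the study conditions and are not tuned per test:

* **Kymographs**: 60 s at 10 frames/s, 63.2 nm pixels, PSF sigma 1.5 px.
  One diffusing spot (a dimer's two emitters co-move: at diffraction-limited
  resolution a dimer is one spot).  Blinks arrive as a Poisson process in
  time (rate 0.18/s per emitter, giving roughly the observed ~10 monomer
  blinks per minute) with geometric dark dwells of mean 3 frames.  Signal is
  a 200-count Gaussian peak with Poisson shot noise over a background of
  10 ± 3 counts — chosen once so that ON frames fit with R² > 0.9 and OFF
  frames with R² < 0.7, reproducing the thresholding behavior the analysis
  relies on.  Diffusion is a reflected 1D walk with D = 0.21 px²/frame, so a
  spot explores ~1 µm over a minute.  The dark-dwell, SNR and D of the real
  instrument are not published; these values reproduce the *analysis
  regime*, not the hardware.
* **Blink counts**: drawn from the mixture model itself — which makes
  mixture-fit tests partly an inverse crime by design; that is why the
  image-based pipeline is tested against its own independent ground truth
  as well.
* **Dual-color populations**: exact multinomial draws from the enumerated
  labeling combinatorics.
* **Spectra**: Gaussian bands with plausible centers/widths (mNeonGreen-like
  506 nm, mCherry-like 587 nm; protein 208/222 nm CD bands, DNA 281 nm
  band) plus iid Gaussian noise; coupling adds a band-localized term that is
  linear in the coupling coefficient, and the CD simulator's
  `consensus = FALSE` switch suppresses it to emulate DNA lacking the
  recognition site.

None of this models real camera noise calibration, Qdot emission spectra,
spectral bleed-through, multi-spot fields, or 2D motion.  Passing tests
demonstrate that the *analysis* is correct and calibrated on data obeying
its assumptions — not that those assumptions hold for any particular
instrument.

## Problem sizes and runtime

The package's own test suite runs the full study scale where it matters:
100 replicate experiments of 2 × 50 kymographs with 1,000-replicate
bootstraps for the recovery check (a few minutes), 200 synthetic kymographs
(120,000 frame fits) for the blink-calling oracle, and 1,000 seeded trials
for the null distribution of the band score.  The end-to-end
`run_replication()` default config analyzes a handful of full kymograph
images (frame fitting is the slow stage at ~0.5 s per 600-frame kymograph)
while fitting blink counts at the full two-condition scale.

## Known limitations

* The bootstrap SE is one reasonable uncertainty definition among several;
  it will not numerically match error bars computed by other conventions.
* The mixture model assumes exactly two populations (no higher oligomers)
  and identical Qdot blink statistics across conditions.
* Blink calling assumes at most one spot per kymograph and no drift
  correction; boundary censoring slightly undercounts long-dwell blinkers.
* The band score treats residual noise as iid across wavelengths; smooth
  baseline errors would inflate it.
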