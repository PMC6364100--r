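---
title: "Screening and surrogate-standard quantification of Dendrobium phenols: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and surrogate-standard quantification of Dendrobium phenols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolscreen)
```

## The analytical problem

Twelve phenols determine the quality of *Dendrobium chrysotoxum*: seven
bibenzyls, two phenanthrenes, two flavones and coumarin. Reference
standards exist for only nine; moscatilin, chrysotoxin and
3,4-dihydroxy-4′,5-dimethoxybibenzyl must be recognised from full-scan
spectra and quantified against a family surrogate standard. The
instrument is a miniature single quadrupole coupled to UPLC: unit mass
resolution, alternating positive and negative full scans over 50–400 Da,
and SIM channels for quantification. This package implements the whole
chain — simulation of such runs with known truth, chromatographic signal
processing, adduct-fingerprint screening, calibration and surrogate
quantification, spike-recovery validation, and reporting.

## The instrument model (synthetic data)

`ms_scenario()` + `simulate_run()` generate one injection:

- **Elution**: each compound is a Gaussian centred at its library
  retention time with width `peak_sigma` (default σ = 0.05 min). No
  gradient model: retention times are library constants.
- **Response**: the integrated SIM area equals
  `response_factor × extract concentration` (µg/mL), with
  `extract concentration = content × recovery × sample_mass /
  elution_volume`. The sample-preparation constants default to the
  method's 0.5 g of dried powder eluted into 10 mL, so 1 µg/mL ↔ 20
  mg/kg. An optional per-compound intercept models matrix background in
  calibration series; sample runs use the pure proportional response.
- **Spectra**: ion intensities are spread over integer-centred 1-Da bins
  according to each compound's adduct fingerprint; all adduct arithmetic
  is nominal ([M+H]⁺ = M+1, [M+Na]⁺ = M+23, [M−H]⁻ = M−1). No isotope
  patterns.
- **Acquisition**: one positive and one negative full scan per cycle at
  the same nominal retention time, cycle period 0.05 min; SIM traces
  restricted to each channel's time window. Compounds sharing a channel
  (gigantol and its dimethoxybibenzyl isomer at m/z 297; erianin and
  chrysotoxin at m/z 341) land in the same trace as separate peaks, as
  on the instrument.
- **Noise**: i.i.d. Gaussian, mean 0, SD `noise_level`, clipped at zero
  — the simplest model consistent with a baseline-noise-based LOD. The
  clipping makes near-zero baselines slightly sub-Gaussian; noise
  windows used for LOD estimation in practice sit on small positive
  baselines where the effect is negligible.
- **Reproducibility**: every stochastic operation takes an explicit
  seed.

What the simulator deliberately does *not* emulate: retention-time
drift, peak tailing, detector saturation, ion suppression, isotope
envelopes, or correlated (drifting) baselines. Tests passing on
simulated data therefore demonstrate the correctness of the *algorithms*
under the stated model, not instrument-proof robustness; the
spike-recovery machinery quantifies accuracy only within this model.

## Signal processing

Chromatograms are tibbles (`rt`, `intensity`). Peak detection
(`detect_peaks()`) works on a centred moving average. The window is 3
points: at the default sampling (cycle period = σ = 0.05 min) a wider
window spans ±2σ and can erase a small peak eluting 0.28 min from a
much larger one on a shared SIM channel — precisely the chrysotoxin /
erianin configuration — by smoothing away the valley between them.
Noise for the S/N filter is estimated as `mad(diff(y))/√2`, which is
insensitive to the peaks themselves and to any constant offset, making
peak lists invariant under baseline shifts.

Boundaries walk out from each apex until the smoothed,
baseline-subtracted trace falls to 0.1% of the apex height, capped at
the flanking local minima. The threshold is 0.1% rather than a more
common 1% because the integration baseline is anchored at the boundary
intensities: anchoring at 1%-height points biases a Gaussian's
trapezoidal area by ≈2.7%, while 0.1% keeps the total systematic error
near 0.3%, inside the 1% budget the package's own linearity tests
impose. The base level for the walk is the *lower* of the two flanking
minima: a valley shared with a larger neighbour is elevated, and using
it would cut the walk short under the neighbour's flank.

Partially co-eluting peaks joined at a valley are treated as a cluster:
one linear baseline across the cluster's outer edges, peaks split at the
valley (drop-line). Full deconvolution of co-eluting peaks is out of
scope; the residual cost is a ≈1.4% low bias and the widest Monte-Carlo
spread for chrysotoxin, which both shares erianin's m/z 341 channel and
is ~17× smaller in the packaged scenario.

`integrate_peak()` is the plain trapezoid of intensity minus the linear
baseline between the boundary intensities, clipped at zero.
`estimate_baseline_noise()` is the SD of raw intensities in a peak-free
window of at least 20 points — the "baseline noise" of the 3×/10×
LOD/LOQ convention. Whether an instrument's software uses SD or
peak-to-peak noise is often unstated; SD is chosen here for
testability (its sampling distribution is known).

## Screening: fingerprints, families, identification

`average_spectrum()` averages the full-scan bins across a peak and
subtracts the mean of a few flanking blank cycles (clipping negatives).
`build_fingerprint()` takes the most intense positive bin as the base
peak — or the most intense negative bin if the positive spectrum is
empty — and keeps ions of the base polarity at ≥10% relative abundance.

`classify_family()` encodes how each family ionises:

1. **Bibenzyl** — a positive pair 22 Da apart ([M+Na]⁺/[M+H]⁺). With the
   sodium adduct as base, the protonated ion must confirm within
   20–80% relative abundance (the standards span 35–52%); with the
   protonated ion as base — chrysotoxin's printed pattern — the sodium
   adduct must be present at ≥20%. MW = lower ion − 1. Negative-mode
   signal is not required (chrysotobibenzyl, which lacks a hydroxyl,
   shows none).
2. **Flavone** — negative signal strictly stronger than positive;
   MW = negative base + 1.
3. **Positive-only**: two ions with a 28 or 32 Da neutral-loss spacing →
   phenanthrene; a single ion → coumarin-like. MW = base − 1. Whether a
   single-ion positive spectrum can be distinguished from a
   phenanthrene lacking its neutral-loss ion is genuinely open; such
   peaks are labelled coumarin-like.

Classification uses only relative abundances and polarity comparisons,
so it is scale-invariant. `identify_compound()` matches peaks against
the nine standards (RT within 0.1 min *and* base ion within 0.5 Da —
unit resolution); non-matching classified peaks become
`newly_elucidated` with the family surrogate (bibenzyls: erianin, or
gigantol when the inferred MW is gigantol's 274 — the nearest-mass
family standard; flavones: naringenin; phenanthrenes: moscatin) and a
SIM ion. For bibenzyls the SIM ion is the sodium adduct (MW + 23) even
when it is not the base peak, because the sodium adduct is the family's
selective, sensitive channel; chrysotoxin is the case where this
matters. Naming a new compound (literature search) is outside
computational scope: identifications carry family + MW and a
user-assignable name.

A note on the library's retention times: the three standard-less
compounds elute at 5.62 (moscatilin), 6.84 (chrysotoxin) and 6.97 min
(the dimethoxybibenzyl). This assignment is the only one consistent
with identification: the dimethoxybibenzyl is gigantol's isomer with an
identical nominal fingerprint, so it can be told apart from gigantol
(5.59 min) only by retention time.

## Calibration, LOD/LOQ, quantification

`fit_calibration()` is unweighted ordinary least squares of area on
concentration — the plain line the method uses; weighted or robust
variants are deliberately not offered. The fitted range is kept as the
linear range; a non-positive slope is flagged degenerate rather than
inverted. `estimate_lod_loq()` converts the slope to predicted peak
height via the Gaussian shape factor (`height/area = 1/(σ√2π)`,
`height_per_area()`) and solves `a·x·h/a.u. = 3×noise` (LOD) and
`10×noise` (LOQ). The intercept is excluded from the signal — LOD
concerns analyte response above baseline — so LOQ/LOD = 10/3 exactly,
and zero noise degenerates to 0/0 with a warning.

`quantify()` inverts the line, clips at zero, flags concentrations below
LOQ (content reported missing), and converts to mg/kg. A newly
elucidated compound is assumed to share its surrogate's response
factor; this is the method's central accuracy caveat, exact in
simulation (where it is true by construction) and an uncontrolled bias
on real extracts.

## Validation and reporting

`simulate_spiked_batch()` + `validate_batch()` implement the
fortified-sample design: five replicates at 50 and 200 mg/kg with paired
blanks, full pipeline on every run, endogenous content as the blank
mean with below-LOQ blanks counted as zero (compounds absent from the
sample still validate), recovery = 100·(mean spiked − endogenous)/added
and RSD with the sample (n−1) SD.

`content_table()` reports samples × compounds with an `Average` row that
means over the non-missing samples only and is missing when a compound
was found nowhere. Display (`display_round()`) truncates toward zero at
3 significant digits, dropping a trailing ".0" — the unique simple rule
consistent with the reported tables (425.5→425, 20.875→20.8,
13.65→13.6, 9.7475→9.74); whether those tables were truncated or copied
from instrument software is unknowable, and one reported cell (246.5)
is not truncated at all. Internal values keep full precision; a 1e-12
relative guard absorbs binary representation shortfalls (10.6 stored as
10.5999…). Missing cells render as "—" and export as empty CSV cells.

## Problem sizes and numerical choices

The packaged demo scenario uses the four reported samples, response
factors equal to the reference calibration slopes (surrogate's slope for
the three standard-less compounds), unit recovery, σ = 0.05 min, cycle
period 0.05 min and baseline noise of 20 counts; its calibration series
is six levels (2–100 µg/mL) in triplicate, integrated through the same
peak pipeline as the samples so small systematic integration biases
cancel in inverse prediction. Monte-Carlo checks use 100 seeds for
content recovery (SIM-only runs; full scans are generated only where
screening is exercised) and 5-replicate batches for recovery/RSD —
sizes chosen to keep the whole suite fast while leaving sampling error
well below the tolerances tested.

Degenerate inputs are handled explicitly: empty windows, flat traces,
all-equal areas, zero noise, missing blanks, and unknown compounds all
raise typed errors or flagged results rather than propagating NaNs.

## Known limitations

- Everything rests on the Gaussian-peak, additive-noise instrument
  model; real matrix effects, drift and tailing are out of scope.
- Surrogate quantification is exactly as accurate as the equal-response
  assumption.
- Unit-resolution fingerprints cannot separate isomers (gigantol vs its
  dimethoxybibenzyl isomer) except chromatographically.
- Co-eluting peaks are split at the valley, not deconvolved.
- The negative-mode relative abundances of bibenzyls are not reported
  with the fingerprints; the simulator uses a nominal 30% of the
  positive base (0 for chrysotobibenzyl), which only needs to be
  detectable, not accurate, for classification.
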