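---
title: "Methods: mass-photometry quantification of AAV capsid subpopulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass-photometry quantification of AAV capsid subpopulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aavmp)
```

## The measurement model

Mass photometry detects single particles landing on a coverslip through the
interference between reflected and scattered light. Each binding event
yields a ratiometric contrast whose magnitude is, to good approximation,
proportional to the particle's molar mass. The analysis chain in this
package rests on three assumptions:

1. **Linearity**: contrast and mass are related by a straight line
   `mass = slope × contrast + intercept` over the working range
   (~0.5–6 MDa). Calibration standards fix the line; no quadratic term is
   modelled.
2. **Independent landings**: binding events arrive as a Poisson process
   whose rate is proportional to particle concentration, so the binding
   count rate carries (rough) concentration information.
3. **Gaussian peaks**: each capsid subpopulation produces an approximately
   Gaussian mass peak, broadened by instrument noise and population
   heterogeneity.

An AAV capsid is a 60-subunit shell of VP1, VP2 and VP3 at ~1:1:10
stoichiometry packaging up to 4.7 kb of single-stranded DNA. The default
`capsid_model()` uses VP masses 82/66/60 kDa at 5:5:50 so that the empty
shell is exactly 3740 kDa — the mass of the commercial "empty" AAV9
calibration standard — since individual VP masses are not independently
anchored. Payload mass is `payload_length × mass_per_nt`, with
`mass_per_nt = 330` Da/nt, the standard ssDNA approximation. The default
genome length of 3800 nt (payload 1254 kDa, full capsid ~4994 kDa) is a
typical single-stranded therapeutic construct; all of these are arguments,
not constants.

## Calibration

`fit_calibration()` supports the three point sets in practical use: two
physical standards (thyroglobulin 670 kDa + empty AAV9 3740 kDa), the zero
point + AAV9e, and all three. The fit is unweighted ordinary least squares
of mass on contrast, with the zero point (mass 0, contrast 0) entering as
an ordinary datum. Two-point fits interpolate exactly and report R² = 1 by
the exact-interpolation convention; the three-point fit genuinely measures
collinearity and reports R² < 1 whenever the middle point is off the chord.
The calibrant contrast is summarized by the **median** of the pooled
binding-event contrasts (mean available), after merging the standard's
start-of-run and end-of-run movies: merging pools is preferred over
averaging two fits because it weights each recorded event equally and is
associative. A minimum of 100 calibrant events is enforced. One source
prints the AAV9e standard as 3.74 MDa and another as 3.75 MDa; the package
uses 3740 kDa throughout.

Negative calibrated masses (possible below a nonzero intercept) are kept,
not clipped, so miscalibration remains visible downstream.

## Histograms, gates, components

Calibrated masses are binned into uniform histograms of **40 kDa** — the
conventional analysis bin width, interpreted here in kDa since the
histograms are mass histograms — with half-open bins `[lo, hi)`. Gates
separating empty / partially filled / full / overfull windows are placed
from single-Gaussian fits of a mostly-empty (meC) and a mostly-full (mfC)
reference: `b1 = μ_e + kσ_e`, `b2 = μ_f − kσ_f`, `b3 = μ_f + kσ_f`,
`lower_cutoff = μ_e − kσ_e`, default `k = 3` (no numeric limits are
published; k is configurable and recorded in every gate object). If the
references are too wide to leave a partial window, `b2` falls back to the
midpoint of the two means, pulling `b1` in with it if needed.

Within each window holding ≥ 50 events, a single Gaussian is fitted to the
bin counts by Levenberg–Marquardt nonlinear least squares, initialised at
the window's count-weighted centroid and SD and bounded inside the window;
windows below threshold simply report no component. Degenerate windows
(fewer than three occupied bins) fall back to the centroid summary. A
whole-axis variable-variance Gaussian mixture fitted by EM over the raw
masses (`fit_mixture_em()`) serves as a cross-check; on well-separated data
the two routes agree within a bin width.

**Percentages are event counts per window** divided by the events at or
above the lower cutoff — robust to fit failures — with Gaussian-area
percentages as an option that requires all four components. Sub-cutoff
events (crude-extract debris) are excluded from the denominator and
reported as a background fraction. Empty and full capsid masses are the
fitted peak means; the partial and overfull classes rarely resolve a peak
and are reported as window medians. The payload (transgene) mass is
`full − empty`, reported as absent (`NA`) when either peak is missing.
Replicate statistics use the n−1 SD and RSD = 100·SD/mean.

## Titer

The landing factor κ (events·s⁻¹ per cp·mL⁻¹) is geometry- and
instrument-specific, so no universal constant is shipped: it must be
calibrated per run from a standard of known concentration
(`calibrate_kappa()`), and `estimate_titer()` then inverts
`titer = rate/κ × dilution`, attaching an exact (Garwood) Poisson 95 %
interval on the event count. The estimator is transparent by design — the
vendor's own titer algorithm is undisclosed — and deliberately labelled
rough: between-movie count-rate fluctuation is the dominant error, and a κ
calibrated in one focus mode applied to another (e.g. the unmixed automated
buffer-dilution mode) biases the estimate upward by the mode's count-rate
inflation. Mass- or serotype-dependent landing efficiency is not modelled.

## The synthetic-data generator

Because no raw instrument data are deposited anywhere, every stage is
driven by `simulate_sample()`. One movie is generated as:

* binding count `n ~ Poisson(κ·C·T·m)` with `κ = 1e-9` ev·s⁻¹ per
  cp·mL⁻¹ (chosen so the standard operating point of 1e11 cp/mL over a
  60 s movie yields ~6000 events), concentration `C`, duration `T = 60` s
  and mode multiplier `m`;
* the unmixed automated buffer-dilution mode uses `m = 1.6` with doubled
  count dispersion (negative-binomial), emulating the robot dispensing
  sample under the buffer without mixing — only "higher counts and
  variance" is documented for the instrument, so these values are explicit
  synthetic choices, configurable and flagged as such;
* each event draws a class from the mixture proportions (or background),
  a mass `N(class mean, 70 kDa)`, and a contrast by inverting the
  generating line (slope 2e4 kDa per contrast unit, intercept 0) plus
  `N(0, 2e-3)` contrast noise (~40 kDa mass-equivalent); the combined
  ~80 kDa peak SD is a realistic width for purified AAV on a mass
  photometer;
* partially filled capsids draw a uniform fill fraction on [0.2, 0.8] of
  one payload mass (overfull capsids carry 1.3 payloads) — these classes
  are described only qualitatively, so the ranges are explicit synthetic
  choices;
* crude-extract background mass is Gamma(shape 4, scale 150) kDa (mean
  600 kDa, well below any intact capsid), at 15–20 % of events in harvest
  presets;
* unbinding events are a 10 % binomial fraction of bindings and are
  excluded from all mass and rate analysis;
* replicate `i` re-seeds the generator at `seed + i`, so a single run seed
  expands deterministically.

The generator emulates landing statistics, mixture composition and linear
contrast formation; it does **not** emulate focal drift, surface
saturation, coincident landings, mass-dependent landing efficiency or any
optics beyond the linear law. Passing tests therefore demonstrate that the
analysis chain recovers known inputs under the stated statistical model,
not that it is robust to every instrument artefact.

### A boundary effect worth knowing about

With the default geometry, the top of the uniform partial-fill range
(shell + 0.8 × payload ≈ 4743 kDa) lies within one peak-SD of the full
window's lower gate (`μ_f − 3σ ≈ 4746` kDa). Gate counting therefore
shifts a few percent of partial events into the full (and empty) windows.
For a reference-like sample with ~6 % partials the effect is a fraction of
a percentage point; for partial-rich harvest material it can reach about a
point and a half on the full-class percentage. This is a faithful property
of hard gating on overlapping populations — orthogonal methods disagree on
exactly such samples — and the test suite checks the classifier against a
window-probability integration oracle that accounts for it exactly.

## Numerical choices and problem sizes

Fits are bounded L-M least squares (200 iterations); EM uses standard BIC
machinery with the component count given. Event CSVs serialize doubles as
`%.17g` and are parsed by `strtod`, making write/read round trips
bit-identical. Ties on bin edges go to the upper bin everywhere.

The shipped tests and the acceptance script use the study's native scales:
5000-event composition runs, five-replicate sets of ~3000–10000 events,
100–200-seed loops for the distributional laws (Poisson count mean,
multinomial class frequencies, slope/κ recovery), and 50-seed-per-point
titer linearity over the four tested concentrations (4.3, 2, 1.5,
1 × 10¹¹ cp/mL). These sizes give the 3-standard-error test bands a few
percent of headroom while keeping a full run in minutes on one CPU.

## Known limitations

* Composition percentages inherit the hard-gating bias described above;
  Gaussian-area percentages mitigate but require all four peaks to fit.
* The titer estimator propagates only Poisson counting error; κ transfer
  across focus modes or serotypes is the user's responsibility.
* The harvest "mix B" and AAV8-extract preset compositions are
  illustrative (only the mix-A filled fraction and the roughly threefold
  mix-B increase are anchored numbers), as are the meC/mfC reference
  compositions.
* No vendor file formats are parsed; events enter as plain CSV.
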