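---
title: "Temporal resolution of visually evoked fields: models and methods"
author: "opmvef"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal resolution of visually evoked fields: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmvef)
```

## The problem

A visual stimulus evokes a sequence of magnetic field pulses over the
occipital cortex — an early component (P1), a main component (P2 for flash
stimulation, P100 for pattern reversal) and a late component (P3). Their
peak latencies, and the latency differences between the primary (Oz) and
associative (POz) visual cortex, carry the physiology: feed-forward and
feedback interaction between V1 and V2. How precisely those latencies can
be read off a trial-averaged trace is a property of the *measurement
system*, not only of the brain. Wearable optically-pumped magnetometers
(OPMs) sit ~5 mm from the scalp; cryogenic SQUID sensors sit ~50 mm away
in a fixed dewar. Closer sensors see larger fields, and larger pulses of
similar width and noise pin their peaks down more tightly.

`opmvef` implements that argument as a tested pipeline: from raw
stimulus-locked magnetometer traces to component latencies, a
temporal-resolution figure of merit, inter-site delays with uncertainties,
and reproducibility statistics — together with a synthetic-data generator
that stands in for participant recordings, which for this kind of study
are typically not shareable.

## The temporal-resolution model

Trial averaging attaches a standard error $\varepsilon(t)$ to the mean
trace $m(t)$ at every time point. A natural resolution measure is the time
that must pass after a peak before the signal differs *significantly* —
by $\varepsilon$ — from the peak value. For a Gaussian pulse
$g(t) = A e^{-(t-t_0)^2/2\sigma^2}$ with constant $\varepsilon$ this has
the closed form

$$t_\mathrm{res} = \sigma\sqrt{-2\ln\!\left(1 - \varepsilon/A\right)},$$

implemented in `t_res_exact()`, valid only while $\varepsilon/A < 1$
(signal-to-noise ratio $\mathrm{SnR} = A/\varepsilon > 1$; the functions
refuse the domain outside it). Its first-order expansion
$t_\mathrm{res} = \sigma\sqrt{2\varepsilon/A}$ (`t_res_taylor()`) shows the
scaling $t_\mathrm{res} \propto w/\sqrt{\mathrm{SnR}}$ that carries over to
non-Gaussian pulses of width $w$, and is always a lower bound on the exact
expression.

Real evoked fields superpose several components, and functional fits are
often unreliable, so pulses are characterized non-parametrically
(`characterize_pulse()`): the width $w$ is the time between the two local
minima adjacent to the peak, and the amplitude $A$ is the difference
between the peak value and the mean of those two minima. Holding
$\varepsilon$ and $w$ fixed, resolution improves with $\sqrt{A}$, which
motivates the figure of merit

$$\eta = \sqrt{A}/w \qquad [\sqrt{\mathrm{fT}}/\mathrm{ms}],$$

larger being better. Its uncertainty is first-order propagation,
$\delta\eta = \eta\sqrt{(\delta A/2A)^2 + (\delta w/w)^2}$, with
$\delta A = \varepsilon(t_\mathrm{peak})$ and $\delta w$ the quadrature sum
of the band-crossing spans at the two bracketing minima.

The *empirical* counterpart of $t_\mathrm{res}$ is `temporal_uncertainty()`:
the span around the peak over which the mean trace stays within
$\varepsilon(t_\mathrm{peak})$ of the peak value, located by sub-sample
linear interpolation of the first crossings on each side. For a sampled
Gaussian with constant $\varepsilon$ it closes on $2\,t_\mathrm{res}$
within one sample (this is asserted in the test suite). The *full*
two-sided span is reported; a one-sided half-width convention would be
equally defensible, so the choice is stated here once and used
consistently — delay uncertainties divide it by two before combining
sites.

## Pipeline stages and their parameters

| stage | default | why |
|---|---|---|
| band-pass | 5–60 Hz, Butterworth order 4 | evoked-field band |
| band-stop | 49–51 Hz, order 4 | mains suppression |
| realization | forward–backward (`filtfilt`) | zero phase: causal filters bias latency, the pipeline's product |
| epochs | −45…350 ms (flash), 0…250 ms (pattern reversal) | component windows plus pre-stimulus context |
| guard band | 1 s at both record ends | keeps filter edge transients out of epochs |
| rejection | non-finite, flatline ≥ 50 ms, \|x\| > 10 pT | operationalizes "interrupted recordings" |
| averaging | mean ± per-timepoint SE | `average_evoked()`; optional pre-stimulus baseline subtraction, off by default |
| component windows | P1 35–60, P2 83–152, P3 160–230 ms | clinical literature ranges |
| delay sign | $\Delta\tau = t_\mathrm{peak}(\mathrm{Oz}) - t_\mathrm{peak}(\mathrm{POz})$ | positive = POz (V2) leads |

Filtering is applied to the continuous recording, not to epochs, so
transients ring out inside the guard band. Within each component window
`find_component_peaks()` characterizes *every* local extremum and selects
the largest characterized amplitude $A$ (ties to the earlier peak):
dominance by $A$ rather than by raw trace value keeps baseline offsets from
deciding the winner. Windows constrain only the peak time; bracketing
minima may lie outside them. Components with no in-window extremum are
reported absent, never fabricated.

For dual-axis OPM data the planar magnitude
$|B_{yz}| = \sqrt{B_y^2 + B_z^2}$ (`planar_magnitude()`) separates changes
of field magnitude from rotations of the field vector, which a single
measured component confounds; magnitude traces are non-negative, so their
characterization skips the negative-polarity branch.

Run-to-run and between-participant consistency use the Pearson correlation
of averaged traces (`pearson_r()`, `correlation_table()`). Within mode
reports the mean of all run-pair correlations with the standard error of
that mean; between mode first averages a participant's runs, then
correlates participants, reporting 95% confidence half-widths from the
Fisher z-transform. Both uncertainty kinds are always computed and
tagged, since the two table conventions differ. The compared time range
defaults to the full common epoch and is configurable.

## What the synthetic generator emulates

The generator exists so that every downstream stage is testable against
known ground truth. Its defaults describe one plausible flash-stimulation
session:

* **Schedules.** Flash: 0.08 s flashes, dark periods drawn uniformly over
  whole 60 Hz projector frames within 0.92–1.00 s, 300 s runs (≈ 280–295
  onsets). Pattern reversal: 0.5 s reversal interval, 280 s runs. The
  frame grid is respected exactly; only frame counts whose duration lies
  inside the stated interval are drawn.
* **Components.** Gaussian pulses with alternating polarity — P1 (+150 fT
  at Oz, $t_0$ = 50 ms, $\sigma$ = 8 ms), P2 (−480 fT, 120 ms, 15 ms), P3
  (+300 fT, 190 ms, 15 ms) on the radial axis, smaller tangential and POz
  amplitudes — so that adjacent-minima characterization is exercised on a
  bipolar trace. The main-component amplitude sits at the few-hundred-fT
  scale of on-scalp recordings. POz leads Oz by 10 ms (P2) and 20 ms (P3)
  by default; these are simulator defaults of the right order of
  magnitude, not ground truth about any participant.
* **Trial jitter.** Component latencies jitter trial-to-trial with
  $\sigma$ = 5 ms, shared across sensors within a trial (physiological,
  not instrumental).
* **Sensors.** OPM: 5 mm stand-off, two axes, 1 kHz, 15 fT/√Hz white
  noise (a typical specified sensitivity). SQUID: 50 mm, radial axis,
  2 kHz, 5 fT/√Hz (a typical axial-gradiometer figure). Noise is white
  Gaussian with RMS $\rho\sqrt{f_s/2}$ over the full Nyquist bandwidth,
  plus a 50 Hz sinusoid (20 fT default) with random phase per channel. An
  optional $1 + f_\mathrm{knee}/f$ excess-noise knee exists and is off by
  default.
* **Stand-off scaling.** Amplitudes are defined at the 5 mm reference and
  scaled by $(5/\mathrm{standoff})^p$ with $p = 2$, a current-dipole
  far-field heuristic. The OPM/SQUID amplitude ratio under the defaults
  (×100) is therefore a geometric statement about this scaling law, not a
  claim about measured gradiometer responses.

Equally important is what the generator does **not** emulate: no
anatomical head model or cortical folding, no volume currents or
multi-dipole forward solution, no SQUID gradiometer physics beyond the
scalar stand-off scaling, no heartbeat, eye-movement or motion artifacts,
and — deliberately — no run-to-run variability of the underlying evoked
morphology. Simulated runs of one configuration differ only by noise and
jitter, so within-participant correlations come out near 1, well above
the ~0.6–0.85 seen between real runs; passing reproducibility tests shows
the statistics are computed correctly, not that real data would be that
reproducible. Likewise, delay-recovery accuracy on simulated runs bounds
estimator error under the model's assumptions only.

## Numerical choices

* Local minima on the discrete grid are strict first-difference sign
  changes; plateaus count once, at their midpoint; when two candidate
  minima tie, the one nearest the peak wins (it is the nearest strict
  minimum by construction). If a side has no minimum, the epoch edge is
  used and the feature flagged `edge_truncated`.
* Negative-going pulses are sign-flipped before the minima search and
  the polarity recorded.
* Band crossings are linearly interpolated between samples, so spans are
  not quantized to the grid.
* Simulated pulses carry ±9σ of support, keeping the noiseless
  epoch-average round trip exact to below 1e-9 fT.
* Onsets map to the nearest sample; epoch grids are stored in ms with 0
  at the onset sample.
* An optional 3-sample running-median guard before extrema detection
  exists for very noisy traces; it is off by default and off in every
  test.
* The 5 Hz high-pass edge, applied zero-phase, ripples each broad
  component into its neighbours: even noiseless filtered peak latencies
  carry a deterministic bias of one–two samples (e.g. P2 121 ms vs the
  programmed 120 ms), and the test suite asserts recovery at that
  fidelity. Inter-site delays are differences of similarly biased
  latencies, so most of the bias cancels.

## Problem sizes used by the test suite

The suite's simulation studies are sized to be decisive yet quick: the
delay-recovery study runs 50 independent 300 s dual-site sessions with
P2/P3 site delays drawn from 5–30 ms around base latencies (Oz P2 125 ms,
P3 200 ms) chosen so every drawn POz latency stays strictly inside its
literature window; the modality comparison runs 20 seed-pairs of 120 s
sessions with matched quiet noise floors (1 fT/√Hz for both modalities) so
that the stand-off effect — not sensor noise — decides the outcome; the
error-propagation check uses 20 random configurations against
$10^5$-draw Monte-Carlo spreads, with relative input uncertainties up to
8% where first-order propagation is expected to hold to a few percent.

## Known limitations

* The adjacent-minima width is morphology-dependent: for the default
  bipolar trace, P2's bracketing "minima" are the P1 and P3 peaks of the
  flipped trace, so $w$ measures the inter-component span rather than an
  isolated pulse width. That is the intended behaviour of the definition,
  but it makes $\eta$ values comparable only between traces of similar
  morphology.
* At low SnR, noise wiggles can become the adjacent minima, shrinking $w$
  and $A$ together; $\eta$ remains finite but its interpretation degrades.
  The median guard mitigates this when explicitly enabled.
* The reconstruction of the third field component from spatial gradients
  (possible in source-free regions via Ampère's law) is out of scope: a
  two-sensor system provides no field gradients.
* No artifact correction (ICA/SSP), no head-movement compensation, no
  vendor MEG file formats, no source localisation or dipole fitting, and
  no cross-correlation latency methods — peak times only.
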