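# opmvef

Temporal-resolution analysis of visually evoked magnetic fields (VEFs)
recorded with on-scalp optically-pumped magnetometers (OPMs) or
conventional SQUID sensors.

A visual stimulus — a brief flash or a checkerboard reversal — evokes a
sequence of field pulses over the occipital cortex: the early P1, the main
P2/P100 and the late P3 component. Their peak latencies, and the latency
differences between the primary (Oz) and associative (POz) visual cortex,
are the physiological signal. This package is for neurophysiologists and
instrumentation scientists who want to quantify *how precisely* a given
MEG system can time those components, and to compare systems on that
footing.

## The model at the core

Trial averaging attaches a standard error ε(t) to the mean trace. For a
Gaussian pulse of amplitude *A* and width parameter σ under constant ε,
the time after the peak at which the signal has dropped significantly
(by ε) is

&nbsp;&nbsp;&nbsp;&nbsp;t_res = σ √(−2 ln(1 − ε/A)),  valid for SnR = A/ε > 1,

with the first-order form t_res = σ √(2 ε/A), i.e. t_res ∝ w / √SnR for
general pulses of width *w*. Because multi-component evoked fields resist
functional fits, pulses are characterized non-parametrically: *w* is the
time between the two local minima adjacent to the peak, *A* the difference
between the peak and the mean of those minima, and the figure of merit

&nbsp;&nbsp;&nbsp;&nbsp;η = √A / w  [√fT / ms]

summarizes temporal resolution (larger is better), with first-order
uncertainty propagation δη = η √((δA/2A)² + (δw/w)²). Closer sensors see
larger *A* at similar *w* and ε, hence higher η — the quantitative case
for on-scalp magnetometry. The package also estimates per-component
inter-site delays Δτ = t_peak(Oz) − t_peak(POz) with band-derived
uncertainties, dual-axis planar magnitudes |B_yz| = √(B_y² + B_z²), and
run/participant reproducibility via Pearson correlation.

A synthetic-data generator (stimulus schedules, Gaussian components,
sensor noise, 50 Hz line, stand-off power-law scaling) stands in for
participant recordings, so the full pipeline is testable end to end.

## Worked example

```r
library(opmvef)
cfg <- synthetic_config(seed = 1)          # 300 s flash session, Oz + POz OPMs
raw <- simulate_run(cfg)
raw
#> <raw_recording> 300000 samples x 4 channels at 1000 Hz (300 s), 287 trigger events
#>   channels: Oz_y, Oz_z, POz_y, POz_z

filt <- apply_filters(raw, filter_spec())  # zero-phase 5-60 Hz + 49-51 Hz stop
ep <- reject_trials(epoch(filt, window = c(-45, 350), guard = 1))
#> 3 onset(s) dropped: epoch window out of bounds
ep
#> <epoch_set> 284 trials x 396 samples x 4 channels, -45..350 ms at 1000 Hz
#>   rejected: 0 non-finite, 0 flatline, 0 amplitude

oz <- average_evoked(ep, "Oz_z")
find_component_peaks(oz)$P2
#> <pulse_feature> negative peak at 120 ms (minima 83 / 189 ms)
#>   w = 106 ms, A = 496.5 +/- 5.94 fT, dt = 4.96 ms, eta = 0.2102 +/- 0.0955 sqrt(fT)/ms

poz <- average_evoked(ep, "POz_z")
compute_delay(oz, poz, "P2")
#> <delay_estimate> P2: delta_tau = 9 +/- 3.73 ms (POz -> Oz, positive = POz leads)
compute_delay(oz, poz, "P3")
#> <delay_estimate> P3: delta_tau = 21 +/- 5.25 ms (POz -> Oz, positive = POz leads)
```

Reading the output: the main component is a negative deflection peaking
120 ms post-flash; its characterized amplitude (peak to mean of the
bracketing minima) is 496.5 fT with a 5.9 fT standard-error band, its
width 106 ms, giving η = 0.21 √fT/ms; the uncertainty band pins the peak
time to a 5.0 ms span. The simulator programmed POz to lead Oz by 10 ms
(P2) and 20 ms (P3); the pipeline recovers 9 ± 3.7 ms and 21 ± 5.3 ms.

`run_pipeline(pipeline_config(...), outdir)` does all of the above in one
call and writes evoked TSVs, `features.json`, `delays.json`, correlation
tables and a `summary.json` stamped with the config hash. A thin CLI with
`simulate / preprocess / resolve / delays / repro / run-all` subcommands
is installed at `system.file("cli/opmvef", package = "opmvef")`.

The methods vignette (`vignettes/evoked-field-timing.Rmd`) documents the
model, every default parameter, the generator's realism limits and the
numerical choices.

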