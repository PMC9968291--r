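# cytorelease

Quantification of cytosolic siRNA release events from live-cell confocal
imaging, in R.

## The problem

During lipid-mediated siRNA delivery, only a small number of endosomal
escape ("release") events deliver siRNA to the cytosol, where the RNAi
machinery acts. Each event appears in time-lapse confocal data as a sudden,
cell-wide jump of the labelled-siRNA fluorescence, followed by a gradual
signal decay as the dispersed siRNA redistributes into foci. Knowing *how
much* siRNA each event releases — in absolute concentration and molecule
counts — is what links delivery to knockdown, and lets one measure the
intracellular dose-response (IC50) of an siRNA sequence rather than the
extracellular dose applied to the dish.

`cytorelease` implements the full analysis chain for researchers working on
nucleic-acid delivery:

1. **Measurement** (`segment_and_track`, `mask_lipoplexes`,
   `measure_traces`): two z-plane stacks → per-cell background-corrected
   median-intensity traces. Bright intact lipoplexes are detected in either
   plane and excluded with a dilated margin, so out-of-focus particle light
   does not contaminate the cytosolic signal.
2. **Calibration** (`build_reference`, `to_concentration`, `to_molecules`):
   a 1 µM reference z-stack is FWHM-projected into a vignette-bearing
   per-pixel reference image; dividing a cell's corrected intensity by the
   reference value at the cell centroid corrects vignetting and converts to
   nM in one step. Molecule counts follow `N = C · V · N_A` (V = 5000 fL
   for a typical HeLa cytosol; 1 nM ≈ 3000 molecules).
3. **Event detection** (`detect_events`): after a 5-frame moving median,
   frame *t* is called when the value and the five following all exceed
   `max(mean₃ + 3·sd₁₀, mean₃ + offset)` over the preceding frames.
4. **Magnitude estimation** (`fit_release`): least-squares fits of
   exponential-decay, step, and double-event models over a 15-frame window,
   selected by AICc; `peak_conc` is the released concentration (for double
   events, the sum of both amplitudes), with per-event R² and a relative-SD
   uncertainty budget `sqrt(se²/A² + 0.08² + 0.05²)`.
5. **Dose-response** (`correct_expression`, `group_by_magnitude`,
   `fit_4pl`, `ic50_timecourse`, `fit_kinetic_model`): bleach-corrected,
   event-aligned reporter traces, release-magnitude quintiles, per-timepoint
   4PL IC50s, and an ODE knockdown model with bootstrap CIs.

A synthetic-data module (`gen_trace_ensemble`, `gen_image_sequence`,
`gen_knockdown_dataset`) generates traces, two-plane image scenes and
knockdown cohorts with full ground truth, so every stage is testable
end-to-end without any external data.

## Worked example

```r
library(cytorelease)

# 40 cells, 80 frames at 5 min, seeded release events of 1-40 nM
ens      <- gen_trace_ensemble(trace_spec(n_cells = 40, n_frames = 80,
                                          event_rate = 0.3, seed = 42))
events   <- detect_events_table(ens$traces)
releases <- fit_release_table(ens$traces, events)

first_truth <- ens$truth$events[!duplicated(ens$truth$events$track_id), ]
evaluate_detection(events, first_truth, 1:40)
#> detection: TP 33 FP 0 TN 7 FN 0 | sensitivity 1.000 specificity 1.000

head(releases[releases$converged,
              c("track_id", "event_frame", "model_kind", "peak_conc",
                "r_squared", "rel_sd", "molecules")], 5)
#>   track_id event_frame model_kind peak_conc r_squared     rel_sd molecules
#> 1        1          12     double 21.791867 0.9996661 0.09453718 65616.846
#> 2        1          21        exp 14.717071 0.9976106 0.09518231 44314.137
#> 3        1          48     double 11.865403 0.9966627 0.09603878 35727.563
#> 4        2          18        exp  2.599745 0.9702494 0.10461447  7828.015
#> 5        2          35        exp  5.537494 0.9932148 0.09672352 16673.785
```

Reading the output: every injected event was found (sensitivity 1.00 on
this clean synthetic well; on real data expect lower specificity and use
the manual-QC flags). The first cell received a double event totalling
21.8 nM — about 66,000 molecules in a 5000 fL cytosol — quantified with
R² > 0.999 and a ~9.5% relative SD, which is dominated by the systematic
calibration (8%) and bleaching (5%) error floor.

The same chain runs from the command line:

```sh
Rscript inst/cli/cytorelease simulate --seed 42 --out run/
Rscript inst/cli/cytorelease detect --traces run/traces.csv --out run/events.csv
Rscript inst/cli/cytorelease fit-release --traces run/traces.csv \
    --events run/events.csv --out run/releases.csv
```

## Documentation

The methods vignette (`vignettes/cytorelease-methods.Rmd`) describes the
models, the synthetic-data assumptions, numerical choices and known
limitations. Function-level documentation is in the roxygen comments in
`R/`.
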