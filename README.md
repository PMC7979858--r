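# phasekin

Pixel-level kinetics and lattice metrology of ligand-triggered solid–solid
phase transitions in molecular crystals, from two kinds of image data:

* **Polarized video microscopy (PVM).** A crystal between crossed
  polarizers transmits light according to its birefringence; when the
  lattice reorganizes, the transmitted intensity of every camera pixel
  drops. `phasekin` extracts per-pixel intensity traces
  \(I_i[(xy)_i, t]\), detects each transition as a Gaussian-fitted peak in
  the negated derivative \(-\partial I/\partial t\) (peak center = transition
  time, half-width at half-max = transition duration), classifies events
  into transitions T1/T2/T3 by k-means on (time, half-width), and
  quantifies *spatiotemporal synchrony* by block-averaging the region of
  interest into superpixels of 1–90 px and testing whether the mean
  transition times depend on the sampling area.
* **Atomic force microscopy (AFM).** Height images of the crystal surface
  resolve the molecular lattice. `phasekin` flattens scan lines, optionally
  denoises (FFT low-pass or correlation averaging), computes the 2D
  autocorrelation, and reads the in-plane unit-cell vectors from its most
  prominent peaks with sub-pixel quadratic refinement — including
  mixed-phase frames measured region by region, and the phase-labeled
  c-axis time series (apo cell AUC ≈ 9.3 nm → transition cells TUC1 ≈ 7.9 nm
  and TUC2 ≈ 12.4 nm) that tracks the transition in real time.

Because the original videos and topographs are not deposited, the package
ships a first-class synthetic-data module that emulates both: multiphasic
logistic intensity decays with ~50% total loss (sharp T1 centered at
227 s, per-pixel jitter sd 1.5 s) and Gaussian-motif lattice topographs on
oblique cells with tilt, roughness and mixed-phase regions. Every stage is
tested against this ground truth and against closed-form oracles.

Intended users: microscopists and crystallographers analyzing time-lapse
birefringence or scanning-probe data of phase-transforming crystals, and
anyone needing a tested reference implementation of derivative-peak
transition detection and autocorrelation lattice measurement.

## Worked example

```r
library(phasekin)

# simulate a small ROI with the default study conditions
g <- generate_video(video_params(height = 30, width = 30, n_frames = 1550,
                                 seed = 1))

# detect per-pixel transition events and classify them
det <- detect_pixel_transitions(g$video)
ct  <- classify_transitions(det, k = 3, seed = 1)
ct$summary
#>   label    n mean_time  sd_time mean_half_width coverage
#>      T1  900  226.9759 1.555499        14.16905        1
#>      T2 1037  354.8379 7.340466        25.37682        1
#>      T3  900  487.1022 1.826362        20.18776        1

synchrony_fraction(ct$events, "T1", 5)$fraction
#> [1] 0.8588889
```

The `T1` row says the first (sharp) transition is detected at 227.0 s —
the designed center — with a 1.56-s spread across pixels, and the
synchrony fraction says ~86% of this small 900-pixel sample completes it
inside a 5-s window (at the full 32,400-pixel study scale the fraction is
~90%): the transition is synchronous over the sampled area. The T2
cluster pools the two overlapping sub-transitions (T2a/T2b); its larger
spread reflects that overlap, not asynchrony. Half-widths are effective
durations under the analysis smoothing windows.

The AFM side in three lines:

```r
g <- generate_topograph(lattice_presets("AUC", roughness_sd = 0.05))
measure_unit_cell(autocorrelate(flatten_lines(g$topograph)), 2, 20)
#> <unit_cell_measurement> a = 4.79 nm, c = 9.32 nm, angle = 85.5 deg
```

which recovers the designed apo cell (a = 4.83 nm, c = 9.3 nm; the angle
is reported as the unsigned inter-vector angle, 180° − 94.5° = 85.5°).

## Analysis workflow

The `analysis/` directory holds the narrative drivers, in order:

1. `01_simulate_pvm.R` — simulate a pixel trace and a demo video; write
   ground truth and figures to `results/pvm_sim/`.
2. `02_analyze_pvm.R` — full PVM pipeline at the 180 × 180-px study scale
   (a few minutes); tables, plots and `pvm_summary.json` to `results/pvm/`.
3. `03_analyze_afm.R` — synthetic AFM series through AUC → TUC1 → (gap,
   mixed frame) → TUC2; per-image cells and the c-axis series to
   `results/afm/`.
4. `04_report.R` — collate the headline numbers into `results/report.md`.

Each script is a thin layer over the exported functions
(`run_pvm_pipeline()`, `run_afm_pipeline()`), which accept the same
configuration as YAML/JSON files via `read_run_config()`.

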