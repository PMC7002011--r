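# cortiquant

Quantification of light-induced plasma-membrane recruitment kinetics and
polarity-factor relocalization in fission-yeast time-lapse microscopy.

Optogenetic experiments that recruit proteins to the cell cortex (CRY2PHR–CIBN
dimerization) read out as small fluorescence changes confounded by camera
background and per-exposure photobleaching. The assay this package implements
images sample cells mixed with fluorophore-only control strains on the same
pad, measures the bleaching of each channel from the controls, and corrects
the sample traces before fitting recruitment kinetics:

- bleaching coefficient from control cells:
  `D(t) = mean_i MA5[ (F_i(t) − B(t)) / (F_i(0) − B(0)) ]`
- corrected signal `S(t) = (R(t) − B(t)) / D(t)`, net signal
  `N(t) = S(t) − S(0)`
- saturating-exponential fit `N(t) = a (1 − e^(−b t))`, half-time
  `t½ = ln 2 / b`
- tip time courses normalized to t0 (`S(t)/S(0)`), cumulative per-cell net
  signal for rank-based group tests, membrane profiles with peak ± 1
  averaging, kymographs, sum projections and cortical tip profiles

A synthetic generator (`generate_traces()`, `generate_timelapse()`) emulates
the full mixing design — 2:1:1 sample:RFP-control:GFP-control plus tag-free
cells and cell-free regions, pulsed acquisition cycles, first-order
recruitment, per-frame bleaching, background and noise — with known ground
truth, so every estimator is validated by parameter recovery.

## Worked example

```r
library(cortiquant)

d   <- generate_traces(scenario_preset("opto_50ms"))   # 30 frames at 0.5 s
res <- run_membrane_recruitment(d$traces)
res$summary
#>   n_cells n_converged n_failed t_half_median t_half_q25 t_half_q75 t_half_mean  t_half_sd
#> 1      30          30        0     0.8765264   0.831404  0.9357761   0.8787228 0.07823673
```

The preset simulates 30 optogenetic cells (plus 15 RFP controls, 15 GFP
controls, 5 tag-free cells, 5 cell-free regions) with a ground-truth
recruitment half-time of 0.85 s, 0.5 %/frame bleaching, background 100 and
5 % Gaussian noise. After background subtraction and bleaching correction,
the median single-cell half-time recovered by the fits is 0.877 s with an
interquartile range of roughly 0.10 s — the pipeline recovers the truth well
inside the experimental dispersion. `autoplot()` on any single fit shows the
net trace with its fitted curve; `tidy()`/`glance()` return the parameters.

The same chain runs from rendered images (`generate_timelapse()` →
`run_membrane_recruitment_stack()`), from CSV trace tables, or from
multi-page TIFF + ROI CSV via `read_stack_tiff()`/`read_roi_csv()`. A thin
command-line wrapper lives at `inst/cli/cortiquant.R`
(`simulate`, `run --config run.yaml`, `validate`).

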