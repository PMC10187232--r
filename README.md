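# spindlemetrics

Quantitative image analysis for mitotic-spindle biology. The package
implements, as tested R functions, the measurements used to phenotype
spindle and kinesin (e.g. KIF18A) perturbations in cultured human cells:

* **Chromosome alignment** — the kinetochore fluorescence profile along the
  pole-to-pole axis is normalized to its maximum and fitted with
  `A·exp(−(x−µ)²/(2σ²)) + c`; the reported metric is the full width at half
  maximum, `FWHM = 2√(2 ln 2)·σ` (µm). Tighter metaphase plates give
  smaller FWHM.
* **Spindle length and pole-axis angle** — Euclidean pole separation in µm,
  and the dot-product angle between the inter-pole vector and the focal
  plane (z converted with the z-step before any vector math).
* **Spindle rotation** — one pole is tracked through a time lapse; the
  polyline path length in µm per elapsed minute is reported.
* **Peripheral vs. spindle intensity** — ratio of the mean intensity in a
  band of stated physical width (built with a Euclidean distance transform)
  around an inner ROI to the mean inside it; a quartile line-scan variant
  divides the outer quarters of a 20 px-wide line by its middle half; and
  background-subtracted spindle/peripheral tubulin densities and
  control-normalized expression levels.
* **Single-molecule velocity** — kymographs from TIRF movies; runs are
  measured both by the manual bounding-rectangle rule
  `(width px × µm/px) / (height frames × s/frame)` and by a least-squares
  ridge fit.
* **Mitotic timing** — NEB→anaphase durations, with never-dividing cells
  called arrested only when ≥ 1 h of movie remained, otherwise censored;
  group comparisons via one-way ANOVA + Tukey or Kruskal–Wallis + Dunn.

A synthetic-microscopy generator (bipolar/monopolar spindles, rotating
spindle movies, kymographs) emits a ground-truth manifest with every
parameter used, so each measurement has recovery tests against known truth.

## Worked example

```r
library(spindlemetrics)

# simulate a metaphase cell with a 1.5 um kinetochore spread
m   <- bipolar_manifest(seed = 1, kinetochore_spread_sigma = 1.5)
sim <- simulate_bipolar_cell(m)

poles <- detect_poles(sim$image, "poles", expected = 2)
alignment_metric(sim$image, poles)
#>   fwhm_um spindle_length_um r_squared converged qc_pass
#> 1   3.369             10.01    0.9377      TRUE    TRUE
```

The fitted FWHM (3.37 µm; truth for σ = 1.5 µm is 2√(2 ln 2)·1.5 = 3.53 µm,
per-cell scatter reflects the finite kinetochore sample) and the spindle
length (10.01 µm vs. 10 µm simulated) come with fit QC. A kymograph run:

```r
kym <- simulate_kymograph(kymograph_manifest(
  1, data.frame(velocity = 0.05, run_length = 1.5,
                start_px = 15, start_frame = 20)))
detect_runs(kym$kymograph)
#>    width_px height_frames velocity_rect velocity_fit run_length_um duration_s
#> fr       10           181        0.0552       0.0499             1       18.1
```

The ridge fit recovers the simulated 0.05 µm/s; the rectangle rule is
coarser (one-pixel quantization). Timing rules:

```r
ev <- event_table(paste0("cell", 1:11),
                  neb_frame       = c(rep(10L, 10), 190L),
                  anaphase_frame  = c(rep(20L, 8), NA, NA, NA),
                  movie_end_frame = rep(200L, 11))
mitotic_timing(ev, frame_interval_min = 3)
#> TimingResult: 8 divided, 2 arrested, 1 censored
#>   median NEB->AO duration: 30.0 min
#>   arrest fraction: 20.0%
```

The methods vignette (`vignettes/spindlemetrics-methods.Rmd`) documents the
models, defaults, numerical choices and known limitations. A thin CLI over
the same functions lives at `inst/cli/spindlemetrics.R` (subcommands
`simulate`, `align`, `angle`, `rotation`, `ratio-band`, `ratio-linescan`,
`tubulin-density`, `expression`, `kymo`, `timing`), writing a JSON parameter
manifest alongside every output.

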