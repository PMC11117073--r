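# plusend

Quantification of actin filament plus-end dynamics from single-filament
TIRF microscopy data.

## What problem this solves

Actin assembly at the filament plus (barbed) end is set by a tug-of-war
between regulators: the formin mDia1 accelerates elongation (strongly so
with profilin), capping protein (CP) arrests it, formin–CP "decision
complexes" stall it, and scaffolds such as IQGAP1 transiently pause growth
and displace the other end binders. In vitro, all of this is measured from
a small set of tabular readouts: filament length over time, single-molecule
intensity traces, end-binding dwell records, and two-channel spot
positions. `plusend` is a tidyverse-native R package for biochemists and
image analysts who have those tables and need the downstream numbers:

* **Elongation rates** — per-filament OLS slope converted by actin's linear
  density, `rate = slope (µm/s) × 370 subunits/µm ÷ [actin] (µM)`, in
  subunits s⁻¹ µM⁻¹, including a growth-phase variant that excludes pauses.
* **Pause detection and statistics** — stalls of ≥ 3 consecutive frames
  (minimum resolvable pause: 15 s at 5-s framing), with Gaussian
  `A·exp(−½((x−x̄)/SD)²)` vs exponential-decay `(Y₀−Dmax)·exp(−kx)+Dmax`
  frequency-distribution fits compared by R².
* **Oligomeric state from step photobleaching** — visible bleaching steps
  follow Binomial(n, p) under partial labeling p (the expanded `(X+Y)ⁿ`),
  conditioned on visibility; a changepoint step counter plus chi-square
  model comparison infers n over monomer→tetramer.
* **Plus-end dwell/survival analysis** — Kaplan–Meier or empirical curves
  of the fraction of molecules still occupying ends, per species.
* **Single-molecule colocalization** — greedy one-to-one matching within a
  radius, with spatial-Poisson chance correction `1 − exp(−λπr²)`.
* **Cell-scale metrics** — intensity skewness (filament bundling),
  mask circularity `4πA/P²`, signal-per-pixel ratios, wound closure, and
  the lamellipodium molecule budget (`conc × N_A × volume` per species vs
  `500 filaments/µm² ×` footprint free ends).

A seeded synthetic-data generator (`sim_config()`,
`simulate_filaments()`, `simulate_bleach_traces()`, `simulate_dwells()`,
`simulate_spots()`, `simulate_bundle_field()`) produces every one of these
inputs with ground-truth labels, so the entire pipeline is testable by
parameter recovery without any imaging data.

## Worked example

Simulate a pausing condition (free ends at 10.2 subunits s⁻¹ µM⁻¹,
Gaussian pauses of mean 20.6 s entered at 0.004 s⁻¹), then recover the
kinetics:

```r
library(plusend)

cfg <- sim_config(length_noise_sd = 0.02,
                  transition_rates = c("free->iqgap1_paused" = 0.004))
sim <- simulate_filaments(cfg, n_filaments = 100, seed = 42)

elongation_rates(sim$tracks, actin_conc = 1) |> head(3)
#> # A tibble: 3 × 5
#>   filament_id  slope  rate n_points fit_r2
#>   <chr>        <dbl> <dbl>    <int>  <dbl>
#> 1 fil-0001    0.0273 10.1        14  0.999
#> 2 fil-0002    0.0269  9.96       12  0.998
#> 3 fil-0003    0.0242  8.96       87  0.995

detect_pauses(sim$tracks) |> head(3)
#> # A tibble: 3 × 6
#>   filament_id start   end duration n_frames truncated_by_movie_end
#> 1 fil-0003      200   225       25        5 FALSE
#> 2 fil-0003      460   480       20        4 FALSE
#> 3 fil-0003      515   530       15        3 FALSE

fit_gaussian(build_histogram(true_pauses(sim$events, 600)$duration))
#> <dist_fit: gaussian>
#>    A = 49.61, mean = 19.93, sd = 4.895
#>   r2 = 0.9974 on 122 events in 8 bins
```

The mean whole-track rate (9.4 here) sits below the free-end 10.2 because
paused frames are included — the signature of a pausing factor. Oligomer
inference from photobleaching runs the same way:

```r
b <- simulate_bleach_traces(2, p_label = 0.7, n_molecules = 300,
                            noise_sd = 0.15, seed = 42)
infer_oligomer(step_histogram(detect_steps(b$traces)), p_label = 0.7)
#> <oligomer_inference>
#>   n = 269 molecules, p_label = 0.70, distance = chisq
#>    n=1: 140.8, n=2: 0.004085, n=3: 0.7831, n=4: 3.051
#>   best_n = 2
```

and the back-of-envelope budget of plus-end regulators in an average
lamellipodium:

```r
molecule_budget(compartment_spec())
#> <molecule_budget>
#>   volume: 2e-15 L, available ends: 5000
#>   CP: 1204 molecules -> 1204 end-binding units
#>   mDia1: 120.4 molecules -> 60 end-binding units
#>   occupied: 1264, remaining free ends: 3736
```

Fitted objects have `tidy()`/`glance()` methods; result types have
`autoplot()`/`plot_*()` companions (`plot_tracks()`, `plot_survival()`,
`plot_spots()`). A thin command-line front end with `simulate`,
`kinetics`, `distfit`, `photobleach`, `occupancy`, `coloc`, and `budget`
subcommands ships in `inst/cli/plusend.R`.

## The methods vignette

`vignettes/plus-end-quantification.Rmd` documents the simulator's model
and calibration, every tunable parameter with units and defaults, the
numerical choices inside the fitters and detectors, and what passing
synthetic-data tests do and do not establish about real images.
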