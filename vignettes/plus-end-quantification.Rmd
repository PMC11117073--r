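---
title: "Quantifying actin plus-end regulation from single-filament TIRF data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying actin plus-end regulation from single-filament TIRF data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plusend)
library(dplyr)
```

## The measurement problem

The fast-growing (plus, or barbed) end of an actin filament is a crowded
place. Formins such as mDia1 ride the end and accelerate subunit addition —
roughly five-fold in the presence of profilin — while capping protein (CP)
blocks addition outright; when both bind at once they form a "decision
complex" that arrests growth until one of them leaves. Scaffolding proteins
such as IQGAP1 complicate the picture further: IQGAP1 transiently pauses
elongation and can displace other end binders, exchanging whoever currently
controls the end. In single-filament TIRF microscopy all of these behaviours
are read out from a handful of primitive measurements: filament length as a
function of time, single-molecule intensity traces, binding and release
times of labelled molecules at ends, and positions of spots in two spectral
channels.

`plusend` implements that measurement layer as composable, tested functions,
together with a seeded generator that synthesises every input with known
ground truth. The generator is not an afterthought: because the real
quantities of interest (rates, pause durations, oligomeric states, dwell
times, colocalized fractions) are parameters of the generator, every
estimator in the package can be validated by parameter recovery, and the
test suite does exactly that.

## The synthetic-data model

`sim_config()` + `simulate_filaments()` model each plus end as a
continuous-time jump process over six states (`free`, `formin`,
`formin_pfn1`, `cp_capped`, `decision_complex`, `iqgap1_paused`). Between
jumps the filament grows linearly at

$$v \;=\; \frac{k_{\text{state}} \cdot [\text{actin}]}{370}\ \ \mu\text{m/s},$$

where $k_{\text{state}}$ is the state's elongation rate in subunits
s$^{-1}$ µM$^{-1}$ and 370 is the number of subunits per micron of filament.
The default calibration uses the measured anchors for these conditions: 10.2
for free ends, 7.6 for formin alone, 52.4 for formin with profilin, and 0
for capped, paused, and decision-complex ends.

Design choices worth making explicit:

* **Pause durations are Gaussian, not exponential.** Measured
  IQGAP1-mediated pauses are well described by a normal distribution with
  mean 20.6 s and spread ~5 s, so visits to `iqgap1_paused` draw their
  duration from N(20.6, 5²) truncated at zero (negative draws are
  resampled; at these parameters the truncated mass is ~2 × 10⁻⁵, so the
  mean is unaffected). All other states exit by competing exponential
  clocks, which is the standard memoryless picture for single-step
  dissociation.
* **Events tile the filament's lifetime, not the whole movie.** A filament
  has no state before it nucleates, so its ground-truth ledger starts at
  its nucleation time and runs to the movie end. Nucleation times are drawn
  uniformly over the movie (stopping 4 frames short of the end so every
  track has at least the 4 samples the rate fit requires).
* **Localization noise** is additive Gaussian on each sampled length,
  default sd 0.05 µm — sub-pixel at the default 0.16 µm pixel size, a
  realistic figure for TIRF centroid localization. It is a free parameter
  because the stall-scoring tolerance of a by-hand analysis is not a
  published number.
* **Determinism.** Every simulator takes an explicit seed and uses the
  global RNG locally; the same (config, seed) pair reproduces output bit
  for bit, which the fixture writer exploits to emit byte-identical
  bundles.

The generator emulates tracks, bleaching traces, dwell records, spot
fields, and pixel-intensity fields. It does **not** emulate raw movies: no
PSF convolution, EMCCD/sCMOS noise, filament crossing or bundle occlusion,
drift, or background fluorophores. Tests passing on synthetic data
therefore validate the estimators given faithful tracking and spot
detection; they say nothing about segmentation quality on real images,
which is out of scope (tracks and spots are the input contract).

## Elongation rates and pauses

`elongation_rates()` fits an ordinary least-squares slope to length vs time
(at least 4 samples per filament, mirroring the at-least-four-time-points
scoring rule) and converts via `rate = slope × 370 / [actin]`. OLS rather
than a robust line matches what a hand-drawn slope over a handful of points
estimates.

`detect_pauses()` scores a frame-to-frame increment as *stalled* when
|Δlength| < `stall_epsilon` and turns every maximal run of ≥ `min_frames`
stalled increments into one pause. The defaults (ε = 0.1 µm, 3 frames at
5 s) give the canonical 15-s minimum resolvable pause
(`min_resolvable_pause()`). ε = 0.1 µm is about one pixel — far above the
0.02–0.05 µm localization noise, far below the 0.14 µm a free end grows in
one frame — and is reported in the output so it is never implicit. Two
stalled runs separated by even one growing increment are distinct pauses,
and runs touching the last frame are flagged `truncated_by_movie_end`
because their durations are right-censored; they are excluded from duration
fitting by default to avoid censoring bias.

Two rate flavours exist because the headline observation — the mean rate
dropping from 10.2 to ~7 subunits s⁻¹ µM⁻¹ when a pausing factor is present
— is a statement about *whole-track* fits that include paused frames. With
`exclude_pauses = TRUE` the function instead estimates the growth-phase
rate: frames interior to detected pauses are dropped **and the remaining
times are collapsed by the cumulative paused duration**. Dropping alone
would leave the pause's dead time in the x-axis and bias the slope low;
after collapsing, the growth-phase estimate recovers the configured state
rate to within ~1% on populations of 500 simulated filaments (the residual
bias comes from partial growth hidden inside edge increments of each
detected pause). A filament that is paused for its entire observed span has
no growth phase; its growth-phase rate is returned as `NA` rather than a
number.

```{r}
cfg <- sim_config(length_noise_sd = 0.02,
                  transition_rates = c("free->iqgap1_paused" = 0.004))
sim <- simulate_filaments(cfg, n_filaments = 60, seed = 1)
whole <- elongation_rates(sim$tracks)
growth <- elongation_rates(sim$tracks, exclude_pauses = TRUE)
c(whole = mean(whole$rate), growth = mean(growth$rate, na.rm = TRUE))
```

## Pause-duration distributions

`build_histogram()` bins durations into uniform bins from zero (default
width 5 s, one frame). `fit_gaussian()` and `fit_exp_decay()` fit

$$y = A\,e^{-\tfrac12\left(\frac{x-\bar x}{SD}\right)^2}
\qquad\text{and}\qquad
y = (Y_0 - D_{max})\,e^{-kx} + D_{max}$$

to the bin counts by Levenberg–Marquardt least squares, and
`select_model()` picks the higher-R² model, flagging exact ties. Pausing
conditions select the Gaussian; non-pausing conditions are monotone and
select the decay. Numerical choices:

* Starting values are deterministic and data-driven: weighted bin moments
  for (x̄, SD), the maximum frequency for A and Y₀, the tail mean for
  $D_{max}$, and a log-linear fit over the early bins for k.
* The fitted Gaussian mean is constrained to the observed duration support
  (it is, physically, a duration). Unconstrained, the optimiser can push
  the mean far below zero and blow up the amplitude so that the surviving
  tail mimics an exponential almost perfectly — a degenerate solution that
  would make the R² comparison meaningless.
* Fits operate on counts, not normalised frequencies; x̄, SD and k are
  invariant to that choice (only A and Y₀ rescale), which the tests assert.
* Whether histogram fits should use counts at all (versus unbinned maximum
  likelihood) is a fair question; R²-based comparison of binned fits is
  used because that is the established readout for this assay, and AIC/BIC
  style comparisons are deliberately out of scope.

On simulated pause durations the fitted mean converges to the configured
20.6 s (within 1 s from a few hundred events up) and R² lands in the
0.99–1.00 range once a couple of thousand events are pooled; at ~330 events
multinomial bin noise alone keeps R² nearer 0.97, which is worth knowing
before comparing against published R² ranges obtained with other pooling.

## Step photobleaching and oligomeric state

`labeling_efficiency()` implements the spectroscopic arithmetic (dye
absorbance over its extinction coefficient, protein absorbance corrected by
the dye's correction factor), clipping at 1. `predict_step_pmf()` expands
$(X+Y)^n$ — i.e. Binomial(n, p) — for candidate states n = 1…4, by default
conditioning on k ≥ 1 because unlabeled molecules are invisible and are
never scored; both conditional and unconditional forms are available since
published prediction plots do not always state which was used.

`detect_steps()` replaces by-hand scoring with binary-segmentation
changepoint detection: the trace is recursively split where the CUSUM gain
is maximal, splits are accepted while the mean shift exceeds a threshold,
and downward shifts of at least `min_step` count as bleaching steps. The
automatic threshold is 3× a robust noise sd, `1.4826 · median|Δy| / √2`,
making the detector deterministic and noise-adaptive. Its known failure
mode is honest: two fluorophores bleaching within ~1 sample of each other
merge into one double-height step (≈5% of dimer events at the default
bleach rate), which bounds per-trace accuracy around 93–96% at noise sd =
0.15 steps.

`infer_oligomer()` compares the observed 1/2/3/4+ step histogram with each
candidate's conditional pmf by Pearson chi-square distance on proportions
(total variation available). Expected proportions are floored at half an
observable count (0.5/n): a candidate that predicts a bin empty is then
penalised in proportion to the stray mass that lands there, instead of
being discarded because one of 300 traces was miscounted. Recovery of the
dimer state at p = 0.70 and n = 300 molecules succeeds in ~100% of seeded
replicates; at p = 0.55 the distance margin between candidates shrinks
markedly — the same reason a low-labeling construct cannot be called
conclusively.

## Dwell times, survival, colocalization

`simulate_dwells()` draws dwell times from Exponential(1/mean +
displacement hazard): baseline dissociation and displacement are competing
clocks, so adding a displacer shortens dwells and, most visibly, collapses
the sample maximum. Bind times are uniform over the movie and molecules
still bound at the end are right-censored.

`survival_curve()` plots the fraction still bound versus time since
binding. The default estimator is Kaplan–Meier (via the survival package):
whether movie-end-bound molecules were treated as events or censored in
published survival plots is unstated, so both modes are exposed, and KM is
the safe superset — it reduces *exactly* to the empirical curve when
nothing is censored, which the tests verify against a brute-force counter.

`colocalize()` matches reference-channel spots to the other channel by
greedy one-to-one nearest-neighbour assignment within a radius (default
0.4 µm ≈ 2.5 pixels, consistent with a 5-pixel particle-detection
footprint). Greedy matching with distance-then-index tie-breaking is
deterministic and at single-molecule densities differs negligibly from
optimal assignment. With the field extent known, the expected chance-match
probability per reference spot, $1 - e^{-\lambda_B \pi r^2}$, is
subtracted; this recovers configured mixture fractions within ~2 points at
the densities used (the subtraction form slightly under-corrects, by
$f \cdot c \le 2.5$ points, and sparse independent fields land in the
few-percent background regime).

## Image and geometry metrics

* `intensity_skewness()`: third standardised moment; bundles put a bright
  tail on the pixel-intensity distribution, so skewness rises with partial
  bundling and returns to ~0 when a field is uniformly singles *or*
  uniformly bundles.
* `circularity()`: 4πA/P² on a single-component binary mask. Perimeter
  comes from the traced boundary chain with a uniform corner-correction
  factor of 0.954, chosen so rasterized disks score 0.99–1.00 (radius
  20–200 px); per-step Vossepoel–Smeulders weights were tried and left
  disks at 0.925, failing the calibration. Raster rectangles consequently
  read ~0.03 above their continuous-geometry value — acceptable against
  the 0.13 circularity separation the metric needs to resolve.
* `wound_closure()`: the difference `t12 − t0` is primary (it is what
  "normalized closure" quantifies); the ratio form appears alongside
  because the verbal definition of the assay admits both readings.
* `molecule_budget()`: volume × concentration × N_A (6.02 × 10²³) per
  species, divided by oligomer size and floored (a fractional dimer does
  not occupy an end), against `filament_density ×` footprint ends. The
  default spec reproduces the worked numbers: ~1,200 CP molecules, <60
  mDia1 dimers, 5,000 ends in a 1 × 10 × 0.2 µm lamellipodium.

## Problem sizes and runtime

The test suite and `scripts/acceptance.R` size their simulations to the
statistics they check, not larger: 500 filaments for rate and recall
recovery (Monte-Carlo error on the mean rate ≈ 0.1%), ~1,000–2,000 pause
events for distribution fits, 300 molecules × 100 replicates for oligomer
recovery, 5,000 dwells for the survival median, six 80 × 80 µm fields for
colocalization. The full suite runs in a few minutes on one CPU.

## Limitations

The package analyses *tracks, traces, and point sets*; it does not segment
filaments, build kymographs from images, or detect particles in raw movies
(a validated reimplementation of any specific detection plugin is a
non-goal). Published in-vivo and in-vitro summary values quoted above are
calibration anchors for the simulator, not quantities this package can
recompute from raw data. Bulk pyrene assembly curves are outside the scope
entirely, as is significance-testing machinery beyond the descriptive
summaries returned by each function.
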