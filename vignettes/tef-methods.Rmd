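---
title: "Estimating the thermic effect of food from chamber calorimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the thermic effect of food from chamber calorimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teftools)
```

## The problem

Daily energy expenditure (EE) decomposes into three components: basal
metabolic rate, the energetic cost of physical activity, and the thermic
effect of food (TEF) — the postprandial rise in EE from digesting,
absorbing and storing a meal. In a whole-room indirect calorimeter EE is
observed at 1-min resolution, but the three components are entangled:
during the hours after a meal the subject also fidgets, shifts posture and
moves about, producing nonexercise activity thermogenesis (NEAT) that
contaminates any naive "postprandial minus baseline" calculation.

The reference measurement is the fed-minus-fasted difference, ΔEE: the same
subject completes two chamber stays, with and without the test meal, and
TEF is the accumulated EE difference over the analysis window. It is
costly — two sessions per estimate — which motivates single-session
approximations:

* **Intercept above RMR.** Regress minute EE on minute activity counts over
  the postprandial period; the intercept EE₀ extrapolates EE to zero
  activity. TEF = (EE₀ − RMR)·duration, with RMR the mean EE over a seated
  pre-breakfast window (07:15–07:45).
* **Intercept above SMR.** Same EE₀, but the baseline is the sleeping
  metabolic rate, the mean EE over 23:00–07:00.
* **NEAT removal** (`tef_original()`). Estimate NEAT explicitly from
  *integrated* activity, subtract it from the EE time course, and
  accumulate the NEAT-free EE above a NEAT-free preprandial baseline.

The package implements all four (`tef_delta_ee()`, `tef_schutz()` with
either baseline, `tef_original()`), a simulator with known latent
components, and Bland–Altman agreement analysis.

## The NEAT-removal model

Movement is not instantaneously reflected in EE: oxygen deficit at onset
and excess post-exercise oxygen consumption smear the energetic cost of a
movement over the following minutes. Minute EE therefore correlates better
with activity aggregated over a moving window than with instantaneous
counts. The method:

1. **Integrated activity.** For window half-width $w$ and lag $L$,
   $A_{w,L}(t)$ is the mean of counts over $[t+L-w,\, t+L+w]$, truncated at
   the series boundaries. The pair $(w, L)$ is chosen per analysis period
   by exhaustive grid search ($w \in 0..30$, $L \in -20..20$ min)
   maximizing the Pearson correlation with EE (`optimize_integration()`).
2. **NEAT model.** OLS of EE on $A_{w,L}$ over the period gives a slope
   $\beta$ (kcal/min per count/min). NEAT is the activity-driven EE above
   the quietest moment of the period:
   $\mathrm{NEAT}(t) = \beta\,(A_{w,L}(t) - \min_P A_{w,L})$, clipped at 0
   (`fit_neat()`, `neat_series()`).
3. **NEAT-free EE.** $EE_{\mathrm{free}}(t) = EE(t) - \mathrm{NEAT}(t)$.
4. **TEF.** The preprandial baseline is the mean NEAT-free EE over
   07:15–07:45 (with its own, separately fitted NEAT model); TEF is the
   1-min left Riemann sum of $EE_{\mathrm{free}} - \mathrm{baseline}$ over
   the analysis window, expressed in kcal and as % of the meal's energy.

Because the pre-breakfast and postprandial windows are fitted separately,
the NEAT-free series is deliberately discontinuous at breakfast; no
re-levelling is applied.

### Parameters that matter

| parameter | default | why |
|---|---|---|
| integration grid | $w$ 0..30, $L$ −20..20 min | brackets published optima (3–11 min windows, ~0 lag) with generous margin |
| integration statistic | windowed mean | Pearson $r$ and the NEAT series are invariant to mean-vs-sum (the slope compensates); the mean keeps counts/min units and makes truncated boundary windows comparable. `integration.statistic = "sum"` is available for sensitivity analysis |
| tie-break | smallest $w$, then smallest $|L|$, then $L \le 0$ first | prefers the most parsimonious, physiologically causal spec; ties within 1e-12 of the maximal $r$ count as exact |
| EE advance | 2 min | validated response time of open-circuit chambers; applied at load time (`advance_ee()`), truncating rather than padding so no fabricated samples enter a regression |
| Weir coefficients | 3.941, 1.106, −2.17 | de-facto standard (kcal, L, g·min⁻¹); alternatives differ by <1%; overridable in config |
| periods | pre-breakfast 07:15–07:45, morning 08:00–12:00, waking 08:00–23:00 (12:00–23:00 without breakfast), sleep 23:00–07:00 | the standard 33-h chamber protocol; all half-open `[start, end)` so a 4-h window holds exactly 240 samples |

### Numerical and degenerate-input choices

* Boundary windows are truncated, not discarded: the pre-breakfast period
  is only 30 min long and cannot afford edge loss. A window entirely
  outside the series yields `NA`, excluded from correlation and regression.
* Gaps in the minute grid are a hard error; optional explicit linear
  interpolation (`fill_gaps = "linear"`, bounded by `max_gap`) is logged,
  never silent.
* A non-positive fitted slope contradicts the assumed positive EE–activity
  dependency: the fit is flagged `degenerate`, NEAT is set to 0 with a
  warning, and the flag propagates into the `tef_result` so the user can
  see that the estimate equals the raw postprandial area. Constant activity
  over a period degrades the same way for the NEAT-removal method, and is a
  hard error for the intercept methods (EE₀ is undefined).
* Negative TEF estimates from the intercept methods are returned as-is
  with a warning — they are a documented failure mode of those methods,
  not a bug.
* Per-meal TEF reuses the NEAT model fitted on the full waking period for
  every 4-h meal window (refitting per window is available), and uses the
  pre-breakfast NEAT-free mean as the baseline for all meals ("preprandial"
  is only defined there); a 30-min-before-each-meal alternative exists but
  is off by default.

## The simulator: what it emulates, and what a green test establishes

`simulate_session()` draws a 33-h stay (22:00 → 07:00 two days later) as
`EE = basal + TEF + NEAT + noise`, with every latent component returned as
ground truth (bit-exactly summing to the emitted EE):

* **basal**: a 24-h cosine (amplitude 0.05 kcal/min, peak 16:00) around
  1.14 kcal/min, reduced 8% during sleep;
* **TEF**: per meal, `tef_fraction × kcal` spread over a gamma-shaped
  response (shape 2, scale 60 min, truncated at 6 h and renormalized).
  The response deliberately keeps ~8% of its mass beyond 4 h, reproducing
  the observed failure of postprandial EE to return to baseline within a
  meal window — so windowed estimates *should* sit slightly below the
  meal's total fraction, and recovery is judged against the ground-truth
  TEF energy inside the window;
* **activity**: an exactly constant waking floor (3100 counts/min) plus a
  small Gaussian jitter (sd 30 counts — seated subjects still fidget) and
  Poisson-timed bursts (6/h, ~2000 counts peak, compact 4–12 min triangular
  support), near-constant 2250 counts/min during sleep. Defaults land the
  24-h EE near 1850 kcal, 24-h mean activity near 3500 counts/min, and the
  NEAT share of waking EE near 10% — the published sedentary-chamber
  ranges. The pre-breakfast window receives ordinary waking activity:
  published baselines put pre-breakfast EE well above the NEAT-free level,
  so a "quiet rest window" would misrepresent the protocol;
* **NEAT**: the same linear model the estimator assumes, with a known
  kernel (half-width 7, lag 0 — on the search grid) and slope
  8×10⁻⁵ kcal/min per count;
* **noise**: white Gaussian, sd 0.05 kcal/min (AR(1) available, off by
  default).

`simulate_pair()` produces the fed/fasted pair for ΔEE by *sharing every
random draw* and simply withholding the breakfast TEF component from the
fasted EE. That makes ΔEE an exact oracle for windowed truth — which is
what a reference method should be in a validation harness — at the price of
not modelling between-visit variability.

What the simulator does **not** emulate: meal-time eating movements
(activity and TEF are independent by construction, while real chewing and
plate-handling correlate with meal onsets), between-day variation of basal
rate, autocorrelated drift of the calorimeter, posture changes, or exercise
(the linear EE–activity model is explicitly a sedentary-range
approximation). A green recovery test therefore establishes correctness of
the *computational pipeline* under the model's own assumptions, not
field accuracy.

## Known limitations

The central one is structural, and the package's validation makes it
visible rather than hiding it. When the NEAT model is fitted on a
postprandial window, the smooth meal response is part of the regression's
error term and correlates, by chance, with integrated activity. The induced
TEF error is approximately
$240 \cdot \rho(\mathrm{tef}, A)\cdot \mathrm{sd}(\mathrm{tef}) \cdot k$
with $\rho$ floored near $\sqrt{\mathrm{kernel\ span}/n}$ by the
kernel-induced autocorrelation, and — notably — *invariant to the scale of
activity*. At zero measurement noise this leaves a residual bias of order
0.5–1 percentage point in morning TEF (mean ≈ −0.9 over 20 simulated
subjects), which no realistic random-activity world can push below
0.2 points. On noisy data this bias is small relative to the noise-driven
spread (±1.5–2 points), and the method remains the best of the three
single-session estimators: in the package's own 20-subject experiments its
Bland–Altman mean difference against ΔEE is an order of magnitude smaller
than either intercept method's, and all its estimates are positive.

Other limitations: the method is undefined during sleep (arousal cost is
not modelled); high-intensity exercise would need nonlinear EE–activity
models; and the pre-breakfast baseline inherits the 30-min window's
sampling noise.

## A worked session

```{r example}
sim <- simulate_session(simulation_params(seed = 1))
s <- sim$session
s

morning <- period("08:00", "12:00", "morning")
intake <- s$meals[[1]]$energy_kcal

tef_original(s, morning, intake)
suppressWarnings(tef_schutz(s, morning, baseline_rmr(s), intake, "rmr"))
tef_schutz(s, morning, baseline_smr(s), intake, "smr")

pair <- simulate_pair(simulation_params(seed = 1))
tef_delta_ee(pair$fed, pair$fasted, morning, intake)

# ground truth inside the window
idx <- period_indices(s, morning)
100 * sum(sim$truth$tef_by_meal[idx, "breakfast"]) / intake
```

```{r recovery}
rec <- recovery_experiment(simulation_params(seed = 1), n_seeds = 10)
rec$summary
```

## Design decisions that were genuinely open

* **Config format.** The configuration schema (periods, integration grids,
  calorimetric coefficients, simulator block) is JSON via `jsonlite`:
  no TOML parser is available in the supported dependency set, and
  hand-rolling one buys nothing scientifically.
* **Windowed mean vs sum** for integration: mean (see table above); both
  give identical NEAT series and correlations.
* **EE advance timing**: applied once at load time, before every
  regression, and exposed in config — the alternative (advancing inside
  each estimator) would let the same session carry two different
  alignments.
* **Recovery oracle**: ground-truth TEF energy inside the analysis window,
  not the meal's total fraction, because the response tail beyond the
  window is a designed feature of the stated world.
* **Tie-breaking** in the grid search and the treatment of degenerate fits
  are documented above; both situations are silent in the published
  description of the method.
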