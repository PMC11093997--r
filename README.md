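# marmonav

Analyses for hippocampal recordings in freely moving primates that explore
space with rapid head–gaze shifts rather than whisking locomotion: 3D
head–gaze kinematics from rigid-body quaternions, putative cell typing,
place/view/speed selectivity, mixed-selectivity encoding models, population
place decoding, and head-movement-triggered LFP theta phase resetting. A
synthetic-session generator with a ground-truth manifest makes every stage
testable by parameter recovery.

The package is organised as an analysis workflow: each computation lives in
`R/` as a tested function, and the numbered drivers under `analysis/` run
the stages in order and write their tables under `results/`.

## The quantities at the core

* **Translation speed** `s = ||Δ(x, y, z)|| / Δt` (cm/s) on 4 Hz low-pass
  filtered positions; **angular head velocity** `ω = θ / Δt` (deg/s) with
  `θ = 2 arccos |⟨q_t, q_{t+1}⟩|` the geodesic distance between consecutive
  unit head quaternions. Rapid head movements are epochs with
  `ω > 200 deg/s` and amplitude `≥ 10°` (artifacts above 2000 deg/s); body
  translations use `s > 16 cm/s` and `≥ 30 cm` (artifacts above 300 cm/s).
* **Main sequence**: peak velocity vs amplitude, fit with the Naka–Rushton
  form `R(X) = R_max · Xⁿ/(Xⁿ + Kⁿ) + b` by multi-start non-linear least
  squares.
* **Burst index** `BI = (Σ ISI_meas − Σ ISI_pred) / (Σ ISI_meas + Σ ISI_pred)`
  over 2–20 ms, with both ISI distributions normalized over 2–40 ms and the
  prediction from a rate-matched Poisson process; 2-means on
  (BI, mean rate) labels putative pyramidal cells vs interneurons.
* **Spatial information content**
  `I = Σᵢ Pᵢ (λᵢ/λ̄) log₂(λᵢ/λ̄)` bits/spike over place bins or
  facing-location ("view") bins, tested against circular-shift permutation
  nulls; **speed scores** are Pearson correlations of 250 ms-smoothed rate
  with TS or AHV, requiring `r > 0.3` and a shuffle criterion.
* **Encoding GAM** `y ~ Poisson(exp(β₀ + Σ f_r(x_r)))` with penalized
  splines; nested forward selection gated on circular-shift nulls of
  explained deviance `ED = 1 − D_fitted/D_null`.
* **Place decoding**: linear one-vs-one SVM on 200 ms fixation trials
  (AHV < 200 deg/s) over 4 coarse place classes, with greedy ensemble
  construction against random-combination controls.
* **Theta phase resetting**: Rayleigh `Z = nR̄²` of the 4–10 Hz phase
  across head movements, per event-relative sample; Morlet
  time–frequency maps in dB against the aperiodic (1/f) spectrum.

## Worked example

```r
library(marmonav)

sess <- gen_session(generator_params(duration_s = 600, n_pyr = 12,
                                     n_int = 6, seed = 1))
kin    <- compute_kinematics(sess$bundle$tracking)
events <- detect_movements(kin)
movement_concurrency(events)$frac_during_stops
#> [1] 0.8067633
he  <- events[events$kind == "head" & !events$artifact, ]
fit <- fit_naka_rushton(he$amplitude, he$peak_velocity, seed = 1)
round(fit$par["r_max"] + fit$par["b"])  # saturating peak velocity, deg/s
#> 696
```

The generator injected 80% of head–gaze shifts during body stops and a
main sequence saturating near `R_max + b = 845 deg/s`; the detected events
recover the stop fraction within its bootstrap CI, and the saturating
velocity to the extent the (amplitude-limited) event sample constrains it.
Running the full workflow:

```sh
Rscript analysis/01_simulate.R     # session + ground truth -> results/
Rscript analysis/02_kinematics.R   # events, concurrency, main sequence
Rscript analysis/03_cell_types.R   # burst index + k-means typing
Rscript analysis/04_selectivity.R  # SIC place/view + speed scores
Rscript analysis/05_encoding.R     # GAM forward selection per unit
Rscript analysis/06_decoding.R     # SVM ensembles (own, richer session)
Rscript analysis/07_theta_reset.R  # TFR, Rayleigh time course, modulation
```

prints, among other things (seed 1):

```
head movements during body stops: 80.7% (99% CI 75.8-85.5%)
agreement with generator labels: 100%
exact variable-set recovery: 83%
label-shuffled accuracy: 0.233 (chance 0.25)
Rayleigh Z peak 289.9 at +14 ms (critical 4.60 at p=0.01)
```

i.e. cell types, encoding variable sets, chance-level decoding and the
injected theta phase reset are all recovered from the synthetic session.

## Acceptance script

`scripts/acceptance.R` regenerates its inputs from scratch and recomputes
three checkable quantities: the chance-level accuracy of the label-shuffled
4-class place decoder, and the Naka–Rushton `R_max` recovered from
synthetic marmoset and rat main-sequence data. Run it from the repository
root against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
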