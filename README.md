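# delayrep

Simulation and kinematic analysis of how a visuomotor delay is
represented by the motor system.

When the visual consequence of a hand movement — a cursor, or the paddle
of a pong game — lags the hand by a delay τ, adaptation could reflect a
veridical **time** representation (hand leads its feedback by τ̂) or a
state-based surrogate: a **spatial shift** (feedback trails by a fixed
Δx̂), a **gain** (feedback moves with smaller amplitude, ĝ), or a
**mechanical system** (the paddle behaves like a damped mass on a spring,
x̂ₕ = xₚ + (B̂/K̂)ẋₚ + (M̂/K̂)ẍₚ, the Taylor form of the time map).
`delayrep` implements all four maps, simulators of the tasks that
dissociate them (minimum-jerk blind reaches, figure-eight / sine /
sinusoid-mixture blind tracking, and a desk-scale delayed-paddle pong
game), the kinematic metrics that read the fingerprints out —

* reach amplitude with velocity-threshold onset/offset (hypermetria),
* tracking R² with the 0.6 exclusion rule,
* direct least-squares conic ellipse fits of target–hand phase plots
  (major-axis slope ↔ gain/mechanical, intercept ↔ spatial shift),
* cross-correlation target–hand delay (positive = hand leads ↔ time),
* Hann-windowed zero-padded periodogram and FFT amplitude spectra with
  dB conversion and band-restricted dominant frequency
  (frequency-flat ↔ gain vs frequency-rising ↔ mechanical),

— plus a seeded synthetic-cohort generator and a parameter-recovery
routine that close the simulate → analyze → recover loop without human
recordings.

## Worked example

```r
library(delayrep)

# A single sagittal sine cycle (A = 8 cm, T = 5 s) tracked blind, with the
# hand trailing the target by the usual 0.2 s:
spec <- track_spec("sine", A = 8, T_cycle = 5)
base <- simulate_blind_tracking(spec, representation_params("none"),
                                baseline_lag = 0.2)
target_hand_delay(base$hand, base$target)
#> [1] -0.2

# After delay exposure, a time representation with tau = 0.5 s makes the
# hand precede the target; its lead over the baseline hand is 0.2 + 0.5:
tim <- simulate_blind_tracking(spec,
                               representation_params("time", tau_hat = 0.5),
                               baseline_lag = 0.2)
target_hand_delay(tim$hand$y, base$hand$y, rate = 200)
#> [1] 0.7

# A spatial-shift representation leaves the lag alone but lifts the
# target-hand ellipse off the identity line:
sh <- simulate_blind_tracking(
  spec, representation_params("spatial_shift", dx_hat = 4),
  baseline_lag = 0.2)
fit_ellipse(sh$target$y, sh$hand$y)[c("slope", "intercept")]
#> $slope
#> [1] 1.000565
#> $intercept
#> [1] 4

# Generate a small synthetic cohort under a gain ground truth and recover
# the parameter from the paired sessions:
cs <- cohort_spec(n_participants = 1, group = "delay", task = "track_sine",
                  true_model = representation_params("gain", g_hat = 1.2),
                  tracking_noise_sd = 0.1, param_jitter_sd = 0,
                  trials_nd = 3, trials_pd = 3, seed = 42)
cohort <- generate_cohort(cs)
recover_parameters(cohort[[1]], cohort[[2]])$best
#> <representation_params> gain (g_hat = 1.20015)
```

The slope near 1 with intercept 4 cm says "spatial shift, not gain"; a
recovered ĝ of 1.2 with the lowest residual says the gain generator was
identified. `run_pipeline()` chains generate → analyze → recover into
seeded, manifest-audited artifacts (`metrics.csv`, `summary.json`,
`recovery.csv`), and `inst/cli/delayrep.R` exposes the same steps as
shell subcommands.

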