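---
title: "Models and metrics for visuomotor delay representation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and metrics for visuomotor delay representation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delayrep)
```

## The problem

When a cursor or game paddle follows the hand with an imposed delay
$\tau$, the motor system adapts — but *what* does it learn? A delay can be
represented veridically as a time lag, or approximated by state-based
surrogates that need no explicit clock. This package implements four
candidate representations as maps from a displayed-paddle (or imagined
cursor) trajectory $x_p(t)$ to the hand trajectory $\hat{x}_h(t)$ a mover
holding that representation would produce:

| variant | map | free parameter |
|---|---|---|
| none | $\hat{x}_h = x_p$ | — |
| time | $\hat{x}_h(t) = x_p(t+\hat\tau)$ | $\hat\tau$ (s) |
| spatial shift | $\hat{x}_h = x_p + \Delta\hat{x}$ | $\Delta\hat{x}$ (cm) |
| gain | $\hat{x}_h = o + \hat{g}\,(x_p - o)$ | $\hat{g}$ |
| mechanical | $\hat{x}_h = x_p + \frac{\hat B}{\hat K}\dot x_p + \frac{\hat M}{\hat K}\ddot x_p$ | $\hat B/\hat K$ (s), $\hat M/\hat K$ (s²) |

The mechanical variant treats the paddle as a damped mass on a spring
attached to the hand; choosing $\hat B/\hat K = \hat\tau$ and
$\hat M/\hat K = \hat\tau^2/2$ makes it the second-order Taylor expansion
of the time map, with frequency-domain amplitude gain
$\sqrt{1 + \hat\tau^4\omega^4/4}$ — it behaves like a gain that *grows
with frequency*, which is the key discriminating signature.

The representations leave distinct fingerprints on three "blind" transfer
tasks (no visual feedback of the hand):

* **reaching** (minimum-jerk, 10 cm, 0.3 s): time → on-target endpoints;
  shift/gain/mechanical → hypermetria (overshoot).
* **figure-eight / sine tracking**: time → the hand leads the target
  (cross-correlation lag); shift → the target–hand ellipse's major axis
  gains an intercept; gain/mechanical → its slope grows.
* **sinusoid-mixture tracking**: gain → a frequency-flat amplitude
  increase; mechanical → an increase that rises with frequency (dB
  difference slope).

## Simulation conventions

**Sampling.** 200 Hz throughout (the rate at which such kinematics are
recorded); the pong physics step is 1 ms (a 1 kHz control loop).

**Tracking baselines and the time variant.** Manual tracking trails the
target; the baseline (post-no-delay) hand is the target path delayed by
0.2 s. Because all track paths are analytic (sine, figure-eight, mixture),
lagged or advanced signals are produced by evaluating the path at shifted
time arguments rather than by shifting and padding sample arrays; padding
a single 5 s cycle with held samples demonstrably biases cross-correlation
measurements. The time variant predicts a hand that precedes the *target*
by $\hat\tau$ — the mover places the imagined cursor on the target and the
hand leads it by the represented delay — so with $\hat\tau = 0.5$ s its
lead over the 0.2 s-lag baseline hand is 0.7 s. The state-based variants
apply pointwise to the lagged cursor, where the phase of the cursor is
immaterial to their amplitude/offset effects.

**Gain origin and shift direction.** The gain map needs a fixed point and
the shift map a direction, neither of which is dictated by the
one-dimensional equations. We scale about the movement start for reaches
and about the path centre (the cursor mean) for tracking, which reproduces
pure amplitude scaling without introducing offsets; the shift points from
start to target for reaches and along +y (sagittal) for tracking, because
game hits happen only on upward paddle strokes.

**Simulated reach endpoints.** The reported endpoint is the point of
maximal along-reach excursion of the hand (before endpoint noise). For
monotone trajectories this is the terminal sample; for the mechanical
variant, whose velocity term overshoots mid-movement, it captures the
hypermetric extreme. Endpoint noise is zero-mean Gaussian, SD 1 cm per
axis.

**Derivatives.** The mechanical map uses 2nd-order central differences
with 2nd-order one-sided stencils at the ends — deterministic and testable
against analytic sines (the measured amplitude gain matches
$\sqrt{1+\hat\tau^4\omega^4/4}$ within 1% for $\omega\hat\tau \le 2$).

**Mechanical parameters.** $\hat B/\hat K$ and $\hat M/\hat K$ are exposed
independently (`taylor_params()` is a convenience, not a constraint),
because useful illustrative settings — e.g. $\hat B/\hat K = 0.5$ s with
$\hat M/\hat K = 0.005$ s² — do not correspond to a single-$\hat\tau$
expansion.

**Pong game.** The ball reflects elastically off side/bottom walls; the
upper wall adds a horizontal jitter (deflection angle
$\mathcal N(0, 0.05\pi\,\mathrm{rad^2})$, or uniform $\pm 13$ cm/s) so
play does not collapse to a fixed pattern. Hits require an upward paddle
and a downward ball and update the velocity as
$\dot x' = 0.7\,\dot x_b + 0.42\,\dot x_p$ (frontal),
$\dot y' = -0.7\,\dot y_b + 0.42\,\dot y_p$ (sagittal, always positive
given the preconditions); preserving ball speed therefore needs a paddle
at least $0.3/0.42 \approx 0.71$ times the ball's fall speed. Delay
schedules: abrupt (0.1 s from trial 1) or gradual (0.004 s/trial, reaching
0.1 s at trial 25). Contact is detected when the ball's sagittal position
crosses the paddle line within the paddle's frontal extent during a step,
with linear interpolation inside the step; wall collisions resolve before
paddle collisions and corner hits reflect both components. The paddle's
frontal width is not dictated by the physics and defaults to 4 cm. Ball
speed changes from the frontal coupling are not clipped. Display-only
details (hit bar, timer, the triangular haptic force profile beyond its
peak magnitude $m_b\,\Delta v/\Delta t$) are not simulated. Reference
policies (dead, scripted, a proportional ball chaser with optional
reaction lag) make the simulator exercisable without a human.

## Analysis conventions

**Reach amplitude.** Onset at 2% of peak speed; offset 0.1 s after speed
first drops below 5% following the peak, clipped to the trial end (the
simulated trajectories stop exactly at $t_f$); amplitude is the Euclidean
distance between the onset and end positions.

**Tracking quality.** $R^2 = 1 - \frac{\mathrm{var}(x_h-x_t) +
\mathrm{var}(y_h-y_t)}{\mathrm{var}(x_h)+\mathrm{var}(y_h)}$, with trials
below 0.6 flagged for exclusion. Note the denominator is the hand variance
only: an uncorrelated equal-variance hand scores $-1$, not 0.

**Ellipse fit.** The target–hand scatter of each dimension (one ellipse
per dimension, frontal $(x_t, x_h)$ and sagittal $(y_t, y_h)$) is fitted
with the direct least-squares conic method under the ellipse constraint
$4ac - 4b^2 > 0$, using the numerically stable partitioned eigensystem on
centred/scaled coordinates. The centre follows from the conic gradient;
the counterclockwise major-axis angle uses the four-case arccotangent
rule *conditioned on* $a$ vs $c$ (with the arccotangent on
$(-\pi/2,\pi/2]$, after normalizing the quadratic form positive definite):
conditioning the branches on the sign of $b$ instead — a formulation that
circulates in the literature — assigns the wrong branch for negative-slope
ellipses, which we verified against eigenvector ground truth on
constructed rotated ellipses. Slope $= \tan\theta$ and intercept
$= o_h - \mathrm{slope}\cdot o_t$. Scatter whose minor/major axis ratio
falls below $10^{-3}$ (e.g. noiseless gain-model tracking, which is a
perfect line) falls back to the principal axis of the centred scatter with
the line through the centroid; exactly collinear input is an error.

**Cross-correlation delay.** Integer-sample argmax over $\pm 2$ s of the
mean-subtracted signals, with each lag's full-overlap product divided by
the norms of the two overlapping segments (an overlap cosine). The
normalization matters: the raw product sum shrinks linearly with overlap
length, which drags the argmax toward zero by ~0.15 s on a single 5 s
cycle; the cosine form recovers constructed lags exactly. Positive values
mean the hand precedes the target.

**Spectra.** The periodogram uses a Hann window and zero padding to 25
times the signal length (rounded up to a 2-3-5-smooth FFT length; a prime
padded length makes the mixed-radix FFT quadratic), scaled so a pure sine
of amplitude $A$ peaks at power $A^2/2$; amplitude $=\sqrt{2\,pow}$ and
$\mathrm{dB} = 10\log_{10}(pow)$. The same dB convention,
$10\log_{10}(A^2/2)$, is used everywhere — including after the plain FFT
amplitude $A = 2|\mathrm{FFT}|/L$ — since a power expressed in dB must go
through a logarithm. Component amplitudes are read as the local power peak
within one Hann main-lobe half-width (2/duration Hz) of each probe
frequency. Dominant frequency restricts a 101-sample moving-average
smoothed dB profile to 0.5–1.5 Hz (excluding the low-frequency pause
peak), with the window shrinking symmetrically at the edges and ties
broken toward the lowest frequency.

## The synthetic cohort generator

Human recordings for this paradigm are not publicly deposited, so the
package generates participant-like datasets with the statistical structure
the analysis assumes: per participant, a post-no-delay session under the
veridical mapping and a post-delay session under a ground-truth
representation (control cohorts use the veridical mapping in both, making
the sessions exchangeable). Defaults mirror the experimental protocol:
45 reaches per session to three targets 10 cm away at 45° spacing;
15/45 tracking trials; one 120 s mixture trial; 10/30 pong trials;
endpoint noise SD 1 cm; baseline lag 0.2 s.

Two quantities are artifact assumptions with no experimental anchor, and
are documented as such:

* **Tracking motor noise** (the experiment specifies endpoint noise only):
  per-sample Gaussian noise, low-pass smoothed at 5 Hz so trajectories
  stay kinematically plausible; default SD 0.1 cm, a small jitter relative
  to the 2–8 cm path amplitudes.
* **Between-participant spread**: the active model parameter is jittered
  multiplicatively with 10% SD, producing spread comparable to published
  per-participant scatter without claiming any exact variance.

`recover_parameters()` inverts the generator: the post-no-delay mean hand
estimates the imagined cursor, and for each candidate variant a single
parameter is fitted by bounded scalar search (an exact grid over
integer-sample lags for the time variant; golden-section otherwise),
reporting per-variant residuals so model selection stays with the caller.
All residuals are evaluated on a common window that excludes the region
contaminated by the time variant's terminal hold, keeping them comparable.
Two parameterization notes: the fitted time parameter is the lead over the
*target* (the baseline lag estimated from the no-delay session is
subtracted from the fitted cursor-advance), so control data truthfully
recovers $\hat\tau \approx -0.2$ s rather than 0; and reach endpoints
alone cannot distinguish gain from spatial shift when all targets are
equidistant — tracking data can. `representation_params()` accepts any
$\hat g > 0$ (the adaptation hypothesis predicts $\hat g > 1$, but
recovery on null data must be free to return $\hat g \approx 1$).

```{r recovery-example}
spec <- cohort_spec(n_participants = 1, group = "delay",
                    task = "track_sine",
                    true_model = representation_params("gain", g_hat = 1.2),
                    tracking_noise_sd = 0.1, param_jitter_sd = 0,
                    trials_nd = 3, trials_pd = 3, seed = 42)
cohort <- generate_cohort(spec)
recover_parameters(cohort[[1]], cohort[[2]])$fits
```

Model discrimination between gain and mechanical generators uses the
least-squares slope of the post-minus-pre dB difference across the five
mixture frequencies (`db_difference_slope()`): ~0 dB/Hz for gain,
~1.2 dB/Hz for a mechanical generator with $\hat\tau = 0.2$ s.

## What passing tests do and do not show

The generator emulates the two-session structure, the representation
maps, and endpoint/tracking noise. It does not emulate reaction times,
submovement corrections, trial-to-trial learning curves, inter-trial
return movements, or realistic motor variability structure — so passing
tests certify that the *pipeline* (simulate → measure → recover) is
self-consistent at the stated noise levels, not that human data would
behave this way. Reproducing published group effect sizes is explicitly
out of scope: those depend on the unavailable participant recordings.
Inferential statistics (mixed ANOVA, sphericity corrections, post hoc
tests) are likewise out of scope; the package stops at the tidy per-trial
metric table.

## Problem sizes and numerical choices

Test and example problem sizes are chosen to exercise every code path at
desk scale: tracking tests use single 5 s cycles (1001 samples at 200 Hz);
the mixture analyses use the full 120 s trial; pong trials in tests run
5–30 s (the physics is identical at any duration, and hit counts simply
scale); recovery noise curves use 20 replicates per noise level and
generator discrimination 100 replicates. Tolerances: exact identities to
1e-12; derivative-based comparisons to the finite-difference truncation
error; stochastic recoveries to 2%. Non-integral delay-buffer lags round
to the nearest control step (all canonical delays are integral at 1 ms).
Seeded runs are byte-reproducible; upper-wall jitter can be disabled
entirely for bit-identical physics regressions.
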