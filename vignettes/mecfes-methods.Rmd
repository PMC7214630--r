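---
title: "Methods: VMC estimation, closed-loop stability and outcome scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VMC estimation, closed-loop stability and outcome scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mecfes)
```

## The problem

Myoelectrically controlled functional electrical stimulation (MeCFES) closes
a loop through the user's body: surface EMG of the voluntarily controlled
wrist extensors is recorded *while* the finger flexors are being electrically
stimulated, the voluntary muscle contraction (VMC) is estimated from it, and
the stimulation current follows the estimate. The recording therefore
contains, besides the low-level stochastic voluntary EMG (microvolts), the
responses to each stimulation pulse — a direct artifact and a compound muscle
action potential (M-wave), both orders of magnitude larger, plus randomly
occurring H-reflexes and F-waves, motion artifacts, and mains hum. The
estimator exists to separate the stochastic, volitional component from this
structured contamination; the controller maps it to stimulation; and because
residual contamination scales with the stimulation itself, the loop can
become unstable (latch-up). This package implements each stage as a tested,
parameterised operation and provides a synthetic-signal generator so every
claim is checkable in simulation.

## Signal model and generator

Sampling is fixed at 2000 Hz with one stimulation pulse per 60 ms, giving
120-sample inter-stimulus bins; all per-bin quantities live at the 16.667 Hz
bin rate.

The generator (`make_envelope()`, `synthesize_emg()`, `inject_responses()`,
`adc_quantize()`) emulates:

* **Voluntary EMG** — Gaussian white noise band-passed to 20–450 Hz
  (4-pole Butterworth), scaled per bin so the bin's sample SD equals the
  envelope value. The 20–450 Hz band is the conventional surface-EMG band;
  the recorded-signal model in the source device is specified only by its
  front-end filter, so a standard band was chosen once. The per-bin scale
  uses the filter's *analytic* white-noise RMS gain (sum of squared impulse
  response), keeping generation strictly causal — the same trace can
  therefore be produced bin-by-bin inside the closed-loop simulator,
  bit-identically.
* **Quasi-stationary responses** — a biphasic double-exponential artifact
  confined to samples 0–19 (peak 150 µV/mA) and a damped-sinusoid M-wave
  over samples 5–45 (peak 40 µV/mA), both scaling linearly with the pulse
  current and multiplied by a common per-pulse jitter factor
  `1 + N(0, jitter_sd)`. Absolute response amplitudes on real skin depend on
  electrode placement and are not standardised; the defaults are plausible
  placeholders and every one is a parameter. Recruitment nonlinearity is
  deliberately outside the recorded-signal model.
* **Late reflexes** — with per-pulse probability `reflex_prob` (only when a
  pulse is actually delivered), a raised-cosine event centred at sample 80
  (40 ms), ±8 samples of support, latency jitter ±3 samples, half-normal
  amplitude with scale `reflex_amp_sd`. This is exactly the region the
  second blanking window targets.
* **Background** — 50 Hz hum with random phase (note: 50 Hz is exactly 3
  cycles per bin, so hum is bin-periodic and the comb filter cancels it);
  Poisson-timed raised-cosine motion transients of 10–50 ms width; 16-bit
  quantization over a ±5000 µV input-referred full scale (the 60 dB
  amplifier gain is folded into µV-referred units), with saturation.

What the generator does **not** emulate: electrode–skin impedance and its
drift, amplifier recovery dynamics, recruitment curves, muscle fatigue, or
any biomechanics. Tests passing on this generator show the estimator handles
the *statistical structure* it assumes — stationary Gaussian EMG,
current-proportional quasi-stationary responses — not that it handles every
physiological recording.

## The estimator

`estimate_vmc()` composes five stages, each exported separately so the
composition can be verified against the manual chain (a test asserts
bit-exact equivalence):

1. **Bandpass** — a single biquad (2 poles) with −3 dB corners at 16 and
   500 Hz, run as direct-form-II-transposed with explicit state. The same
   recursion, state carried across bins, is used by the streaming simulator,
   so batch and closed-loop estimation agree bit-exactly.
2. **Segmentation** into 120-sample bins; a trace whose length is not a
   multiple of 120 is a shape error, not silently truncated.
3. **Comb filter** — subtract the previous bin per sample. The first output
   bin is defined as zero (no predecessor); the alternative, passing it
   through, would break exact annihilation of bin-periodic input from bin 1
   and was rejected. Disabled, the stage is the identity.
4. **Blanking** — samples `[0,20) ∪ [70,90)` are *excluded from the ARV*,
   not zero-filled, so the divisor is the 80 retained samples. "Around the
   80th sample" is realised as the symmetric window `[70,90)`; both windows
   are configuration, not constants.
5. **ARV and smoothing** — mean absolute value over retained samples, then
   `v_k = α a_k + (1−α) v_{k−1}` with `α = 1 − exp(−Δt/τ)` (exact
   zero-order-hold discretisation of a first-order lag; the nominal device
   parameter "1 s" is read as the time constant τ), initial state 0.

Two numerical facts matter when comparing the estimate to a known envelope
`A`:

* the comb is a difference of two nearly independent Gaussian bins, so it
  inflates the expected ARV by √2;
* the 2-pole bandpass is not flat over the EMG band: its RMS gain over the
  20–450 Hz synthesis band is ≈ 0.905 (computed from the designed transfer
  functions, `arv_expectation_factor()` does this from the impulse
  responses).

The steady-state estimate for clean EMG is therefore
`A · √(2/π) · √2 · 0.905 ≈ 1.021 A`, and that product — not the bare
half-normal mean — is the oracle the tests use, at Monte-Carlo tolerance
(±7 % at 500 bins). The estimator itself reports the uncorrected ARV, as the
device does.

Blanking-window immunity is exact at the stage level: contamination confined
to the blanked samples cannot change the ARV, bit-for-bit, and the tests
assert it there. Through the *full* chain the IIR bandpass smears energy
from blanked into retained samples (as any front-end filter, analog or
digital, does), so full-chain immunity is approximate; the corresponding
full-chain test asserts strong suppression (steady estimate ≤ 2 % of the raw
response ARV) rather than bit-exactness.

## Controller and buttons

The VMC-to-current map is the minimal piecewise-linear law consistent with
its three named parameters: zero below the offset, slope `gain` above it,
clipped at `max_stim`. It is 1-Lipschitz in the VMC with constant `gain`
(property-tested). The three-button interface is a small state machine:
short mode-press toggles paused/active, long press cycles
none → offset → gain → max_stim → none, plus/minus nudge the selected
parameter. Step sizes (offset 0.5 µV, gain ×1.1, max_stim 1 mA) and ranges
(offset 0–100 µV, gain 0.01–100 mA/µV, max_stim 1–60 mA) are package
defaults — the hardware steps are not documented anywhere — and every
transition is logged (the buzzer surrogate).

## Closed loop and the latch-up boundary

`run_closed_loop()` applies the command computed from bin *k* to the pulse
of bin *k + 1* — a one-bin (60 ms) actuation delay, the minimal causal
ordering. Voluntary EMG does not depend on the loop, so it is pre-generated
from the envelope; contamination randomness is drawn from a derived
substream, which keeps the silent-model loop bit-identical to open-loop
estimation (tested).

Define leakage λ as the steady-state estimate per mA of constant
stimulation on a zero-EMG trace (`measure_leakage()`). At zero offset the
small-signal rest dynamics are `v ← (1−α) v + α λ G v`, so the rest fixed
point loses stability exactly at `G·λ = 1`; saturation at `max_stim` then
turns divergence into a latched full-on state. This criterion is the
package's own derivation and is tested only against the simulation.

Realising a *prescribed* λ needs care: with the comb enabled, deterministic
quasi-stationary templates are cancelled and the only leakage is stochastic
(jitter-driven — measured and checked against a Monte-Carlo oracle
`E|j_k − j_{k−1}| ×` filtered-template ARV in its own test). The stability
map therefore disables the comb, scales the response templates so the
measured λ matches the request (leakage is linear in template amplitude;
`leakage_model()` calibrates via `measure_leakage()`), adds a small 0.3 µV
hum as the perturbation that lets an unstable fixed point escape — 50 Hz is
bin-periodic, so with the comb off it contributes a constant, small ARV
drive — and disables quantization (`adc_range = Inf`), because the
converter's ±0.076 µV deadband would otherwise dominate the microvolt-scale
small-signal behaviour that is the object of study.

The default grid (gains 2.5–40 mA/µV × leakages 0.03–0.24 µV/mA, factor-2
spacing, 30 s of rest per point, τ = 0.5 s) spans loop gains 0.075–9.6;
the acceptance test checks that the empirical boundary brackets `G = 1/λ`
within one grid step on every leakage row, that latching is monotone in
gain, that λ = 0 never latches, and that all 20 points agree with the
scalar fixed-point oracle `latch_oracle()`, which iterates the loop map
directly with no signal synthesis.

`tracking_error()` compares the command to the one an ideal estimator would
produce (envelope × `arv_expectation_factor()`, same smoother, same PWL),
skipping the first 5τ; for a clean step-tracking run the relative RMS error
is under 10 % (test tolerance).

## Outcome scoring

IPPA: score = mean over the chosen items (1–7 of them) of importance ×
difficulty, each rated 1–5; follow-up reuses baseline importance; change =
baseline − follow-up, in [−20, 20] (property-tested, extremes attained
exactly). QUEST: eight device items rated 1–5; total = mean of item scores;
with a single respondent the SDs are undefined and flagged.

`cohort_summary()` reports mean/SD of the change, the paired effect size
mean/SD (large if > 0.8), the count of participants with change divided by a
reference SD above 0.8, the count with strictly positive change, a paired
Wilcoxon signed-rank test (zero differences dropped, normal approximation
with continuity and tie correction — the standard `wilcox.test` behaviour
for tied paired data), and usefulness counts by C5/C6/C7 level group. Two
definitional choices were open and are fixed here: the per-person "effect"
is the individual change divided by the *group* SD of changes, and the
reference SD may be supplied externally (`sd_ref`) because published summary
tables sometimes disagree with their own rows. The packaged participant
table is such a case: its printed summary row (mean 4.6, SD 3.5) does not
match recomputation from its 27 printed rows (mean 4.43, SD 2.65), and four
rows are internally inconsistent between the printed change and pre − fu.
The package carries the table as printed and reports both recomputed and
printed-summary statistics side by side rather than reconciling them.

`make_synthetic_cohort()` generates cohorts with a target expected mean
change: per item, an integer difficulty reduction is drawn as
Binomial(4, q), giving expectation `3 · 4q` with uniform importance
(attainable up to 12); above that, importance is upweighted toward 5 (the
absolute ceiling is 20, beyond which the generator refuses). Baseline
difficulties are drawn uniformly from the values that keep the follow-up in
range, which leaves the change distribution unaffected. Recovery of the
target (±5 % at n = 500) is an acceptance test.

## Problem sizes and tolerances

Monte-Carlo tests use 200–1000 bins of synthetic signal (12–60 s), 500-bin
runs for steady-state estimates (±5–7 %), a 5 × 4 stability grid at 30 s per
point, and n = 500 synthetic cohorts (±5 %); the full suite runs in well
under a minute. File outputs round to 6 significant digits, and file-based
comparisons in tests use that declared precision. Degenerate inputs are
errors, not guesses: empty retained sets, non-multiple-of-120 traces,
ratings outside 1–5, fewer than two cohort records, |target effect| > 20.

## Known limitations

* The artifact/M-wave amplitudes, reflex statistics and motion model are
  plausible defaults, not fitted to recordings; leakage magnitudes in real
  devices are unknown, so the stability map is a property surface, not a
  reproduction of any clinical event.
* The estimator band-gain correction assumes the synthetic 20–450 Hz EMG
  spectrum; real EMG spectra differ by muscle and electrode geometry.
* Single recording and stimulation channel; no slew-rate limiting of the
  command (the hardware may have had one); no muscle force, fatigue or grip
  biomechanics.
* The logistic regressions relating usefulness to IPPA/QUEST items in the
  source trial are routine fits reported only as p-values and are out of
  scope.
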