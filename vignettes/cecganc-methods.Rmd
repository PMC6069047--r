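---
title: "Methods: QRS-preserving active noise cancellation for capacitive ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QRS-preserving active noise cancellation for capacitive ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cecganc)
```

## The problem

Capacitive ECG sensors measure the cardiac potential through clothing. Four
sensors mounted in a row give two outer channels (`sigL`, `sigR`) that see
the cardiac dipole with opposite polarity, and two inner channels (`sigaL`,
`sigaR`) that see nearly the same cardiac pickup as their outer neighbours.
The measured ECG and the noise references are formed by differencing:

* `ECGm = BPF_{0.05–35 Hz}(sigL − sigR)` — cardiac projections add, common
  interference cancels;
* `rL = sigL − sigaL`, `rR = sigR − sigaR` — the cardiac component (almost)
  cancels, the motion artifact survives because each sensor couples to body
  motion through a slightly different path.

Active noise cancellation streams `d(i) = ECGm(i)`, predicts its noise
component from the stacked reference vector
`n'_i = [rL(i)…rL(i−L+1), rR(i)…rR(i−L+1)]ᵀ` through an adaptive filter
`y(i) = ŵᵀ n'_i`, and outputs the error `e(i) = d(i) − y(i)`.

Two facts break the textbook setting. First, the references are never
perfectly cardiac-free: a residual of the clean signal leaks into them, so a
fast filter learns to cancel the ECG itself. Second, the QRS complex is a
large intermittent event; from the filter's point of view it is impulsive
noise that provokes a violent weight update, after which the filter actively
removes QRS power. Both effects erode exactly the feature an R-peak detector
needs.

## The switched update rule

The filter computes, at every sample, the affine-projection (APA) update
with step μ₁ over the last `P` reference vectors `U_i`, and its Euclidean
norm `q_i = ‖μ₁ U_i (U_iᵀU_i + εI)⁻¹ e_i‖₂` — the *update quantity*. The
switch compares `q_i` to an adaptive threshold `β δ(i−1)`:

* `q_i < β δ(i−1)` (ordinary noise): apply the APA update, and let the
  threshold state track the update quantity,
  `δ(i) = α δ(i−1) + (1−α) q_i`;
* `q_i ≥ β δ(i−1)` (impulsive event — a QRS complex, a motion spike): apply
  the affine projection *sign* algorithm (APSA) step with the small length
  `μ₂ = γ δ(i−1)`, i.e.
  `ŵ_i = ŵ_{i-1} + μ₂ U sgn(e) / √(sgn(e)ᵀUᵀU sgn(e))`, and leave δ
  **frozen**.

The APSA step has exactly norm μ₂ whatever the data, so a single QRS complex
moves the weights by at most `γδ` per sample instead of `q`. Freezing δ on
the sign branch matters: it is what prevents a run of impulsive samples from
inflating the threshold and re-admitting them as "ordinary". Two classical
baselines are also provided: plain APA with fixed step μ, and the
robust-variable-step-size switch in its original form (unit APA step,
APSA step δ, and a threshold recursion driven by `min(|e|/‖n'‖, δ)`; that
recursion's published typesetting is ambiguous and we read the middle term
as `|e(i)|/‖n'_i‖₂` — the proposed rule above does not depend on this
reading).

## Parameters

| Parameter | Default | Meaning, units, rationale |
|---|---|---|
| μ (`mu`) | 0.05 | plain-APA step; the comparison operating point for ANC-by-APA |
| μ₁ (`mu1`) | 0.4 | APA step of the switch; large enough to track nonstationary motion noise, safe because QRS events are diverted to the sign branch |
| γ (`gamma`) | 0.01 | sign-step scale (< 1); keeps the per-sample movement during QRS two orders below the threshold |
| β (`beta`) | 3.5 | threshold scale separating ordinary from impulsive update quantities |
| α (`alpha`) | 0.995 | threshold memory; time constant ≈ 200 APA iterations (1 s at 200 Hz) |
| δ₀ (`delta0`) | 0.01 | threshold start; δ self-calibrates to the running update quantity within seconds, and end-state behaviour is insensitive to δ₀ over 0.01–0.2 (verified during development) |
| ε (`eps_reg`) | 1e-6 | ridge on `UᵀU`; start-up safety only — see below |
| L | 16 | taps per reference channel (80 ms at 200 Hz) |
| P | 4 | projection order |

**Why L = 16, P = 4.** Neither value is dictated by the method; they were
fixed by a pilot grid (L ∈ {4, 8, 16} × P ∈ {1, 2, 4}) on the moderate
synthetic preset. Short filters (L = 4) cannot model the difference between
the sensors' motion-coupling paths, and the switch then loses its advantage;
L = 16 reproduces the expected qualitative ordering (switched > small-step
APA > raw > large-step APA in estimated SNR) robustly across seeds. P > 1
matters because the reference is strongly autocorrelated and plain NLMS-type
updates converge slowly on it.

**Why ε must stay tiny.** A large ridge stabilises plain APA in quiet
stretches, but the switch's QRS discriminator *is* the unregularised
amplification `q ≈ μ₁ |e| / ‖u‖`: an error the reference cannot explain
produces a huge candidate update, which is precisely the rejection signal.
Regularising it away (ε comparable to `‖u‖²`) makes QRS events look
ordinary and they get eroded. ε = 1e-6 therefore only guards the exactly
singular start-up (zero-padded history).

## What the synthetic generator emulates

No recordings are distributed with the method, so the package ships a
generator (`synth_params()`, `generate_record()`) that emulates the
measurement chain:

* clean ECG: per-beat Gaussian bumps for P, Q, R, S, T at fixed offsets
  around scheduled R positions; RR intervals jittered (5% default); P and T
  magnitudes small, since capacitive sensors barely register them;
* motion noise: baseline wander (random-phase sinusoids < 0.8 Hz), bursts
  (Poisson-scheduled, 10 Hz low-passed, Hann-tapered white noise), and
  single-sample impulses;
* sensors: `sigL/R = ±s/2 + h∗n + v`, `sigaL/R = ±(1−λ)s/2 + h∗n + v` with
  per-sensor random length-5 unit-DC-gain FIR coupling paths `h` and white
  sensor noise `v`. The reference then carries the motion difference plus a
  residual `λ·s/2`; λ (`leakage_coeff`, default 0.1) dials how badly the
  ANC correlation condition is violated, λ = 0 giving ideal references.

The *moderate* preset (equal to the `synth_params()` defaults) was
calibrated once, against the **raw** signal only, so that the unfiltered
`ECGm` reproduces the raw operating conditions reported for real
chair/driving recordings — detection average around 75–85% and estimated
SNR of a few units (measured: Avg mean 78.2, range 65–93, SNR mean 7.6 over
five 300-s seeds). The *clean* preset models a motionless subject and uses
λ = 0. The *abnormal* preset scales amplitudes several-fold to emulate
sensor-separation events and severe vibration; no algorithm is expected to
cope with it, and it exists to reproduce the failure mode qualitatively.

What the generator does **not** model: respiration, electrode-impedance
drift, powerline interference, physiologic waveform variability and
arrhythmia, or noise statistically indistinguishable from QRS complexes.
A green test on synthetic data therefore establishes internal correctness
and the direction of the claimed effects, not clinical performance.

## Numerical and procedural choices

* **Band-pass realisation**: cascaded Butterworth biquads (bilinear
  transform, prewarped), order 4 per band edge by default. Order 2 leaves
  |H| = 0.19 at 60 Hz for fs = 200, too little rejection for mains
  interference; order 4 gives < 0.04. Causal by default (the system is
  meant to run near-real-time); a zero-phase forward–backward option
  exists. The causal acquisition filter delays R peaks by ≈ 2 samples at
  200 Hz — well inside the 80-ms evaluation window; the ANC itself adds no
  further lag (verified by test).
* **References are used raw** (no band-pass), matching their defining
  equations; an optional band argument exists.
* **Start-up**: reference vectors are zero-prepadded, so output length
  equals input length; ε keeps the start-up normal matrix invertible.
* **sgn(0) = 0**, which turns a zero-error APSA step into an explicit
  no-op (`SKIPPED` branch) rather than a division by zero.
* **Windowing**: the adaptive filter runs as one continuous stream; the
  6-s/2-s-overlap windows exist for the optional postprocessing fallback
  only (RR-ratio rule outside (0.5, 2.0) or filtered/raw power above 4.0
  reverts a window to its raw input — thresholds are reconstructions, the
  originals being unpublished, and default off in evaluations). Stitching
  filtered windows was rejected: it would double-filter overlaps and
  create boundary discontinuities.
* **Detector**: classic Pan–Tompkins chain with the published stage
  constants (5–15 Hz, 150-ms integration, 200-ms refractory, 0.125/0.875
  threshold updates, search-back at 1.66× the running RR mean). The
  internal band-pass is zero-phase and the integration window is
  centre-aligned, so detection carries no systematic latency; peaks are
  refined to the band-passed maximum within ±50 ms. All thresholds are
  data-adaptive, making the detector invariant to positive rescaling.
* **Peak matching**: 80-ms closed windows centred on true peaks; greedy
  one-to-one matching in time order, which for fixed-width windows equals
  the optimal assignment (cross-checked against an exhaustive
  augmenting-path matcher in the tests).
* **Estimated SNR**: power inside 100-ms windows around R peaks over power
  elsewhere. The window set is caller-chosen (true peaks when ground truth
  exists, detected peaks otherwise), honouring both phrasings of the
  definition.

## Known limitations

* The power-ratio **QRS-conservation metric can be inflated by artifacts**:
  a comparator that both erodes the QRS *and* rings inside the QRS windows
  (large-step APA under impulsive noise) can show a higher power ratio than
  a filter that genuinely preserves the complex. A shape-regression
  coefficient against the band-passed clean signal separates the two; the
  package reports the power ratio as defined and the test suite documents
  one seed where the comparator's artifacts win the power comparison.
* With an **uninformative reference** (ideal, noise-free conditions), any
  normalised-update APA at a large step injects misadjustment noise driven
  by the unpredictable signal itself; its level is invariant to the
  reference amplitude. Perfect positive predictivity is then unattainable
  for the large-step comparator even on clean data.
* Abnormal noise — events that rewrite the reference statistics or mimic
  QRS morphology — is not removed by any algorithm here; the switch then
  degrades gracefully towards the raw signal but cannot improve it.
* The sign branch protects only the QRS; P and T waves in the S-Q interval
  are treated as noise territory and may be attenuated.

## Reproducibility

Every stochastic object is a deterministic function of an integer seed;
records embed their seed and parameters in `meta`, CLI commands write
manifests. The compiled streaming loop and the pure-R step functions are
alternative engines of `run_anc()` and are asserted to agree to 1e-9 on all
four algorithms.
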