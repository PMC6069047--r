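# cecganc — QRS-preserving motion-artifact cancellation for capacitive ECG

Capacitive (non-contact) ECG sensors, e.g. mounted in a chair back or a
driver's seat, pick up the cardiac signal through clothing — and, with it,
large motion artifacts that ruin R-peak detection. Active noise cancellation
(ANC) with reference signals taken from *adjacent* sensor pairs can remove the
motion component, but a plain adaptive filter also attacks the QRS complex:
the references are never perfectly free of cardiac signal, and the QRS is a
large, intermittent event that provokes a violent weight update. The filter
then cancels the very feature the downstream detector needs.

This package implements an ANC scheme that treats the QRS complex as
*impulsive noise* seen from the adaptive filter's point of view. It switches
between two update rules:

- **APA** (affine projection algorithm), projection order *P*, step μ₁:
  `w_i = w_{i-1} + mu1 * U (UᵀU)⁻¹ e_i` — fast convergence on the correlated
  motion reference, used between beats;
- **APSA** (affine projection sign algorithm), a fixed-norm robust step
  `w_i = w_{i-1} + step * U sgn(e) / sqrt(sgn(e)ᵀUᵀU sgn(e))`, used whenever
  the APA update quantity `q = ‖mu1·U(UᵀU)⁻¹e‖₂` exceeds an adaptive threshold
  `beta * delta(i-1)`, with the small step `gamma * delta(i-1)`.

The threshold state δ tracks the APA update quantity with memory α on APA
iterations and is frozen on sign iterations, so a QRS burst cannot inflate it.
Result: motion noise in the S-Q interval is removed at full speed while the
QRS power survives filtering. The package also provides the four-channel
measurement model (`ECGm = BPF(sigL − sigR)`, references `rL = sigL − sigaL`,
`rR = sigR − sigaR`, 0.05–35 Hz band), a Pan–Tompkins R-peak detector, the
standard evaluation indices (Se, P+, Avg, estimated SNR, PIR), a calibrated
synthetic-data generator with ground-truth R peaks, and a small CLI.

## Worked example

```r
library(cecganc)

p     <- noise_preset("moderate", duration_s = 120, seed = 42)
gen   <- generate_record(p)            # 4 sensor channels + ground truth
d     <- build_measured_ecg(gen$record)
refs  <- build_references(gen$record)
truth <- peak_set(gen$truth$true_r_peaks, 200)

res <- run_anc(d, refs$r_left, refs$r_right,
               anc_config(filter_config("proposed")), fs = 200)
res
#> <anc_result> 24000 samples, algorithm 'proposed'
#>   branches: APA=18098, APSA=5902

metrics_report(truth, pan_tompkins(res$filtered, 200),
               signal = res$filtered, fs = 200)
#> <metrics_report> TP=127 FN=13 FP=19 | Se=90.71% P+=86.99% Avg=88.85% | SNR^=8.30

metrics_report(truth, pan_tompkins(d, 200), signal = d, fs = 200)
#> <metrics_report> TP=119 FN=21 FP=70 | Se=85.00% P+=62.96% Avg=73.98% | SNR^=2.08
```

The APSA branch fires on roughly a quarter of the samples — the QRS complexes
and impulsive artifacts — and the switched filter lifts Avg from 74.0% to
88.9% and the estimated SNR from 2.1 to 8.3 on this record. The one-shot
comparison against plain APA:

```r
run_benchmark("moderate", seed = 42, duration_s = 120)
#>  condition    se p_plus   avg snr_hat qrs_conservation
#>        raw 85.00  62.96 73.98   2.079           1.9839
#> apa_mu0.05 90.71  70.56 80.63   3.822           0.6201
#>  apa_mu0.4 23.57  52.38 37.98   1.127           0.4502
#>   proposed 90.71  86.99 88.85   8.300           0.9048
```

`qrs_conservation` is the power of the filtered signal inside 100-ms windows
around the true R peaks relative to the band-passed clean signal: the
large-step APA keeps only 45% of the QRS power (and collapses to Se = 24%),
the small-step APA keeps 62% but removes little noise, while the switched
algorithm keeps 90% of the QRS and still achieves the best SNR.

## Command line

```sh
Rscript inst/cli/cecganc.R simulate --duration 60 --noise-preset moderate --seed 7 --out rec.csv
Rscript inst/cli/cecganc.R denoise  --in rec.csv --algorithm proposed --out filt.csv
Rscript inst/cli/cecganc.R detect   --in filt.csv --fs 200 --out peaks.txt
Rscript inst/cli/cecganc.R evaluate --truth rec.csv.rpeaks.txt --detected peaks.txt \
                                    --fs 200 --signal filt.csv --report report.json
Rscript inst/cli/cecganc.R benchmark --preset moderate --seed 7 --out bench/
```

Every command writes a JSON manifest (seed, config, package version)
sufficient to reproduce its outputs.

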