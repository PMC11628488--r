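---
title: "Methods: simulating and decoding auditory stream-segregation ERP BCIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding auditory stream-segregation ERP BCIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmebci)
```

## The paradigm

An auditory stream-segregation multiclass ERP (ASME) brain-computer
interface presents several interleaved oddball tone streams. Because the
streams are widely separated in pitch and rapid, listeners perceive them as
concurrent segregated streams; attending to the rare deviant tones of one
stream elicits event-related potentials (an N200, a P300, and a late
frontal negativity) that a classifier can detect, so the attended deviant
— one of four selection targets — can be decoded from the EEG.

Two four-class designs are supported, plus a single-stream control:

| design | streams | overall SOA | stimuli/trial | per-stream ratio |
|---|---|---|---|---|
| `asme4stream` | 4, one deviant each | 0.15 s | 600 | 9:1 |
| `asme2stream` | 2, two deviants each | 0.30 s | 300 | 8:1:1 |
| `oddball` | 1 | 1.0 s | 120 (configurable) | 5:1 |

Streams are interleaved in a fixed cyclic order — the only interleaving
that keeps the within-stream SOA constant at `n_streams * soa` (0.6 s for
both ASME designs, chosen so each stream remains perceptually segregated).
The two designs deliberately differ in SOA and ratio so that the
within-stream SOA and the target:nontarget ratio (1:9 within the attended
stream) match across designs once attention is fixed on one deviant.

Deviants are placed uniformly at random within each stream's slot list,
subject to two constraints that are standard oddball practice (the designs
themselves only fix the ratios): no deviant in a stream's first two slots,
and no two deviants of the same stream back to back. Counts per role are
exact for every seed, never merely expected. A trial's duration is
`n_stimuli * soa` (90 s for both ASME defaults).

## The synthetic recordings

`simulate_recording()` emulates what a 64-channel EEG + 2-channel EOG
acquisition at 1000 Hz would see during one trial:

* **ERP components** — each an asymmetric raised-cosine bump with an onset
  latency, peak latency, width, amplitude and a smooth scalp topography,
  added at the onsets of the events matching its eliciting condition
  (attended deviants only, all deviants, or every stimulus). The defaults
  (`default_erp_components()`) are a fronto-central N200 (2 µV at 0.20 s),
  a centro-parietal P300 (3.2 µV with 0.30 s onset for the four-stream
  preset, 3.5 µV with 0.24 s onset for the two-stream preset), a frontal
  N700 for the four-stream preset only, and a small exogenous response to
  every tone. These mirror the orderings this paradigm family shows so the
  comparisons are exercisable; they are simulation defaults, not empirical
  claims.
* **Background noise** — spatially correlated 1/f^α activity (α = 1 by
  default) built by randomly mixing independent pink-noise sources into
  the 64 channels, each channel rescaled to the configured broadband SD,
  plus 10%-variance independent sensor noise to keep the spatial
  covariance full-rank.
* **Ocular artifacts** — Poisson blinks (12/min, 0.3 s raised-cosine,
  200 µV in VEOG) coupled into the EEG with gains decaying front to back
  (Fp\* 0.5, AF\* 0.3, frontal 0.15, elsewhere 0.01), and Poisson saccades
  (6/min, 80 µV steps in HEOG with small lateral-frontal coupling). The
  coupling values are conventional plumbing, not fitted to data.

`simulate_session()` replicates the session layout — 6 runs of 4 trials,
each of the four attention targets instructed once per run in
seed-dependent order — and `simulate_epochs()` produces analysis-ready
epochs directly (continuous 1/f noise, band-pass filtered and sliced at a
fixed spacing, plus the injected kernels), which is the right surface for
validating the bootstrap estimators against known ground truth.

### What the generator does and does not emulate

The generator reproduces the features the analysis chain is sensitive to:
attention-dependent components with realistic latencies and topographic
gradients, 1/f spectra, spatially correlated background, and ocular
artifacts that dominate frontal channels. It does **not** model volume
conduction from dipolar sources, non-stationarity (drowsiness, alpha
bursts), muscle or line noise, or inter-subject variability. The default
background SD is 2 µV: calibrated once so that session-scale bootstrap
estimates carry less than ±0.5 µV error at 90 target epochs — the
package's stated parameter-recovery condition — which makes single-epoch
SNR optimistic relative to real recordings. Passing tests therefore
demonstrate correctness of the machinery and recoverability of injected
parameters at that SNR, not expected real-data performance; real P300
decoding operates closer to the decision threshold than the high-SNR
preset suggests.

## Preprocessing: EOG artifact removal

Per run, EEG channels are high-pass filtered at 1 Hz (zero-phase
Butterworth of designed order 2; the forward–backward application makes
the effective order 4 and the phase exactly zero), then runs are
concatenated. PCA reduces the 64 EEG channels to 15 whitened principal
components; FastICA (logcosh contrast, symmetric decorrelation, tolerance
1e-4) unmixes them. Each EOG channel is band-pass filtered 1–10 Hz
(zero-phase, for alignment with the zero-phase EEG filtering) and the
independent component with the highest absolute Pearson correlation is
zeroed — absolute value because an IC's sign is arbitrary. Removal
subtracts the back-projection of the zeroed components: an idempotent
oblique projection of rank equal to the number of zeroed ICs (1 if both
EOG channels pick the same component, else 2) that leaves the retained
subspace and the EOG channels untouched. In the four-class simulation the
remover is fitted on the training runs only and applied unchanged to the
held-out runs.

Zero-phase filtering applies the exact forward–backward response of the
Butterworth design — its squared magnitude, with zero phase — in the
frequency domain after odd-reflection padding. This is the ideal
transient-free realisation of forward–backward filtering: the designed
attenuation holds exactly and filtering commutes with time reversal to
machine precision, a property the test suite asserts. (Sequential
time-domain passes approximate the same response but leave
edge-transient asymmetries at very low cutoff frequencies.)

FastICA convergence: on signal-poor, near-Gaussian data the symmetric
update may not reach tolerance even though the blink component separates
within a few iterations and the zeroing procedure stays well defined. The
fitter therefore warns and proceeds with the last iterate by default
(storing `n_iter` and `converged`), and raises an error only with
`strict = TRUE`. Pipeline drivers cap the iterations at 100 for the same
reason: past the point where the artifact components have separated,
further rotation of the Gaussian bulk does not change which components
correlate with the EOG.

## ERP statistics

Epochs span `[-0.1, 1.2)` s around each stimulus — half-open by
convention, so 1300 samples at 1000 Hz and exactly 325 after decimation
to 250 Hz — band-passed 1–40 Hz for ERP work (the band itself
anti-aliases the 4:1 decimation) and baseline-corrected with the
pre-stimulus mean (standard practice; switchable off). Events too close
to a recording edge are dropped and counted, never silently.

* **Signed-r²** — per channel and time point, the point-biserial
  correlation `r` between amplitude and the binary target/nontarget
  label, reported as `sign(r)·r²`; zero-variance points map to 0 by
  convention. Values are bounded by 1 and flip sign with label polarity.
* **P300 peak amplitude** — 1200 bootstrap replicates; each draws 80% of
  the target epochs without replacement, averages them, and takes the
  spatiotemporal maximum over the configured channels within 0.2–0.5 s.
  The estimate is the replicate mean.
* **P300 onset latency** — 250 replicates; each draws 80% of the target
  and of the standard epochs, averages the configured channels into one
  virtual channel (chosen for robustness; a per-channel alternative is a
  config away), and runs a one-sided Welch t-test (target > standard) per
  time point. The replicate's latency is the first time in 0.2–0.5 s with
  p < 0.05; replicates with none are discarded and counted in `n_failed`,
  and if all fail the estimate is undefined (`NA`), not an error. With
  zero variance the p-value is 0 or 1 by the sign of the mean difference,
  which makes noiseless step inputs exact test oracles.

The default channel set is Fz, FCz, Cz, CPz, Pz. The conventional midline
quintet for P300 work is sometimes printed with FPz in place of CPz, but
FPz does not exist on this 64-channel montage (only Fp1/Fp2 do), so CPz —
the standard centro-parietal midline site — is the default and any
channel list can be supplied explicitly.

## Decoding

Features are the mean amplitudes of ten non-overlapping 0.1 s intervals
over 0–1.0 s post-onset, per EEG channel, after 0.1–8 Hz band-passing:
10 × 64 = 640 dimensions. The classifier is LDA with the pooled
within-class covariance shrunk toward a scaled identity,
`(1-γ)S + γνI`, γ estimated by the analytic Ledoit–Wolf formula (clipped
to [0, 1]); the bias puts the decision boundary at the class-mean
midpoint, `f(x) ≥ 0` predicting target.

* **Binary decoding** is scored by AUC (rank/Mann–Whitney formulation
  with midranks on ties) under 4-fold chronological cross-validation:
  contiguous, temporally ordered blocks, never shuffled. Chance is 0.5.
* **The four-class simulation** uses 3 folds over 6 runs (2 consecutive
  training runs, 4 test runs, every run tested twice). Per fold the EOG
  remover, features and LDA are fitted on the training runs only. For
  each test trial, `f(x)` is computed for every deviant epoch, grouped by
  deviant class, and the class with the largest mean decision value wins;
  ties break to the lowest class index and are counted, and a class with
  no epochs gets `-Inf` and is never selected. Chance is 1/4.

Accuracy is tallied over all 48 fold-level predictions (24 unique trials,
each tested twice); the binomial significance threshold uses the 24
unique trials, matching the convention that reports P_th = 0.42 at
α = 0.05 for 24 four-class trials: the threshold is `k/n` with `k` the
(1-α) binomial quantile at chance 1/N, so accuracies strictly above it
have tail probability below α. Note that the threshold *decreases* with
more classes (chance falls), and with more trials.

The information transfer rate is
`R = log2 N + P log2 P + (1-P) log2((1-P)/(N-1))` bits per trial (with
`0·log 0 = 0`) and `B = V·R` bits per minute. Because published ITRs in
this family are subject averages with an unstated trial-rate convention,
`V` is always an explicit argument; the default used by the simulation is
the trial rate implied by the paradigm (60 / trial duration, i.e. 2/3
trials per minute at the full 90 s trials).

## Workload

NASA-TLX weighted workload: six subscale scores on 0–100 and the 15
pairwise comparisons tallied into per-dimension weights,
`WWL = Σ tally·score / 15`. Scores are accepted on the continuous 0–100
scale (the 21-tick variant maps onto it).

## Validation scale and determinism

Every stochastic step is seeded: sessions derive per-run/per-trial seeds
from a master seed by fixed arithmetic, the ICA initialisation and both
bootstrap estimators take explicit seeds, and equal seeds give
bit-identical results (asserted in the tests). The test suite and the
acceptance script run the full session layout at a validation scale
chosen to keep 20-seed studies fast while preserving every structural
property exactly — 80-stimulus four-stream trials (40 for the two-stream
design: ratios, interleaving and labeling are unchanged) synthesised at
250 Hz, which is also the analysis rate, so decimation is exercised by a
dedicated 1000 Hz case rather than by every test. Estimator-recovery
checks use 90 target epochs (15 deviants × 6 runs, the full-session
count). The latency-ordering check pairs the two designs on the same
noise seed, mirroring a within-subject comparison.

## Known limitations

* The generator's SNR presets are free parameters; nothing here estimates
  them from real recordings.
* ICA on near-Gaussian data is only defined up to rotation in the
  Gaussian subspace; the EOG-correlation selection is stable because the
  artifact directions are strongly non-Gaussian, but the non-artifact ICs
  should not be interpreted.
* The 3-fold run-level scheme tests each run once with a training block
  recorded after it; "chronological" here means contiguous unshuffled
  blocks, not strict causality.
* BrainVision support covers the multiplexed IEEE-float32 layout only,
  and import is read-only.
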