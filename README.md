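# asmebci

Analysis toolkit for **auditory stream-segregation multiclass ERP (ASME)
brain-computer interfaces** — BCIs in which several interleaved oddball
tone streams are presented at once and the stream/deviant a listener
attends to is decoded from the event-related potentials (N200, P300,
late frontal negativity) its rare deviant tones elicit.

The package is aimed at BCI and ERP methods researchers who want to
design such paradigms, analyse recordings, or study the pipeline's
statistical behaviour on fully synthetic data with known ground truth.
It covers, end to end:

* **Paradigm design** — ASME-4stream (4 streams × 2-stimulus oddball,
  SOA 0.15 s, 600 stimuli/trial, ratio 9:1), ASME-2stream (2 streams ×
  3-stimulus oddball, SOA 0.3 s, 300 stimuli, 8:1:1) and a single-stream
  control; exact per-stream ratios, fixed cyclic interleaving (so the
  within-stream SOA is N·t = 0.6 s), target/nontarget labeling, TSV
  serialisation and WAV rendering.
* **Synthetic EEG** — continuous 64-EEG + 2-EOG recordings with
  attention-dependent ERP components, spatially correlated 1/f noise and
  Poisson blink/saccade artifacts; full 6-run × 4-trial sessions with
  stored ground truth.
* **Preprocessing** — zero-phase Butterworth filtering, PCA (15
  components) + FastICA EOG removal zeroing the independent components
  most correlated with the (1–10 Hz filtered) EOG channels; strict
  train/apply separation for decoding.
* **ERP statistics** — signed-r² discriminability maps and bootstrap
  estimators of P300 peak amplitude (1200 resamples of 80% of target
  epochs, spatiotemporal max in 0.2–0.5 s) and onset latency (250
  resamples, first significant one-sided Welch t between target and
  standard epochs).
* **Decoding** — 640-dimensional interval-mean features (10 × 0.1 s
  intervals × 64 channels, 0.1–8 Hz), shrinkage-LDA
  `f(x) = wᵀx + b` with `w = Σ̂γ⁻¹(μ₊ − μ₋)`, analytic Ledoit–Wolf γ;
  binary AUC under 4-fold chronological CV; a four-class BCI simulation
  (3 folds over 6 runs, per-trial argmax of class-mean decision values);
  the binomial significance threshold P_th; and the information transfer
  rate `R = log₂N + P log₂P + (1−P) log₂((1−P)/(N−1))`, `B = V·R`.
* **Workload** — NASA-TLX weighted workload `WWL = Σ tallyᵢ·scoreᵢ / 15`.

See `vignettes/asme-bci-pipeline.Rmd` for the methods account: models,
defaults, numerical conventions, and what the synthetic tests do and do
not demonstrate.

## Worked example

Simulate a four-stream session at validation scale (80-stimulus trials,
250 Hz synthesis) and run the full pipeline:

```r
library(asmebci)

cfg <- asme_paradigm("asme4stream", n_stimuli_per_trial = 80)
cfg
#> <asme_paradigm> asme4stream: 4 stream(s), SOA 0.15 s (within-stream 0.60 s), 80 stimuli/trial, ratio 9:1

session <- simulate_session(cfg, preset = "default", fs = 250, master_seed = 7)
sim <- run_bci_simulation(session, seed = 7)
sim
#> <bci_simulation> accuracy 1.000 over 48 predictions (24 unique trials)
#>   significance threshold P_th = 0.42 (alpha = 0.05) -> significant
#>   ITR: 2.000 bits/trial, 10.000 bits/min

erp <- run_erp_analysis(session, seed = 7)
erp$amplitude
#> P300 peak amplitude: 2.117 uV (bootstrap, 1200 replicates, 0.2-0.5 s, channels Fz/FCz/Cz/CPz/Pz)
erp$latency
#> P300 onset latency: 0.356 s (bootstrap, 250/250 replicates retained)
```

Reading the numbers: at the default moderate-SNR preset all 24 trials
(each tested in two of the three chronological folds, hence 48
predictions) are decoded correctly — well above the binomial significance
threshold of 0.42 for 24 four-class trials at α = 0.05 — giving the
ceiling ITR of log₂4 = 2 bits/trial. The bootstrap amplitude (2.1 µV
here) sits below the injected 3.2 µV kernel peak because the continuous
chain's 1 Hz drift-removal and 1–40 Hz band-pass attenuate the slow
unipolar P300 bump; the estimators recover injected parameters exactly
when epochs are built without that chain (see the estimator tests and
`simulate_epochs()`). The onset latency is the first time the
target-vs-standard Welch test turns significant, which trails the true
kernel onset by the time the response needs to clear the noise floor.

Standalone utilities print their published operating points directly:

```r
significance_threshold(24, 4, 0.05)$threshold_2dp
#> [1] 0.42
information_transfer_rate(0.86, 4, V = 60/90)
#> ITR: 1.1939 bits/trial, 0.7959 bits/min (N = 4, P = 0.860, V = 0.667 trials/min)
```

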