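# Shared fixtures, all generated in code. Validation-scale sessions keep
# the full session layout (6 runs x 4 trials, exact presentation ratios)
# but use shorter trials and a 250 Hz synthesis rate so multi-seed checks
# stay fast; see the methods vignette for the rationale.

desk_paradigm <- function(name = "asme4stream") {
  n <- switch(name, asme4stream = 80L, asme2stream = 40L, oddball = 24L)
  asme_paradigm(name, n_stimuli_per_trial = n)
}

.session_cache <- new.env(parent = emptyenv())

desk_session <- function(preset = "high-snr", master_seed = 1L,
                         paradigm = "asme4stream") {
  key <- paste(preset, master_seed, paradigm, sep = "|")
  if (is.null(.session_cache[[key]]))
    .session_cache[[key]] <- simulate_session(
      desk_paradigm(paradigm), preset = preset, fs = 250,
      master_seed = master_seed)
  .session_cache[[key]]
}

# One-trial recording with blinks for EOG-removal tests.
blink_recording <- function(seed = 42L, fs = 250, background_sd = 2,
                            blink_rate = 20) {
  sq <- build_sequence(desk_paradigm("asme4stream"), seed)
  simulate_recording(sq, trial_plan(1L, "D1"), list(),
                     noise_spec(background_sd = background_sd,
                                blink_rate = blink_rate),
                     fs = fs, seed = seed)
}

# Noiseless single-trial recording carrying only the given components.
noiseless_recording <- function(components, seed = 5L, fs = 250,
                                paradigm = "asme4stream") {
  sq <- build_sequence(desk_paradigm(paradigm), seed)
  simulate_recording(sq, trial_plan(1L, "D1"), components,
                     noise_spec(0, 0, 0, 0, 0, 0), fs = fs, seed = seed)
}

default_p300 <- function(amp = 5, onset = 0.30) {
  erp_component("P300", +1, peak_latency = onset + 0.12,
                onset_latency = onset, width = 0.30, peak_amplitude = amp,
                topography = erp_topography("centroparietal"))
}

# Epochs as the ERP analysis sees them, without the continuous filtering
# chain (kernel injected exactly); labels from the trial plan.
raw_epochs <- function(rec, ...) {
  make_epochs(as_continuous(rec, prefiltered = TRUE), band = c(1, 40),
              fs_out = rec$sampling_rate, ...)
}
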