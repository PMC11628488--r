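#' Standard 64-channel montage + EOG
#'
#' Channel labels of the extended 10-20 montage used throughout the package
#' (64 EEG channels followed by vertical and horizontal EOG).
#'
#' @return character vector of length 66.
#' @export
asme_channels <- function() {
  c("Fp1", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "FT10", "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "TP10", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2",
    "VEOG", "HEOG")
}

eeg_channels <- function() head(asme_channels(), 64L)

# Per-channel gain vector (unit max-abs) from a named gain table keyed by
# channel-name prefix; longest matching prefix wins, `default` otherwise.
topography_from_prefixes <- function(gains, default = 0.05) {
  ch <- eeg_channels()
  g <- rep(default, length(ch))
  names(g) <- ch
  keys <- names(gains)[order(nchar(names(gains)))]  # longest applied last
  for (k in keys) g[startsWith(ch, k)] <- gains[[k]]
  g / max(abs(g))
}

#' Scalp topographies for the simulated ERP components
#'
#' Smoothly graded per-channel gain vectors (unit max-abs) approximating a
#' centro-parietal (P300-like), fronto-central (N200-like) or frontal
#' (N700-like) scalp distribution on the 64-channel montage.
#'
#' @param which one of "centroparietal", "frontocentral", "frontal".
#' @return named numeric vector over the 64 EEG channels.
#' @export
erp_topography <- function(which = c("centroparietal", "frontocentral",
                                     "frontal")) {
  which <- match.arg(which)
  switch(which,
    centroparietal = topography_from_prefixes(list(
      CPz = 1.0, Pz = 1.0, Cz = 0.85, CP = 0.8, P = 0.65, C = 0.6,
      FCz = 0.5, PO = 0.35, FC = 0.3, Fz = 0.25, F = 0.1, O = 0.15,
      T = 0.1, Fp = 0.08, AF = 0.08)),
    frontocentral = topography_from_prefixes(list(
      FCz = 1.0, Fz = 0.9, Cz = 0.85, FC = 0.8, F = 0.6, C = 0.55,
      AF = 0.4, Fp = 0.3, CP = 0.3, P = 0.15, T = 0.1, PO = 0.08,
      O = 0.05)),
    frontal = topography_from_prefixes(list(
      Fz = 1.0, AFz = 0.9, FCz = 0.85, F = 0.8, AF = 0.7, Fp = 0.55,
      FC = 0.6, C = 0.35, Cz = 0.4, CP = 0.15, P = 0.08, T = 0.08)))
}

#' Specify a simulated ERP component
#'
#' The component's kernel is an asymmetric raised-cosine bump: zero before
#' `onset_latency`, rising to `polarity * peak_amplitude` at `peak_latency`,
#' back to zero at `onset_latency + width`.
#'
#' @param name component name ("N200", "P300", "N700", "exogenous", ...).
#' @param polarity +1 or -1.
#' @param peak_latency,onset_latency seconds relative to stimulus onset;
#'   `onset_latency < peak_latency < onset_latency + width`.
#' @param width total kernel duration in seconds.
#' @param peak_amplitude microvolts (non-negative; sign carried by polarity).
#' @param topography per-EEG-channel gain vector, unit max-abs.
#' @param elicited_by which events receive the component: `"target"`
#'   (attended deviants only), `"deviant"` (every deviant), or `"all"`.
#' @return object of class `erp_component`.
#' @export
erp_component <- function(name, polarity, peak_latency, onset_latency, width,
                          peak_amplitude,
                          topography = erp_topography("centroparietal"),
                          elicited_by = c("target", "deviant", "all")) {
  elicited_by <- match.arg(elicited_by)
  stopifnot(width > 0, peak_amplitude >= 0, polarity %in% c(-1, 1),
            onset_latency < peak_latency,
            peak_latency < onset_latency + width,
            length(topography) == 64L)
  structure(list(name = name, polarity = polarity,
                 peak_latency = peak_latency, onset_latency = onset_latency,
                 width = width, peak_amplitude = peak_amplitude,
                 topography = topography, elicited_by = elicited_by),
            class = "erp_component")
}

#' Default ERP component sets per paradigm
#'
#' Attention-dependent N200 and P300 (plus a late frontal N700 for the
#' four-stream design, where its target/nontarget difference is larger) and
#' a small exogenous response to every stimulus. P300 onset defaults differ
#' between designs (0.30 s four-stream vs 0.24 s two-stream) with peak
#' amplitudes in the low-microvolt range, mirroring the ordering that
#' attended-deviant responses show in this paradigm family; they are
#' simulation defaults, not empirical claims.
#'
#' @param paradigm_name "asme4stream", "asme2stream" or "oddball".
#' @param p300_amplitude,p300_onset overrides for the P300 parameters.
#' @return list of [erp_component()] objects.
#' @export
default_erp_components <- function(paradigm_name,
                                   p300_amplitude = NULL, p300_onset = NULL) {
  p3_on <- p300_onset %||%
    switch(paradigm_name, asme4stream = 0.30, asme2stream = 0.24, 0.24)
  p3_amp <- p300_amplitude %||%
    switch(paradigm_name, asme4stream = 3.2, asme2stream = 3.5, 5.0)
  comps <- list(
    erp_component("exogenous", -1, peak_latency = 0.1, onset_latency = 0.05,
                  width = 0.12, peak_amplitude = 1.0,
                  topography = erp_topography("frontocentral"),
                  elicited_by = "all"),
    erp_component("N200", -1, peak_latency = 0.20, onset_latency = 0.13,
                  width = 0.16, peak_amplitude = 2.0,
                  topography = erp_topography("frontocentral"),
                  elicited_by = "target"),
    erp_component("P300", +1, peak_latency = p3_on + 0.12,
                  onset_latency = p3_on, width = 0.30,
                  peak_amplitude = p3_amp,
                  topography = erp_topography("centroparietal"),
                  elicited_by = "target"))
  if (identical(paradigm_name, "asme4stream"))
    comps <- c(comps, list(
      erp_component("N700", -1, peak_latency = 0.70, onset_latency = 0.55,
                    width = 0.35, peak_amplitude = 1.5,
                    topography = erp_topography("frontal"),
                    elicited_by = "target")))
  comps
}

#' Background noise and artifact specification
#'
#' @param background_sd per-channel standard deviation of the 1/f^alpha
#'   background, microvolts (broadband, before any filtering).
#' @param spectral_exponent alpha of the 1/f^alpha spectrum.
#' @param blink_rate,saccade_rate ocular artifact rates, events per minute.
#' @param blink_amplitude VEOG blink amplitude, microvolts.
#' @param saccade_amplitude HEOG saccade amplitude, microvolts.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(background_sd = 2, spectral_exponent = 1,
                       blink_rate = 12, blink_amplitude = 200,
                       saccade_rate = 6, saccade_amplitude = 80) {
  stopifnot(background_sd >= 0, spectral_exponent >= 0, blink_rate >= 0,
            blink_amplitude >= 0, saccade_rate >= 0, saccade_amplitude >= 0)
  structure(list(background_sd = background_sd,
                 spectral_exponent = spectral_exponent,
                 blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 saccade_rate = saccade_rate,
                 saccade_amplitude = saccade_amplitude),
            class = "noise_spec")
}

#' Single-channel ERP component kernel
#'
#' Piecewise raised-cosine bump: rises over `[onset, peak]`, falls over
#' `[peak, onset + width]`; extremum is exactly
#' `polarity * peak_amplitude` at `peak_latency`; zero before the onset.
#' Its integral is `polarity * peak_amplitude * width / 2`.
#'
#' @param spec an [erp_component()].
#' @param fs sampling rate, Hz.
#' @param length kernel length in seconds (must cover onset + width).
#' @return numeric vector of `round(length * fs)` samples, microvolts.
#' @export
make_component_waveform <- function(spec, fs, length = NULL) {
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  length <- length %||% (spec$onset_latency + spec$width)
  if (length < spec$onset_latency + spec$width)
    stop("kernel length must cover onset_latency + width", call. = FALSE)
  n <- round(length * fs)
  t <- (seq_len(n) - 1L) / fs
  k <- numeric(n)
  on <- spec$onset_latency; pk <- spec$peak_latency
  off <- spec$onset_latency + spec$width
  rise <- t >= on & t <= pk
  fall <- t > pk & t <= off
  k[rise] <- 0.5 * (1 - cos(pi * (t[rise] - on) / (pk - on)))
  k[fall] <- 0.5 * (1 + cos(pi * (t[fall] - pk) / (off - pk)))
  spec$polarity * spec$peak_amplitude * k
}

# n samples of 1/f^alpha noise with unit-ish variance (scaled afterwards).
pink_noise <- function(n, alpha) {
  if (n == 0L) return(numeric(0))
  x <- stats::rnorm(n)
  if (alpha == 0) return(x)
  X <- stats::fft(x)
  f <- c(1e-12, seq_len(n - 1L))          # DC removed below
  f <- pmin(f, n - f)                     # two-sided frequency index
  scale <- f^(-alpha / 2)
  scale[1L] <- 0
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Spatially correlated multichannel 1/f background: random mixtures of
# independent pink sources plus a little independent sensor noise, each
# channel rescaled to `sd_target`.
background_noise <- function(n_channels, n_samples, sd_target, alpha,
                             n_sources = 16L) {
  if (sd_target == 0 || n_samples == 0L)
    return(matrix(0, n_channels, n_samples))
  src <- matrix(0, n_sources, n_samples)
  for (k in seq_len(n_sources)) src[k, ] <- pink_noise(n_samples, alpha)
  mix <- matrix(stats::rnorm(n_channels * n_sources), n_channels)
  out <- mix %*% src
  for (i in seq_len(n_channels)) {
    out[i, ] <- out[i, ] / stats::sd(out[i, ]) * sqrt(0.9) * sd_target
    out[i, ] <- out[i, ] + stats::rnorm(n_samples, sd = sqrt(0.1) * sd_target)
  }
  out
}

# Blink coupling gains into frontal EEG, by channel prefix.
blink_coupling <- function() {
  ch <- eeg_channels()
  g <- rep(0.01, length(ch))
  g[startsWith(ch, "F") & !startsWith(ch, "FC") & !startsWith(ch, "FT")] <- 0.15
  g[startsWith(ch, "AF")] <- 0.30
  g[startsWith(ch, "Fp")] <- 0.50
  names(g) <- ch
  g
}

saccade_coupling <- function() {
  ch <- eeg_channels()
  g <- rep(0.005, length(ch))
  lateral_frontal <- ch %in% c("F7", "F8", "AF7", "AF8", "FT7", "FT8")
  g[lateral_frontal] <- 0.15
  g[startsWith(ch, "Fp")] <- 0.10
  names(g) <- ch
  g
}

#' Simulate one trial's continuous EEG + EOG recording
#'
#' Sums, over every ERP component and every event matching its
#' `elicited_by` condition, the component kernel times its scalp topography
#' at the event onset; adds spatially correlated 1/f background noise; and
#' adds Poisson blink/saccade artifacts into VEOG/HEOG with fixed coupling
#' gains into frontal EEG. Event markers and the full ground truth are
#' stored on the result.
#'
#' @param seq a labeled or unlabeled [build_sequence()] event sequence
#'   (labels are derived from `plan` when absent).
#' @param plan the trial's [trial_plan()].
#' @param components list of [erp_component()] objects (possibly empty).
#' @param noise a [noise_spec()].
#' @param fs sampling rate in Hz (default 1000).
#' @param seed integer seed; identical seeds give bit-identical recordings.
#' @param pad seconds of signal-free (noise-only) padding before the first
#'   and after the last stimulus (default 1.5, enough for epoch windows).
#' @return object of class `eeg_recording`: list with `data` (66 x samples
#'   matrix, microvolts), `sampling_rate`, `channel_names`, `events`
#'   (data.frame: sample, onset_s, stream, stimulus_id, role, label, tag,
#'   trial_index, run_index), `run_index`, `ground_truth`.
#' @export
simulate_recording <- function(seq, plan, components = list(),
                               noise = noise_spec(), fs = 1000, seed = 1L,
                               pad = 1.5) {
  stopifnot(inherits(seq, "event_sequence"))
  if (is.null(seq$label)) seq <- assign_event_labels(seq, plan)
  for (cm in components)
    if (length(cm$topography) != 64L)
      stop("component '", cm$name, "' topography does not match the ",
           "64-channel montage", call. = FALSE)
  n_ev <- nrow(seq)
  dur <- 2 * pad + (if (n_ev) max(seq$onset_s) else 0)
  n <- ceiling(dur * fs)
  ch <- asme_channels()
  with_seed(seed, {
    data <- matrix(0, length(ch), n, dimnames = list(ch, NULL))
    ev_sample <- round((seq$onset_s + pad) * fs) + 1L
    # ERP components
    for (cm in components) {
      sel <- switch(cm$elicited_by,
        target = seq$label == "target",
        deviant = seq$role != "standard",
        all = rep(TRUE, n_ev))
      if (!any(sel)) next
      kern <- make_component_waveform(cm, fs)
      nk <- length(kern)
      drive <- numeric(n)
      for (s0 in ev_sample[sel]) {
        idx <- s0:min(n, s0 + nk - 1L)
        drive[idx] <- drive[idx] + kern[seq_along(idx)]
      }
      data[1:64, ] <- data[1:64, ] + cm$topography %o% drive
    }
    # background
    data[1:64, ] <- data[1:64, ] +
      background_noise(64L, n, noise$background_sd, noise$spectral_exponent)
    data["VEOG", ] <- stats::rnorm(n, sd = 0.3 * noise$background_sd)
    data["HEOG", ] <- stats::rnorm(n, sd = 0.3 * noise$background_sd)
    # blinks: 0.3 s half-cosine bump in VEOG, coupled front->back
    add_artifacts <- function(data, rate, amp, tmpl, eog, gains) {
      n_art <- stats::rpois(1L, rate * dur / 60)
      if (n_art == 0L || amp == 0) return(data)
      starts <- sort(round(stats::runif(n_art, 1, n - length(tmpl))))
      wav <- numeric(n)
      for (s0 in starts) {
        idx <- s0:(s0 + length(tmpl) - 1L)
        wav[idx] <- wav[idx] + tmpl
      }
      data[eog, ] <- data[eog, ] + amp * wav
      data[1:64, ] <- data[1:64, ] + (amp * gains) %o% wav
      data
    }
    blink_tmpl <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = round(0.3 * fs))))
    sacc_len <- round(0.2 * fs)
    sacc_tmpl <- c(seq(0, 1, length.out = round(sacc_len / 4)),
                   rep(1, sacc_len - 2 * round(sacc_len / 4)),
                   seq(1, 0, length.out = round(sacc_len / 4)))
    data <- add_artifacts(data, noise$blink_rate, noise$blink_amplitude,
                          blink_tmpl, "VEOG", blink_coupling())
    data <- add_artifacts(data, noise$saccade_rate,
                          noise$saccade_amplitude * sample(c(-1, 1), 1L),
                          sacc_tmpl, "HEOG", saccade_coupling())
    events <- data.frame(sample = ev_sample,
                         onset_s = seq$onset_s + pad,
                         stream = seq$stream,
                         stimulus_id = seq$stimulus_id,
                         role = seq$role, label = seq$label, tag = seq$tag,
                         trial_index = plan$trial_index,
                         run_index = plan$run_index,
                         stringsAsFactors = FALSE)
    structure(list(data = data, sampling_rate = fs, channel_names = ch,
                   events = events, run_index = plan$run_index,
                   ground_truth = list(components = components, plan = plan,
                                       noise = noise, seed = seed)),
              class = "eeg_recording")
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz, %d events, run %d\n",
              nrow(x$data), ncol(x$data), x$sampling_rate, nrow(x$events),
              x$run_index))
  invisible(x)
}

# Concatenate per-trial recordings into one run.
concat_recordings <- function(recs, run_index = 1L) {
  stopifnot(length(recs) >= 1L)
  fs <- recs[[1L]]$sampling_rate
  offs <- cumsum(c(0L, vapply(recs, function(r) ncol(r$data), 0L)))
  data <- do.call(cbind, lapply(recs, `[[`, "data"))
  events <- do.call(rbind, lapply(seq_along(recs), function(i) {
    e <- recs[[i]]$events
    e$sample <- e$sample + offs[i]
    e$onset_s <- e$onset_s + offs[i] / fs
    e
  }))
  events$run_index <- run_index
  structure(list(data = data, sampling_rate = fs,
                 channel_names = recs[[1L]]$channel_names, events = events,
                 run_index = run_index,
                 ground_truth = lapply(recs, `[[`, "ground_truth")),
            class = "eeg_recording")
}

#' Simulate analysis-ready epochs directly
#'
#' Generates an `epoch_set` as the analysis chain would see it, without the
#' continuous acquisition detour: per channel, a continuous 1/f^alpha noise
#' stream is band-pass filtered (zero-phase) and sliced into epochs at a
#' fixed spacing, the injected component kernels (times their topography)
#' are added, and the pre-stimulus baseline is subtracted. Intended for
#' estimator validation against known ground truth; the continuous
#' [simulate_recording()] path exercises the full pipeline instead.
#'
#' @param n_epochs number of epochs.
#' @param components list of [erp_component()]s injected into every epoch.
#' @param channels channel subset to synthesise (default the P300 set).
#' @param background_sd broadband noise SD in microvolts.
#' @param spectral_exponent 1/f exponent.
#' @param band analysis band in Hz applied to the noise.
#' @param fs sampling rate (default 250).
#' @param window epoch window in seconds.
#' @param spacing epoch spacing in the underlying noise stream, seconds.
#' @param label epoch label attached to every epoch.
#' @param seed RNG seed.
#' @return an `epoch_set`.
#' @export
simulate_epochs <- function(n_epochs, components = list(),
                            channels = c("Fz", "FCz", "Cz", "CPz", "Pz"),
                            background_sd = 2, spectral_exponent = 1,
                            band = c(1, 40), fs = 250, window = c(-0.1, 1.2),
                            spacing = 4, label = "target", seed = 1L) {
  nt <- round((window[2L] - window[1L]) * fs)
  times <- seq(window[1L], by = 1 / fs, length.out = nt)
  n_pre <- sum(times < 0)
  sig <- matrix(0, length(channels), nt)
  for (cm in components) {
    kern <- make_component_waveform(cm, fs, window[2L])
    drive <- c(numeric(n_pre), kern)[seq_len(nt)]
    sig <- sig + cm$topography[channels] %o% drive
  }
  n_cont <- n_epochs * round(spacing * fs) + nt
  starts <- (seq_len(n_epochs) - 1L) * round(spacing * fs) + 1L
  with_seed(seed, {
    eps <- array(0, c(n_epochs, length(channels), nt))
    for (c_i in seq_along(channels)) {
      nz <- if (background_sd > 0)
        filter_zero_phase(pink_noise(n_cont, spectral_exponent) * background_sd,
                          fs, band, "pass")
      else numeric(n_cont)
      for (i in seq_len(n_epochs))
        eps[i, c_i, ] <- sig[c_i, ] + nz[starts[i]:(starts[i] + nt - 1L)]
    }
    M <- matrix(eps, n_epochs * length(channels), nt)
    M <- M - rowMeans(M[, times < 0, drop = FALSE])
    structure(list(epochs = array(M, dim(eps)), times = times,
                   sampling_rate = fs, channel_names = channels,
                   labels = data.frame(label = rep(label, n_epochs),
                                       stringsAsFactors = FALSE),
                   band = band),
              class = "epoch_set")
  })
}

#' Simulate a full multi-run session
#'
#' Replicates the session layout of the replication design: `n_runs` runs of
#' `trials_per_run` trials each; within a run, each of the four attention
#' targets (deviant classes) is used once, in seed-dependent order. Per-trial
#' seeds are derived deterministically from the master seed.
#'
#' @param paradigm an [asme_paradigm()] (or paradigm name).
#' @param preset "default" (moderate SNR), "high-snr", or "no-signal"
#'   (noise and artifacts only, no ERP components); ignored when
#'   `components` is given.
#' @param n_runs,trials_per_run session layout (defaults 6 and 4).
#' @param components optional explicit list of [erp_component()]s.
#' @param noise optional [noise_spec()] override.
#' @param fs sampling rate, Hz.
#' @param master_seed master integer seed.
#' @return object of class `asme_session`: list with `paradigm`, `runs`
#'   (list of `eeg_recording`), `plans` (data.frame: run_index, trial_index,
#'   target_stream, target_stimulus_id, class), `fs`, `master_seed`.
#' @export
simulate_session <- function(paradigm, preset = c("default", "high-snr",
                                                  "no-signal"),
                             n_runs = 6L, trials_per_run = 4L,
                             components = NULL, noise = NULL, fs = 1000,
                             master_seed = 1L) {
  preset <- match.arg(preset)
  if (is.character(paradigm)) paradigm <- asme_paradigm(paradigm)
  stopifnot(inherits(paradigm, "asme_paradigm"),
            !is.null(paradigm$classes))
  if (is.null(components))
    components <- switch(preset,
      "default"  = default_erp_components(paradigm$name),
      "high-snr" = default_erp_components(paradigm$name),
      "no-signal" = list())
  if (is.null(noise))
    noise <- switch(preset,
      "default"   = noise_spec(),
      "high-snr"  = noise_spec(background_sd = 1),
      "no-signal" = noise_spec())
  classes <- paradigm$classes
  plans <- list(); runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    order_r <- with_seed(derive_seed(master_seed, r, 0L),
                         sample(rep_len(classes$class, trials_per_run)))
    trials <- vector("list", trials_per_run)
    for (tr in seq_len(trials_per_run)) {
      cls <- order_r[tr]
      plan <- trial_plan(classes$stream[classes$class == cls],
                         classes$stimulus_id[classes$class == cls],
                         trial_index = tr, run_index = r)
      sd_tr <- derive_seed(master_seed, r, tr)
      sq <- build_sequence(paradigm, sd_tr)
      trials[[tr]] <- simulate_recording(sq, plan, components, noise,
                                         fs = fs, seed = sd_tr + 1L)
      plans[[length(plans) + 1L]] <-
        data.frame(run_index = r, trial_index = tr,
                   target_stream = plan$target_stream,
                   target_stimulus_id = plan$target_stimulus_id,
                   class = cls, stringsAsFactors = FALSE)
    }
    runs[[r]] <- concat_recordings(trials, run_index = r)
  }
  structure(list(paradigm = paradigm, runs = runs,
                 plans = do.call(rbind, plans), fs = fs,
                 master_seed = as.integer(master_seed)),
            class = "asme_session")
}

#' @export
print.asme_session <- function(x, ...) {
  cat(sprintf("<asme_session> %s: %d runs x %d trials @ %g Hz (master seed %d)\n",
              x$paradigm$name, length(x$runs),
              max(x$plans$trial_index), x$fs, x$master_seed))
  invisible(x)
}
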