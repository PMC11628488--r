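#' Whole-session ERP analysis
#'
#' Fits the EOG remover on all runs, cleans and epochs the session with the
#' ERP band (1-40 Hz), and computes the signed-r2 discriminability map plus
#' the bootstrap P300 peak amplitude (target epochs) and onset latency
#' (target vs standard epochs).
#'
#' @param session an `asme_session`.
#' @param fs_out epoch sampling rate (default 250).
#' @param seed seed for ICA and the bootstrap estimators.
#' @return list with `epochs`, `signed_r2`, `amplitude`
#'   (`p300_amplitude`), `latency` (`p300_latency`) and `remover`.
#' @export
run_erp_analysis <- function(session, fs_out = 250, seed = 1L,
                             ica_max_iter = 100L) {
  cont <- highpass_and_concatenate(session$runs)
  remover <- fit_eog_remover(cont, seed = seed, max_iter = ica_max_iter)
  eps <- make_epochs(apply_eog_remover(remover, cont), band = c(1, 40),
                     fs_out = fs_out)
  r2 <- signed_r2_map(eps)
  target <- subset_epochs(eps, eps$labels$label == "target")
  standard <- subset_epochs(eps, eps$labels$role == "standard")
  amp <- estimate_peak_amplitude(target, seed = derive_seed(seed, 1L))
  lat <- estimate_onset_latency(target, standard,
                                seed = derive_seed(seed, 2L))
  list(epochs = eps, signed_r2 = r2, amplitude = amp, latency = lat,
       remover = remover)
}

#' Run the full synthetic replication pipeline
#'
#' Simulates a session per paradigm, then runs preprocessing, ERP analysis
#' (signed-r2, bootstrap amplitude/latency), binary AUC decoding and the
#' four-class BCI simulation with ITR and binomial significance threshold.
#' All randomness derives from `master_seed`; identical seeds give an
#' identical report.
#'
#' @param paradigms paradigm names to replicate.
#' @param preset synthetic signal preset ("default", "high-snr",
#'   "no-signal").
#' @param n_stimuli_per_trial optional reduced trial length (named list or
#'   single value); `NULL` uses each paradigm's standard count.
#' @param n_runs,trials_per_run session layout.
#' @param fs synthesis sampling rate, Hz.
#' @param fs_out epoch sampling rate, Hz.
#' @param master_seed master integer seed.
#' @param out optional path: writes the report as JSON.
#' @return object of class `replication_report`: per-paradigm list with
#'   `accuracy`, `threshold`, `itr`, `mean_auc`, `p300_amplitude`,
#'   `p300_latency`, `n_failed`, plus the layout and seed.
#' @export
run_replication <- function(paradigms = c("asme4stream", "asme2stream"),
                            preset = "default", n_stimuli_per_trial = NULL,
                            n_runs = 6L, trials_per_run = 4L, fs = 1000,
                            fs_out = 250, master_seed = 1L, out = NULL) {
  res <- list()
  for (pname in paradigms) {
    nst <- if (is.list(n_stimuli_per_trial)) n_stimuli_per_trial[[pname]]
           else n_stimuli_per_trial
    cfg <- asme_paradigm(pname, n_stimuli_per_trial = nst)
    session <- simulate_session(cfg, preset = preset, n_runs = n_runs,
                                trials_per_run = trials_per_run, fs = fs,
                                master_seed = derive_seed(master_seed,
                                                          match(pname, paradigms)))
    erp <- run_erp_analysis(session, fs_out = fs_out,
                            seed = derive_seed(master_seed, 11L))
    bin <- run_binary_analysis(session, fs_out = fs_out,
                               seed = derive_seed(master_seed, 12L))
    sim <- run_bci_simulation(session, fs_out = fs_out,
                              seed = derive_seed(master_seed, 13L))
    res[[pname]] <- list(
      paradigm = pname,
      accuracy = sim$accuracy,
      n_predictions = sim$n_predictions,
      n_trials = sim$n_trials,
      threshold = sim$threshold$threshold_2dp,
      significant = sim$accuracy > sim$threshold$threshold,
      itr_bits_per_trial = sim$itr$R,
      itr_bits_per_min = sim$itr$B,
      mean_auc = bin$auc$mean_auc,
      p300_amplitude_uv = erp$amplitude$estimate,
      p300_latency_s = erp$latency$estimate,
      latency_n_failed = erp$latency$n_failed)
  }
  report <- structure(list(paradigms = res, preset = preset,
                           n_runs = n_runs, trials_per_run = trials_per_run,
                           fs = fs, master_seed = master_seed),
                      class = "replication_report")
  if (!is.null(out))
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  report
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf("<replication_report> preset '%s', %d runs x %d trials, master seed %d\n",
              x$preset, x$n_runs, x$trials_per_run, x$master_seed))
  for (p in x$paradigms) {
    cat(sprintf("  %s:\n", p$paradigm))
    cat(sprintf("    4-class accuracy %.3f (P_th %.2f, %s), ITR %.3f bits/min\n",
                p$accuracy, p$threshold,
                if (p$significant) "significant" else "not significant",
                p$itr_bits_per_min))
    cat(sprintf("    binary mean AUC %.3f; P300 %.2f uV, onset %s\n",
                p$mean_auc, p$p300_amplitude_uv,
                if (is.na(p$p300_latency_s)) "undefined"
                else sprintf("%.3f s", p$p300_latency_s)))
  }
  invisible(x)
}
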