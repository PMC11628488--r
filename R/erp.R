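#' Band-pass filter, epoch and downsample continuous data
#'
#' EEG channels are band-pass filtered (zero-phase Butterworth, designed
#' order 2), cut into epochs around every event marker, and downsampled to
#' `fs_out` by integer decimation. The band-pass acts as the anti-alias
#' filter whenever its upper edge is below the output Nyquist rate; an
#' additional zero-phase low-pass is applied otherwise. The epoch window is
#' half-open `[window[1], window[2])`: 1300 samples at 1000 Hz, 325 after
#' decimation to 250 Hz.
#'
#' Events whose window falls outside the recording are dropped and counted
#' in the `n_dropped` attribute, never silently.
#'
#' @param cont a `continuous_eeg`.
#' @param band band edges in Hz, e.g. `c(1, 40)` for ERP analysis or
#'   `c(0.1, 8)` for classification features.
#' @param window epoch window in seconds relative to stimulus onset.
#' @param fs_out output sampling rate; `sampling_rate / fs_out` must be a
#'   whole number.
#' @param baseline if `TRUE` (default), subtract the pre-stimulus mean
#'   (`window[1]` to 0) per epoch and channel.
#' @param select optional predicate over the event data.frame restricting
#'   which events are epoched (e.g. deviants only).
#' @return object of class `epoch_set`: list with `epochs`
#'   (n_epochs x n_channels x n_times array, EEG channels only), `times`
#'   (s), `sampling_rate`, `channel_names`, `labels` (per-epoch event rows)
#'   and `band`.
#' @export
make_epochs <- function(cont, band = c(1, 40), window = c(-0.1, 1.2),
                        fs_out = 250, baseline = TRUE, select = NULL) {
  stopifnot(inherits(cont, "continuous_eeg"))
  fs <- cont$sampling_rate
  k <- fs / fs_out
  if (abs(k - round(k)) > 1e-9)
    stop("sampling_rate / fs_out must be an integer decimation factor",
         call. = FALSE)
  k <- as.integer(round(k))
  ch <- cont$channel_names
  eeg_rows <- which(!ch %in% c("VEOG", "HEOG"))
  if (isTRUE(attr(cont, "prefiltered"))) {
    d <- cont$data[eeg_rows, , drop = FALSE]
  } else {
    d <- filter_rows(cont$data[eeg_rows, , drop = FALSE], fs, band,
                     type = "pass", order = 2L)
    if (band[2L] > fs_out / 2 && k > 1L)
      d <- filter_rows(d, fs, 0.4 * fs_out, type = "low", order = 4L)
  }
  offs <- seq(round(window[1L] * fs), round(window[2L] * fs) - 1L, by = k)
  times <- offs / fs
  n_samp <- ncol(d)
  ev <- cont$events
  if (!is.null(select)) ev <- ev[select(ev), , drop = FALSE]
  ok <- ev$sample + offs[1L] >= 1L & ev$sample + offs[length(offs)] <= n_samp
  n_dropped <- sum(!ok)
  ev <- ev[ok, , drop = FALSE]
  n_ep <- nrow(ev)
  nch <- length(eeg_rows)
  nt <- length(offs)
  epochs <- array(0, dim = c(n_ep, nch, nt))
  if (n_ep > 0L) {
    idx <- as.vector(outer(ev$sample, offs, "+"))   # (epoch, time) pairs
    tmp <- matrix(0, n_ep * nt, nch)                # (epoch, time) x channel
    for (c_i in seq_len(nch)) tmp[, c_i] <- d[c_i, idx]
    epochs <- aperm(array(tmp, c(n_ep, nt, nch)), c(1L, 3L, 2L))
    if (baseline) {
      pre <- which(times < 0)
      if (length(pre) > 0L) {
        M <- matrix(epochs, n_ep * nch, nt)         # (epoch, channel) x time
        M <- M - rowMeans(M[, pre, drop = FALSE])
        epochs <- array(M, c(n_ep, nch, nt))
      }
    }
  }
  rownames(ev) <- NULL
  structure(list(epochs = epochs, times = times, sampling_rate = fs_out,
                 channel_names = ch[eeg_rows], labels = ev, band = band),
            class = "epoch_set", n_dropped = n_dropped)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d ch x %d samples @ %g Hz, band %g-%g Hz\n",
              dim(x$epochs)[1L], dim(x$epochs)[2L], dim(x$epochs)[3L],
              x$sampling_rate, x$band[1L], x$band[2L]))
  if (nrow(x$labels) > 0L && "label" %in% names(x$labels))
    cat(sprintf("  labels: %s\n",
                paste(sprintf("%s=%d", names(table(x$labels$label)),
                              as.integer(table(x$labels$label))),
                      collapse = ", ")))
  invisible(x)
}

#' Subset an epoch set
#'
#' @param eps an `epoch_set`.
#' @param i logical or integer epoch selector (evaluated against
#'   `eps$labels` rows).
#' @param channels optional channel-name subset.
#' @return an `epoch_set`.
#' @export
subset_epochs <- function(eps, i = NULL, channels = NULL) {
  out <- eps
  if (!is.null(i)) {
    out$epochs <- eps$epochs[i, , , drop = FALSE]
    out$labels <- eps$labels[i, , drop = FALSE]
  }
  if (!is.null(channels)) {
    missing_ch <- setdiff(channels, out$channel_names)
    if (length(missing_ch) > 0L)
      stop("channels not in montage: ", paste(missing_ch, collapse = ", "),
           call. = FALSE)
    ci <- match(channels, out$channel_names)
    out$epochs <- out$epochs[, ci, , drop = FALSE]
    out$channel_names <- channels
  }
  out
}

#' Grand-average ERP
#'
#' Arithmetic mean over the selected epochs.
#'
#' @param eps an `epoch_set`.
#' @param selector logical/integer epoch selector, or a predicate function
#'   of the labels data.frame; `NULL` averages everything.
#' @return channels x times matrix with the time axis as attribute.
#' @export
grand_average <- function(eps, selector = NULL) {
  sel <- if (is.null(selector)) rep(TRUE, dim(eps$epochs)[1L])
         else if (is.function(selector)) selector(eps$labels)
         else selector
  sub <- eps$epochs[sel, , , drop = FALSE]
  if (dim(sub)[1L] == 0L) stop("empty epoch selection", call. = FALSE)
  avg <- apply(sub, c(2L, 3L), mean)
  dimnames(avg) <- list(eps$channel_names, NULL)
  attr(avg, "times") <- eps$times
  avg
}

#' Signed-r2 discriminability map
#'
#' For every (channel, time) point, the point-biserial Pearson correlation
#' `r` between the amplitude and the binary target/nontarget label is
#' computed, and `sign(r) * r^2` returned. Points with zero amplitude
#' variance are set to 0. Values lie in `[-1, 1]`; swapping the label
#' polarity flips every sign.
#'
#' @param eps an `epoch_set` whose labels contain both classes.
#' @param positive label value treated as the positive class
#'   (default "target").
#' @return object of class `signed_r2`: channels x times matrix.
#' @export
signed_r2_map <- function(eps, positive = "target") {
  y <- as.numeric(eps$labels$label == positive)
  if (length(unique(y)) < 2L)
    stop("both binary labels must be present", call. = FALSE)
  n <- length(y)
  dm <- dim(eps$epochs)
  M <- matrix(eps$epochs, n)              # columns: (channel, time) pairs
  yc <- y - mean(y)
  xc <- sweep(M, 2L, colMeans(M))
  sx <- sqrt(colSums(xc^2))
  r <- as.numeric(crossprod(xc, yc)) / (sx * sqrt(sum(yc^2)))
  r[!is.finite(r)] <- 0
  # M's columns vary channel fastest, so refold channel-major
  vals <- matrix(sign(r) * r^2, nrow = dm[2L])
  dimnames(vals) <- list(eps$channel_names, NULL)
  structure(vals, times = eps$times, class = c("signed_r2", "matrix"))
}

# Default P300 channel set. The conventional printed midline quintet lists
# FPz, which does not exist on this 64-channel montage (Fp1/Fp2 only); CPz
# is used in its place and any channel list can be supplied via `channels`.
p300_channels <- function() c("Fz", "FCz", "Cz", "CPz", "Pz")

#' Bootstrap estimate of P300 peak amplitude
#'
#' Each replicate draws 80% of the target epochs without replacement,
#' averages them, and takes the maximum over the configured channels and
#' the 0.2-0.5 s window (the spatiotemporal peak). The estimate is the mean
#' of the replicate peaks.
#'
#' @param target_eps `epoch_set` of target-stimulus epochs.
#' @param channels channel subset (default Fz, FCz, Cz, CPz, Pz).
#' @param window peak-search window in seconds.
#' @param n_boot number of bootstrap replicates (default 1200).
#' @param resample_fraction fraction drawn per replicate (default 0.8).
#' @param seed RNG seed.
#' @return object of class `p300_amplitude`: list with `estimate`
#'   (microvolts), `samples` (the replicate vector), and the settings.
#' @export
estimate_peak_amplitude <- function(target_eps, channels = p300_channels(),
                                    window = c(0.2, 0.5), n_boot = 1200L,
                                    resample_fraction = 0.8, seed = 1L) {
  eps <- subset_epochs(target_eps, channels = channels)
  n <- dim(eps$epochs)[1L]
  if (n < 2L)
    stop("at least 2 target epochs are required", call. = FALSE)
  wi <- which(eps$times >= window[1L] & eps$times <= window[2L])
  M <- matrix(eps$epochs[, , wi, drop = FALSE], n)   # n x (ch*time)
  m <- max(1L, round(resample_fraction * n))
  v <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    max(colMeans(M[sample.int(n, m), , drop = FALSE]))
  }, 0))
  structure(list(estimate = mean(v), samples = v, n_boot = n_boot,
                 resample_fraction = resample_fraction, window = window,
                 channels = channels, seed = seed),
            class = "p300_amplitude")
}

#' @export
plot.signed_r2 <- function(x, ...) {
  times <- attr(x, "times")
  graphics::image(times, seq_len(nrow(x)), t(unclass(x)),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  zlim = c(-1, 1) * max(abs(x), 1e-12),
                  xlab = "time (s)", ylab = "channel",
                  main = "signed r^2 (target vs nontarget)", ...)
  invisible(x)
}

#' @export
plot.p300_amplitude <- function(x, ...) {
  graphics::hist(x$samples, breaks = 30,
                 xlab = expression(paste("bootstrap peak (", mu, "V)")),
                 main = sprintf("P300 peak amplitude: %.2f uV", x$estimate),
                 ...)
  graphics::abline(v = x$estimate, lwd = 2)
  invisible(x)
}

#' @export
print.p300_amplitude <- function(x, ...) {
  cat(sprintf("P300 peak amplitude: %.3f uV (bootstrap, %d replicates, %g-%g s, channels %s)\n",
              x$estimate, x$n_boot, x$window[1L], x$window[2L],
              paste(x$channels, collapse = "/")))
  invisible(x)
}

# Vectorised one-sided Welch t-test p-values (greater) per column of A vs B.
welch_p_greater <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2L, stats::var) / na
  vb <- apply(B, 2L, stats::var) / nb
  se2 <- va + vb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- stats::pt(t, df, lower.tail = FALSE)
  zero <- se2 == 0
  p[zero] <- ifelse(ma[zero] > mb[zero], 0, 1)
  p
}

#' Bootstrap estimate of P300 onset latency
#'
#' Each replicate draws 80% of the target and of the standard epochs
#' (without replacement), averages the configured channels into one virtual
#' channel per epoch, and runs a one-sided Welch t-test (target > standard)
#' at every time point. The replicate's latency is the first time in the
#' 0.2-0.5 s window where `p < alpha`; replicates with no significant time
#' point are discarded and counted in `n_failed`. The estimate is the mean
#' of the retained latencies; if every replicate fails the estimate is
#' `NA` (undefined), not an error.
#'
#' @param target_eps,standard_eps `epoch_set`s on the same time grid.
#' @param channels channel subset averaged into the test feature.
#' @param window latency window in seconds.
#' @param n_boot number of replicates (default 250).
#' @param alpha per-time-point significance level (default 0.05).
#' @param resample_fraction fraction drawn per replicate.
#' @param seed RNG seed.
#' @return object of class `p300_latency`: `estimate` (s or `NA`),
#'   `samples` (retained latencies), `n_failed`, and the settings.
#' @export
estimate_onset_latency <- function(target_eps, standard_eps,
                                   channels = p300_channels(),
                                   window = c(0.2, 0.5), n_boot = 250L,
                                   alpha = 0.05, resample_fraction = 0.8,
                                   seed = 1L) {
  stopifnot(isTRUE(all.equal(target_eps$times, standard_eps$times)))
  te <- subset_epochs(target_eps, channels = channels)
  se <- subset_epochs(standard_eps, channels = channels)
  if (dim(te$epochs)[1L] < 2L || dim(se$epochs)[1L] < 2L)
    stop("both epoch sets must contain at least 2 epochs", call. = FALSE)
  # channel-mean virtual channel: n x n_times
  A <- apply(te$epochs, c(1L, 3L), mean)
  B <- apply(se$epochs, c(1L, 3L), mean)
  times <- te$times
  wi <- which(times >= window[1L] & times <= window[2L])
  na <- nrow(A); nb <- nrow(B)
  ma <- max(1L, round(resample_fraction * na))
  mb <- max(1L, round(resample_fraction * nb))
  lat <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    p <- welch_p_greater(A[sample.int(na, ma), wi, drop = FALSE],
                         B[sample.int(nb, mb), wi, drop = FALSE])
    hit <- which(p < alpha)
    if (length(hit) == 0L) NA_real_ else times[wi[hit[1L]]]
  }, 0))
  ok <- !is.na(lat)
  structure(list(estimate = if (any(ok)) mean(lat[ok]) else NA_real_,
                 samples = lat[ok], n_failed = sum(!ok), n_boot = n_boot,
                 alpha = alpha, window = window, channels = channels,
                 resample_fraction = resample_fraction, seed = seed),
            class = "p300_latency")
}

#' @export
print.p300_latency <- function(x, ...) {
  if (is.na(x$estimate))
    cat(sprintf("P300 onset latency: undefined (all %d bootstrap replicates failed)\n",
                x$n_boot))
  else
    cat(sprintf("P300 onset latency: %.3f s (bootstrap, %d/%d replicates retained)\n",
                x$estimate, x$n_boot - x$n_failed, x$n_boot))
  invisible(x)
}
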