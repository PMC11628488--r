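#' High-pass filter runs and concatenate them in time
#'
#' Each run's EEG channels are independently high-pass filtered (zero-phase
#' forward-backward Butterworth, designed order 2, cutoff 1 Hz) to remove
#' slow drift, then the runs are concatenated along the time axis. EOG
#' channels are carried through unfiltered here; they are band-pass filtered
#' separately when the EOG remover is fitted.
#'
#' @param recordings list of `eeg_recording` objects (or a single one) with
#'   identical channel sets and sampling rates.
#' @param cutoff high-pass cutoff in Hz.
#' @return object of class `continuous_eeg`: list with `data`
#'   (66 x samples), `sampling_rate`, `channel_names`, `run_boundaries`
#'   (cumulative end sample of each run) and `events`.
#' @export
highpass_and_concatenate <- function(recordings, cutoff = 1.0) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1L)
  ch <- recordings[[1L]]$channel_names
  fs <- recordings[[1L]]$sampling_rate
  for (r in recordings) {
    if (!identical(r$channel_names, ch))
      stop("recordings have mismatched channel sets", call. = FALSE)
    if (r$sampling_rate != fs)
      stop("recordings have mismatched sampling rates", call. = FALSE)
  }
  eeg_rows <- which(!ch %in% c("VEOG", "HEOG"))
  filtered <- lapply(recordings, function(r) {
    d <- r$data
    d[eeg_rows, ] <- filter_rows(d[eeg_rows, , drop = FALSE], fs, cutoff,
                                 type = "high", order = 2L)
    d
  })
  lens <- vapply(filtered, ncol, 0L)
  offs <- cumsum(c(0L, lens))
  events <- do.call(rbind, lapply(seq_along(recordings), function(i) {
    e <- recordings[[i]]$events
    e$sample <- e$sample + offs[i]
    e
  }))
  structure(list(data = do.call(cbind, filtered), sampling_rate = fs,
                 channel_names = ch, run_boundaries = cumsum(lens),
                 events = events),
            class = "continuous_eeg")
}

#' Wrap a recording as continuous data without filtering
#'
#' Useful for analyses on synthetic data where the drift-removal high-pass
#' is not wanted (e.g. estimator validation against noiseless ground
#' truth). `prefiltered = TRUE` additionally marks the data so that
#' [make_epochs()] skips its band-pass.
#'
#' @param rec an `eeg_recording`.
#' @param prefiltered mark the data as already filtered.
#' @return a `continuous_eeg`.
#' @export
as_continuous <- function(rec, prefiltered = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  structure(list(data = rec$data, sampling_rate = rec$sampling_rate,
                 channel_names = rec$channel_names,
                 run_boundaries = ncol(rec$data), events = rec$events),
            class = "continuous_eeg", prefiltered = prefiltered)
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("<continuous_eeg> %d ch x %d samples @ %g Hz, %d run(s), %d events\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              length(x$run_boundaries), nrow(x$events)))
  invisible(x)
}

# Symmetric-decorrelation FastICA with the logcosh (tanh) contrast on
# whitened data Z (components x samples). Returns the orthogonal unmixing
# matrix W (sources = W %*% Z).
fastica_core <- function(Z, tol = 1e-4, max_iter = 1000L) {
  k <- nrow(Z); n <- ncol(Z)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(matrix(stats::rnorm(k * k), k))
  it <- 0L; conv <- Inf
  while (it < max_iter) {
    it <- it + 1L
    U <- W %*% Z
    G <- tanh(U)
    W1 <- G %*% t(Z) / n - diag(rowMeans(1 - G^2), k) %*% W
    W1 <- sym_decorrelate(W1)
    conv <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (conv < tol) break
  }
  list(W = W, n_iter = it, converged = conv < tol, tol = tol)
}

#' Fit an EOG artifact remover (PCA + FastICA + correlation zeroing)
#'
#' PCA reduces the 64 EEG channels to `n_components` principal components
#' (descending explained variance, whitened), FastICA (logcosh contrast,
#' symmetric decorrelation) unmixes them into independent components, and
#' for each EOG channel (band-pass filtered 1-10 Hz, zero-phase) the IC with
#' the highest absolute Pearson correlation is marked for zeroing. The
#' absolute value is used because an IC's sign is arbitrary. If both EOG
#' channels select the same IC the zeroed set has one element.
#'
#' @param cont a [highpass_and_concatenate()] result (training data only).
#' @param n_components number of principal components (default 15).
#' @param seed seed for the FastICA initialisation.
#' @param max_iter,tol FastICA stopping parameters.
#' @param strict if `TRUE`, non-convergence of FastICA raises an error
#'   carrying the iteration count; default warns and proceeds with the last
#'   iterate (the zeroing procedure remains well defined).
#' @return object of class `eog_remover`: centering vector, PCA basis and
#'   variances, ICA unmixing/mixing matrices, zeroed IC indices and the
#'   per-IC/per-EOG correlation table.
#' @export
fit_eog_remover <- function(cont, n_components = 15L, seed = 1L,
                            max_iter = 1000L, tol = 1e-4, strict = FALSE) {
  stopifnot(inherits(cont, "continuous_eeg"))
  ch <- cont$channel_names
  if (!all(c("VEOG", "HEOG") %in% ch))
    stop("both EOG channels (VEOG, HEOG) are required", call. = FALSE)
  eeg_rows <- which(!ch %in% c("VEOG", "HEOG"))
  if (length(eeg_rows) < 64L)
    stop("at least 64 EEG channels are required", call. = FALSE)
  X <- cont$data[eeg_rows, , drop = FALSE]
  mu <- rowMeans(X)
  Xc <- X - mu
  n <- ncol(Xc)
  C <- tcrossprod(Xc) / (n - 1)
  e <- eigen(C, symmetric = TRUE)
  V <- e$vectors[, seq_len(n_components), drop = FALSE]
  d <- pmax(e$values[seq_len(n_components)], 1e-12 * e$values[1L])
  Z <- (t(V) %*% Xc) / sqrt(d)          # whitened PC scores
  ica <- with_seed(seed, fastica_core(Z, tol = tol, max_iter = max_iter))
  if (!ica$converged) {
    msg <- sprintf("FastICA did not reach tol %g within %d iterations",
                   tol, ica$n_iter)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  S <- ica$W %*% Z
  eog <- cont$data[c(which(ch == "VEOG"), which(ch == "HEOG")), ,
                   drop = FALSE]
  fs <- cont$sampling_rate
  eog_f <- filter_rows(eog, fs, c(1, 10), type = "pass", order = 2L)
  cors <- t(apply(eog_f, 1L, function(v) as.numeric(stats::cor(t(S), v))))
  rownames(cors) <- c("VEOG", "HEOG")
  picked <- apply(abs(cors), 1L, which.max)
  zeroed <- sort(unique(unname(picked)))
  structure(list(center = mu, pca_basis = V, pca_var = d,
                 ica_unmixing = ica$W, ica_mixing = t(ica$W),
                 zeroed_ics = zeroed,
                 selection = data.frame(
                   eog = c("VEOG", "HEOG"), ic = unname(picked),
                   r = cors[cbind(1:2, picked)]),
                 correlations = cors,
                 n_components = n_components, sampling_rate = fs,
                 n_iter = ica$n_iter, converged = ica$converged,
                 eeg_rows = eeg_rows, channel_names = ch, seed = seed),
            class = "eog_remover")
}

#' @export
print.eog_remover <- function(x, ...) {
  cat(sprintf("<eog_remover> %d PCs -> FastICA (%s after %d iter)\n",
              x$n_components,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  for (i in seq_len(nrow(x$selection)))
    cat(sprintf("  %s -> IC %d (r = %+.3f)%s\n", x$selection$eog[i],
                x$selection$ic[i], x$selection$r[i],
                if (x$selection$ic[i] %in% x$zeroed_ics) " [zeroed]" else ""))
  invisible(x)
}

#' Remove the fitted EOG components from continuous data
#'
#' Projects the EEG onto the fitted PCA/ICA basis, zeroes the selected
#' independent components, and subtracts the back-projection. The operation
#' is an idempotent oblique projection; the non-zeroed subspace is
#' unchanged. EOG channels are untouched. The remover may be fitted on
#' training runs and applied to held-out runs.
#'
#' @param model an [fit_eog_remover()] object.
#' @param cont a `continuous_eeg` with the same channel set.
#' @return a `continuous_eeg` with cleaned EEG.
#' @export
apply_eog_remover <- function(model, cont) {
  stopifnot(inherits(model, "eog_remover"), inherits(cont, "continuous_eeg"))
  if (!identical(cont$channel_names, model$channel_names))
    stop("channel set does not match the fitted remover", call. = FALSE)
  out <- cont
  J <- model$zeroed_ics
  if (length(J) == 0L) return(out)
  X <- cont$data[model$eeg_rows, , drop = FALSE]
  Xc <- X - model$center
  Z <- (t(model$pca_basis) %*% Xc) / sqrt(model$pca_var)
  SJ <- model$ica_unmixing[J, , drop = FALSE] %*% Z
  removed <- (model$pca_basis %*%
                (sqrt(model$pca_var) * model$ica_mixing[, J, drop = FALSE])) %*% SJ
  out$data[model$eeg_rows, ] <- X - removed
  out
}
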