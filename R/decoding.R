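#' Interval-mean classification features
#'
#' Per epoch and EEG channel, the mean amplitudes in ten non-overlapping
#' 0.1 s intervals from 0 to 1.0 s relative to stimulus onset, concatenated
#' channel-major: 10 intervals x 64 channels = 640 dimensions.
#'
#' @param eps an `epoch_set` built with the classification band (0.1-8 Hz)
#'   and the standard window (must cover 0 to 1.0 s post-onset).
#' @param n_intervals number of intervals (default 10).
#' @param interval_length interval length in seconds (default 0.1).
#' @return object of class `feature_set`: list with `X`
#'   (n_epochs x features), `y` (+1 target / -1 nontarget, when labels are
#'   present), and `info` (per-epoch label rows).
#' @export
extract_features <- function(eps, n_intervals = 10L, interval_length = 0.1) {
  stopifnot(inherits(eps, "epoch_set"))
  t_end <- n_intervals * interval_length
  if (max(eps$times) < t_end - 1e-9)
    stop("epochs end before ", t_end, " s post-onset", call. = FALSE)
  dm <- dim(eps$epochs)
  n <- dm[1L]; nch <- dm[2L]; nt <- dm[3L]
  # rows: (epoch, channel) pairs, columns: time
  M <- matrix(eps$epochs, n * nch, nt)
  X <- matrix(0, n, nch * n_intervals)
  for (k in seq_len(n_intervals)) {
    ti <- which(eps$times >= (k - 1L) * interval_length &
                eps$times < k * interval_length)
    mk <- rowMeans(M[, ti, drop = FALSE])          # length n * nch
    X[, (seq_len(nch) - 1L) * n_intervals + k] <- matrix(mk, n, nch)
  }
  y <- NULL
  if ("label" %in% names(eps$labels))
    y <- ifelse(eps$labels$label == "target", 1, -1)
  structure(list(X = X, y = y, info = eps$labels,
                 n_intervals = n_intervals, n_channels = nch),
            class = "feature_set")
}

# Ledoit-Wolf analytic shrinkage intensity toward nu * I for the pooled
# within-class scatter; Z is the class-mean-centered data (n x d).
shrinkage_intensity <- function(Z) {
  n <- nrow(Z); d <- ncol(Z)
  S <- crossprod(Z) / n
  nu <- mean(diag(S))
  sq_norms <- rowSums(Z^2)
  # sum_ij Var-hat(s_ij) = (1/n) sum_k ||z_k||^4 - ||S||_F^2, up to the
  # usual n/(n-1)^2 small-sample factor
  num <- (n / (n - 1)^2) * (sum(sq_norms^2) / n - sum(S^2))
  den <- sum((S - diag(nu, d))^2)
  if (den <= 0) return(1)
  min(1, max(0, num / den))
}

#' Fit a shrinkage-LDA binary classifier
#'
#' Linear discriminant analysis with the pooled within-class covariance
#' shrunk toward a scaled identity, `(1 - gamma) * S + gamma * nu * I`,
#' with the shrinkage intensity `gamma` estimated analytically
#' (Ledoit-Wolf). The decision function is `f(x) = w'x + b` with
#' `w = inv(S_gamma) (mu+ - mu-)` and the bias set so that `f = 0` at the
#' midpoint of the class means: `f(x) >= 0` predicts class +1 (target).
#'
#' @param feats a [extract_features()] `feature_set` (or a plain matrix,
#'   with `y` supplied).
#' @param y class labels in `{-1, +1}` (taken from `feats$y` when absent).
#' @param gamma optional fixed shrinkage intensity in `[0, 1]`; estimated
#'   analytically when `NULL`.
#' @return object of class `slda`: `w`, `b`, `gamma`, class means.
#' @export
fit_slda <- function(feats, y = NULL, gamma = NULL) {
  X <- if (inherits(feats, "feature_set")) feats$X else as.matrix(feats)
  y <- y %||% feats$y
  if (is.null(y) || !all(y %in% c(-1, 1)))
    stop("labels y in {-1, +1} are required", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  mu_p <- colMeans(X[y == 1, , drop = FALSE])
  mu_m <- colMeans(X[y == -1, , drop = FALSE])
  Z <- X
  Z[y == 1, ] <- sweep(X[y == 1, , drop = FALSE], 2L, mu_p)
  Z[y == -1, ] <- sweep(X[y == -1, , drop = FALSE], 2L, mu_m)
  g <- gamma %||% shrinkage_intensity(Z)
  if (g < 0 || g > 1) stop("gamma must lie in [0, 1]", call. = FALSE)
  d <- ncol(X)
  S <- crossprod(Z) / nrow(Z)
  nu <- mean(diag(S))
  Sg <- (1 - g) * S
  diag(Sg) <- diag(Sg) + g * nu
  w <- tryCatch(solve(Sg, mu_p - mu_m), error = function(e)
    stop("shrunk covariance is singular (n < d with gamma ~ 0); ",
         "use analytic gamma estimation", call. = FALSE))
  b <- -sum(w * (mu_p + mu_m) / 2)
  structure(list(w = as.numeric(w), b = b, gamma = g, nu = nu,
                 mu_pos = mu_p, mu_neg = mu_m, n = nrow(X), d = d),
            class = "slda")
}

#' @export
predict.slda <- function(object, newdata, type = c("decision", "class"),
                         ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "feature_set")) newdata$X else as.matrix(newdata)
  f <- as.numeric(X %*% object$w + object$b)
  if (type == "decision") f else ifelse(f >= 0, 1, -1)
}

#' @export
coef.slda <- function(object, ...) c(`(bias)` = object$b, object$w)

#' @export
print.slda <- function(x, ...) {
  cat(sprintf("<slda> %d features, n = %d, shrinkage gamma = %.4f\n",
              x$d, x$n, x$gamma))
  invisible(x)
}

#' Area under the ROC curve (rank statistic, midranks on ties)
#'
#' @param scores decision values.
#' @param y labels in `{-1, +1}`.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, y) {
  pos <- y == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)          # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary target/nontarget AUC under chronological cross-validation
#'
#' Epochs are split, in their chronological order, into `n_folds`
#' contiguous blocks; each block serves once as the test set for a
#' shrinkage-LDA trained on the remaining blocks, and the AUC of its
#' decision values is recorded. Folds missing one of the classes are
#' skipped with a warning.
#'
#' @param feats a `feature_set` with labels.
#' @param n_folds number of chronological folds (default 4).
#' @return object of class `auc_cv`: per-fold AUCs, their mean, fold
#'   boundaries.
#' @export
binary_auc_cv <- function(feats, n_folds = 4L) {
  stopifnot(inherits(feats, "feature_set"), !is.null(feats$y))
  n <- nrow(feats$X)
  fold_id <- as.integer(cut(seq_len(n), n_folds, labels = FALSE))
  aucs <- rep(NA_real_, n_folds)
  for (f in seq_len(n_folds)) {
    te <- fold_id == f
    if (length(unique(feats$y[te])) < 2L ||
        length(unique(feats$y[!te])) < 2L) {
      warning("fold ", f, " lacks a class; skipped", call. = FALSE)
      next
    }
    model <- fit_slda(feats$X[!te, , drop = FALSE], feats$y[!te])
    aucs[f] <- auc_score(predict(model, feats$X[te, , drop = FALSE]),
                         feats$y[te])
  }
  structure(list(auc = aucs, mean_auc = mean(aucs, na.rm = TRUE),
                 n_folds = n_folds, fold_id = fold_id),
            class = "auc_cv")
}

#' @export
print.auc_cv <- function(x, ...) {
  cat(sprintf("Binary AUC (%d-fold chronological CV): mean %.3f [%s]\n",
              x$n_folds, x$mean_auc,
              paste(sprintf("%.3f", x$auc), collapse = ", ")))
  invisible(x)
}

#' Information transfer rate
#'
#' Bits per trial for an `N`-class selection at accuracy `P`,
#' `R = log2 N + P log2 P + (1 - P) log2((1 - P) / (N - 1))`
#' (with the convention `0 log2 0 = 0`), and bits per minute `B = V R` for
#' a rate of `V` trials per minute.
#'
#' @param P classification accuracy in `[0, 1]`.
#' @param N number of classes (>= 2).
#' @param V trials per minute (> 0).
#' @return object of class `itr_result`: list with `N`, `P`, `V`,
#'   `R` (bits/trial) and `B` (bits/min).
#' @export
information_transfer_rate <- function(P, N, V = 1) {
  if (P < 0 || P > 1) stop("P must lie in [0, 1]", call. = FALSE)
  stopifnot(N >= 2, V > 0)
  xlog2 <- function(p) ifelse(p == 0, 0, p * log2(p))
  R <- log2(N) + xlog2(P) + (1 - P) * log2((1 - P) / (N - 1))
  if (P == 1) R <- log2(N)
  structure(list(N = N, P = P, V = V, R = R, B = V * R),
            class = "itr_result")
}

#' @export
print.itr_result <- function(x, ...) {
  cat(sprintf("ITR: %.4f bits/trial, %.4f bits/min (N = %d, P = %.3f, V = %.3f trials/min)\n",
              x$R, x$B, x$N, x$P, x$V))
  invisible(x)
}

#' Binomial significance threshold for classification accuracy
#'
#' The smallest accuracy `k/n` deemed above chance at level `alpha` under a
#' binomial null with success probability `1/n_classes`: `k` is the
#' `(1 - alpha)` quantile of `Binomial(n, 1/N)` (accuracies strictly above
#' the threshold are significant, `P(X > k) < alpha`).
#'
#' @param n_trials number of test selections.
#' @param n_classes number of classes.
#' @param alpha significance level in (0, 1).
#' @return list with `threshold` (exact fraction `k/n`), `threshold_2dp`
#'   (rounded for reporting), `k`, `n_trials`, `n_classes`, `alpha`.
#' @export
significance_threshold <- function(n_trials, n_classes = 4L, alpha = 0.05) {
  stopifnot(n_trials >= 1L)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  k <- stats::qbinom(1 - alpha, n_trials, 1 / n_classes)
  list(threshold = k / n_trials, threshold_2dp = round(k / n_trials, 2L),
       k = k, n_trials = n_trials, n_classes = n_classes, alpha = alpha)
}

#' Chronological cross-validation folds over runs
#'
#' Consecutive pairs (or `n_train`-tuples) of runs form the training set of
#' each fold; all remaining runs are the test set. With 6 runs and
#' `n_train = 2` this gives 3 folds in which every run is tested exactly
#' twice.
#'
#' @param n_runs total number of runs.
#' @param n_train training runs per fold.
#' @return list of `list(train =, test =)` run-index pairs.
#' @export
chrono_folds <- function(n_runs = 6L, n_train = 2L) {
  stopifnot(n_runs %% n_train == 0L)
  lapply(seq_len(n_runs %/% n_train), function(i) {
    tr <- ((i - 1L) * n_train + 1L):(i * n_train)
    list(train = tr, test = setdiff(seq_len(n_runs), tr))
  })
}

# Concatenate already high-passed single-run continuous objects.
concat_continuous <- function(conts) {
  lens <- vapply(conts, function(c) ncol(c$data), 0L)
  offs <- cumsum(c(0L, lens))
  events <- do.call(rbind, lapply(seq_along(conts), function(i) {
    e <- conts[[i]]$events
    e$sample <- e$sample + offs[i]
    e
  }))
  structure(list(data = do.call(cbind, lapply(conts, `[[`, "data")),
                 sampling_rate = conts[[1L]]$sampling_rate,
                 channel_names = conts[[1L]]$channel_names,
                 run_boundaries = cumsum(lens), events = events),
            class = "continuous_eeg")
}

# Shared fold preprocessing: fit the remover on the (already high-passed)
# training runs only, apply it to both sides, epoch with the
# classification band. `hp_runs` is a list of per-run continuous objects.
fold_features <- function(hp_runs, train, test, band = c(0.1, 8),
                          fs_out = 250, seed = 1L, ica_max_iter = 100L) {
  tr_cont <- concat_continuous(hp_runs[train])
  remover <- fit_eog_remover(tr_cont, seed = seed, max_iter = ica_max_iter)
  tr_eps <- make_epochs(apply_eog_remover(remover, tr_cont), band = band,
                        fs_out = fs_out)
  te_cont <- apply_eog_remover(remover, concat_continuous(hp_runs[test]))
  # only deviant epochs enter the trial-level decision rule
  te_eps <- make_epochs(te_cont, band = band, fs_out = fs_out,
                        select = function(e) e$role != "standard")
  list(train = extract_features(tr_eps), test = extract_features(te_eps),
       remover = remover)
}

#' Four-class BCI simulation (offline replay)
#'
#' For each chronological fold, the EOG remover and the shrinkage-LDA
#' decoder are fitted on the training runs only and applied to the held-out
#' runs. In every test trial the decision value `f(x)` of every
#' deviant-stimulus epoch is computed, grouped by deviant class, and the
#' class with the largest mean decision value is the predicted attention
#' target (ties broken by lowest class index and counted). A class with no
#' epochs in a trial gets mean `-Inf` and is never selected. Accuracy is
#' tallied over all fold-level predictions (each trial is tested in two
#' folds); the binomial significance threshold uses the number of unique
#' trials, and the ITR uses the trial duration implied by the paradigm.
#'
#' @param session an [simulate_session()] (or equally shaped) session.
#' @param n_train training runs per fold (default 2, giving 3 folds of 6).
#' @param fs_out epoch sampling rate (default 250).
#' @param alpha significance level for the accuracy threshold.
#' @param seed seed for the per-fold ICA initialisation.
#' @return object of class `bci_simulation`: `predictions` (one row per
#'   fold x test trial: fold, run, trial, true and predicted class, the
#'   per-class mean decision values), `accuracy`, `n_predictions`,
#'   `n_trials`, `threshold` (P_th), `itr`, `folds`, `n_ties`.
#' @export
run_bci_simulation <- function(session, n_train = 2L, fs_out = 250,
                               alpha = 0.05, seed = 1L,
                               ica_max_iter = 100L) {
  stopifnot(inherits(session, "asme_session"))
  classes <- session$paradigm$classes
  folds <- chrono_folds(length(session$runs), n_train)
  hp_runs <- lapply(session$runs, highpass_and_concatenate)
  preds <- list(); n_ties <- 0L
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    ff <- fold_features(hp_runs, fold$train, fold$test, fs_out = fs_out,
                        seed = derive_seed(seed, fi),
                        ica_max_iter = ica_max_iter)
    model <- fit_slda(ff$train)
    f_te <- predict(model, ff$test)
    info <- ff$test$info
    for (run in fold$test) {
      for (tr in sort(unique(info$trial_index[info$run_index == run]))) {
        in_trial <- info$run_index == run & info$trial_index == tr
        cls_mean <- vapply(seq_len(nrow(classes)), function(ci) {
          sel <- in_trial & info$stimulus_id == classes$stimulus_id[ci]
          if (!any(sel)) -Inf else mean(f_te[sel])
        }, 0)
        pred <- which(cls_mean == max(cls_mean))
        if (length(pred) > 1L) n_ties <- n_ties + 1L
        pred <- pred[1L]
        truth <- session$plans$class[session$plans$run_index == run &
                                       session$plans$trial_index == tr]
        preds[[length(preds) + 1L]] <- data.frame(
          fold = fi, run_index = run, trial_index = tr,
          true_class = truth, predicted_class = pred,
          t(stats::setNames(cls_mean, paste0("f_class", classes$class))))
      }
    }
  }
  preds <- do.call(rbind, preds)
  acc <- mean(preds$predicted_class == preds$true_class)
  n_unique <- nrow(unique(preds[, c("run_index", "trial_index")]))
  thr <- significance_threshold(n_unique, nrow(classes), alpha)
  trial_min <- session$paradigm$n_stimuli_per_trial * session$paradigm$soa / 60
  itr <- information_transfer_rate(acc, nrow(classes), V = 1 / trial_min)
  structure(list(predictions = preds, accuracy = acc,
                 n_predictions = nrow(preds), n_trials = n_unique,
                 threshold = thr, itr = itr, folds = folds,
                 n_ties = n_ties),
            class = "bci_simulation")
}

#' @export
print.bci_simulation <- function(x, ...) {
  cat(sprintf("<bci_simulation> accuracy %.3f over %d predictions (%d unique trials)\n",
              x$accuracy, x$n_predictions, x$n_trials))
  cat(sprintf("  significance threshold P_th = %.2f (alpha = %g) -> %s\n",
              x$threshold$threshold_2dp, x$threshold$alpha,
              if (x$accuracy > x$threshold$threshold) "significant"
              else "not significant"))
  cat(sprintf("  ITR: %.3f bits/trial, %.3f bits/min\n", x$itr$R, x$itr$B))
  invisible(x)
}

#' Whole-session binary target/nontarget decoding
#'
#' Fits the EOG remover on all runs (as in the offline binary analysis),
#' cleans and epochs the session with the classification band, extracts
#' interval-mean features, and evaluates the shrinkage-LDA AUC under
#' chronological cross-validation.
#'
#' @param session an `asme_session`.
#' @param n_folds chronological folds (default 4).
#' @param fs_out epoch sampling rate.
#' @param seed ICA seed.
#' @return list with `auc` (an `auc_cv`), `features` (the `feature_set`)
#'   and `remover`.
#' @export
run_binary_analysis <- function(session, n_folds = 4L, fs_out = 250,
                                seed = 1L, ica_max_iter = 100L) {
  cont <- highpass_and_concatenate(session$runs)
  remover <- fit_eog_remover(cont, seed = seed, max_iter = ica_max_iter)
  eps <- make_epochs(apply_eog_remover(remover, cont), band = c(0.1, 8),
                     fs_out = fs_out)
  feats <- extract_features(eps)
  list(auc = binary_auc_cv(feats, n_folds), features = feats,
       remover = remover)
}
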