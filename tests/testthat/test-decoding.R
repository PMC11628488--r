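test_that("interval-mean features have dimension 640 on the 64-channel montage", {
  rec <- noiseless_recording(list(default_p300()))
  eps <- make_epochs(highpass_and_concatenate(rec), band = c(0.1, 8),
                     fs_out = 250)
  feats <- extract_features(eps)
  expect_equal(ncol(feats$X), 640L)
  expect_equal(nrow(feats$X), dim(eps$epochs)[1L])
  expect_setequal(unique(feats$y), c(1, -1))
})

test_that("features are exact interval means", {
  nt <- 325L
  times <- seq(-0.1, by = 1 / 250, length.out = nt)
  e <- list(epochs = array(0, c(2, 2, nt)), times = times,
            sampling_rate = 250, channel_names = c("Cz", "Pz"),
            labels = data.frame(label = c("target", "nontarget")),
            band = c(0.1, 8))
  class(e) <- "epoch_set"
  # constant epoch: every feature equals the constant
  e$epochs[1L, , ] <- 7
  # linear ramp a * t: interval means equal a * mean(times in interval)
  a <- 3
  e$epochs[2L, 1L, ] <- a * times
  feats <- extract_features(e)
  expect_true(all(feats$X[1L, ] == 7))
  oracle <- vapply(1:10, function(k) {
    ti <- times >= (k - 1) * 0.1 & times < k * 0.1
    a * mean(times[ti])
  }, 0)
  expect_equal(feats$X[2L, 1:10], oracle, tolerance = 1e-12)
})

test_that("shrinkage-LDA recovers the Bayes direction for spherical classes", {
  # Monte-Carlo vs the closed form w proportional to mu+ - mu-
  set.seed(21)
  d <- 20L; n <- 2000L
  mu <- rnorm(d)
  X <- rbind(matrix(rnorm(n / 2 * d), ncol = d) + rep(mu, each = n / 2),
             matrix(rnorm(n / 2 * d), ncol = d))
  y <- rep(c(1, -1), each = n / 2)
  model <- fit_slda(X, y)
  angle <- acos(sum(model$w * mu) / sqrt(sum(model$w^2) * sum(mu^2))) * 180 / pi
  expect_lt(angle, 5)
  expect_true(model$gamma >= 0 && model$gamma <= 1)
})

test_that("gamma = 1 gives the mean-difference direction and a midpoint bias", {
  set.seed(4)
  X <- matrix(rnorm(60 * 8), 60)
  y <- rep(c(1, -1), 30)
  model <- fit_slda(X, y, gamma = 1)
  mu_diff <- colMeans(X[y == 1, ]) - colMeans(X[y == -1, ])
  ratio <- model$w / mu_diff
  expect_equal(max(ratio), min(ratio), tolerance = 1e-9)
  mid <- (colMeans(X[y == 1, ]) + colMeans(X[y == -1, ])) / 2
  expect_equal(as.numeric(predict(model, matrix(mid, 1))), 0,
               tolerance = 1e-9)
  expect_error(fit_slda(X, rep(1, 60)), "both classes")
})

test_that("AUC is a rank statistic: separable data, ties, monotone invariance", {
  y <- rep(c(1, -1), each = 20)
  s <- c(rnorm(20, 5), rnorm(20, 0))
  expect_equal(auc_score(s, y), 1)
  expect_equal(auc_score(exp(s / 3), y), auc_score(s, y))
  expect_equal(auc_score(rep(1, 40), y), 0.5)   # all tied: midranks
  # permutation null: mean AUC near 0.5 within 3 sigma of the
  # Mann-Whitney null standard deviation
  set.seed(9)
  n1 <- 20; n0 <- 20
  null_sd <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  aucs <- replicate(200, auc_score(rnorm(40), sample(y)))
  expect_lt(abs(mean(aucs) - 0.5), 3 * null_sd / sqrt(200))
})

test_that("chronological CV uses contiguous blocks and perfect features give AUC 1", {
  set.seed(2)
  n <- 160L
  X <- matrix(rnorm(n * 6), n)
  y <- rep(rep(c(1, -1), each = 4), 20)
  X[y == 1, 1] <- X[y == 1, 1] + 8
  feats <- structure(list(X = X, y = y,
                          info = data.frame(label = ifelse(y == 1, "target",
                                                           "nontarget"))),
                     class = "feature_set")
  cv <- binary_auc_cv(feats, n_folds = 4L)
  expect_true(all(cv$auc == 1))
  expect_true(all(diff(cv$fold_id) >= 0))       # contiguous chronological blocks
  expect_equal(unname(table(cv$fold_id)), rep(40L, 4L), ignore_attr = TRUE)
})

test_that("folds missing a class are skipped with a warning", {
  X <- matrix(rnorm(40 * 3), 40)
  y <- c(rep(1, 10), rep(c(1, -1), 15))
  feats <- structure(list(X = X, y = y, info = NULL), class = "feature_set")
  expect_warning(cv <- binary_auc_cv(feats, n_folds = 4L), "lacks a class")
  expect_true(is.na(cv$auc[1L]))
})

test_that("ITR follows the multiclass channel-capacity formula", {
  expect_equal(information_transfer_rate(1, 4)$R, 2)
  expect_equal(information_transfer_rate(0.25, 4)$R, 0)
  expect_equal(information_transfer_rate(0.5, 2)$R, 0)
  # frozen high-precision evaluation at the published operating point
  res <- information_transfer_rate(0.86, 4, V = 60 / 90)
  expect_equal(res$R, 1.1938664383, tolerance = 1e-9)
  expect_equal(res$B, 0.7959109588, tolerance = 1e-9)
  expect_error(information_transfer_rate(1.2, 4), "\\[0, 1\\]")
})

test_that("ITR is monotone in accuracy above chance and tops out at log2 N", {
  for (N in c(2, 4)) {
    P <- seq(1 / N + 1e-6, 1, length.out = 1000)
    R <- vapply(P, function(p) information_transfer_rate(p, N)$R, 0)
    expect_true(all(diff(R) > 0))
    expect_equal(R[1000], log2(N))
  }
})

test_that("the binomial accuracy threshold matches the printed value and an exhaustive oracle", {
  expect_equal(significance_threshold(24, 4, 0.05)$threshold_2dp, 0.42)
  # exhaustive tail-sum oracle, independent of qbinom:
  # smallest k with P(X > k) < alpha
  oracle2 <- function(n, p, alpha) {
    tail_gt <- function(k) sum(dbinom((k + 1):n, n, p))
    for (k in 0:(n - 1)) if (tail_gt(k) < alpha) return(k / n)
    1
  }
  expect_equal(significance_threshold(24, 2, 0.05)$threshold,
               oracle2(24, 0.5, 0.05))
  expect_equal(significance_threshold(24, 4, 0.05)$threshold,
               oracle2(24, 0.25, 0.05))
  expect_equal(significance_threshold(100, 4, 0.01)$threshold,
               oracle2(100, 0.25, 0.01))
})

test_that("the threshold tightens with more trials and with more classes", {
  th_n <- vapply(c(24, 48, 96, 192), function(n)
    significance_threshold(n, 4)$threshold, 0)
  expect_true(all(diff(th_n) <= 0))
  # lower chance level (more classes) pulls the threshold down
  th_N <- vapply(2:5, function(N) significance_threshold(24, N)$threshold, 0)
  expect_true(all(diff(th_N) <= 0))
  # alpha -> 1: any nonzero accuracy counts as significant
  expect_equal(significance_threshold(24, 4, 0.999)$threshold, 0)
  expect_error(significance_threshold(24, 4, 1.5), "alpha")
})

test_that("six runs make three chronological folds testing each run twice", {
  folds <- chrono_folds(6L, 2L)
  expect_length(folds, 3L)
  tested <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(unname(table(tested)), rep(2L, 6L), ignore_attr = TRUE)
  for (f in folds) {
    expect_length(f$train, 2L)
    expect_equal(diff(f$train), 1L)             # contiguous training block
    expect_length(intersect(f$train, f$test), 0L)
  }
})

test_that("the high-SNR simulation decodes every trial and reports coherent tallies", {
  ses <- desk_session("high-snr", 1L)
  sim <- suppressWarnings(run_bci_simulation(ses, seed = 1L))
  expect_equal(sim$accuracy, 1)
  expect_equal(sim$n_predictions, 48L)
  expect_equal(sim$n_trials, 24L)
  expect_equal(sim$threshold$threshold_2dp, 0.42)
  expect_equal(sim$itr$R, 2)
  # every prediction is the argmax of its stored per-class decision means
  f_cols <- grep("^f_class", names(sim$predictions))
  argmax <- apply(sim$predictions[, f_cols], 1L, which.max)
  expect_equal(unname(argmax), sim$predictions$predicted_class)
  # the decision rule is shift-invariant within a trial
  shifted <- apply(sim$predictions[, f_cols] + 5, 1L, which.max)
  expect_equal(unname(shifted), sim$predictions$predicted_class)
})
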