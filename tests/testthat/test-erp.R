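test_that("the half-open epoch window yields 325 samples at 250 Hz from 1000 Hz", {
  sq <- build_sequence(asme_paradigm("oddball", n_stimuli_per_trial = 12L), 1L)
  rec <- simulate_recording(sq, trial_plan(1L, "D1"), list(), noise_spec(),
                            fs = 1000, seed = 1L)
  eps <- make_epochs(highpass_and_concatenate(rec), band = c(1, 40),
                     fs_out = 250)
  expect_equal(dim(eps$epochs)[3L], 325L)
  expect_equal(eps$times[1L], -0.1)
  expect_equal(diff(eps$times)[1L], 1 / 250)
  expect_lte(max(eps$times), 1.2 - 1 / 250 + 1e-12)
  expect_equal(dim(eps$epochs)[1L], 12L)
})

test_that("every in-range event becomes one epoch; edge events are counted, not lost", {
  sq <- build_sequence(desk_paradigm("asme4stream"), 2L)
  rec <- simulate_recording(sq, trial_plan(1L, "D1"), list(), noise_spec(),
                            fs = 250, seed = 2L, pad = 1.5)
  cont <- highpass_and_concatenate(rec)
  eps <- make_epochs(cont, fs_out = 250)
  expect_equal(dim(eps$epochs)[1L], nrow(sq))
  expect_equal(attr(eps, "n_dropped"), 0L)
  # shift markers so the last event's window exceeds the recording
  cont$events$sample <- cont$events$sample +
    (ncol(cont$data) - max(cont$events$sample))
  eps2 <- make_epochs(cont, fs_out = 250)
  expect_gt(attr(eps2, "n_dropped"), 0L)
  expect_equal(dim(eps2$epochs)[1L] + attr(eps2, "n_dropped"), nrow(sq))
})

test_that("constant-zero input gives all-zero epochs", {
  rec <- noiseless_recording(list())
  eps <- make_epochs(highpass_and_concatenate(rec), fs_out = 250)
  expect_true(all(eps$epochs == 0))
})

test_that("grand averages behave like arithmetic means", {
  rec <- noiseless_recording(list(default_p300(amp = 4)))
  eps <- raw_epochs(rec)
  one <- subset_epochs(eps, 1L)
  expect_equal(grand_average(one)[, ], one$epochs[1L, , ], ignore_attr = TRUE)
  # two epochs x and -x average to zero
  flip <- subset_epochs(eps, 1:2)
  flip$epochs[2L, , ] <- -flip$epochs[1L, , ]
  expect_true(all(abs(grand_average(flip)) < 1e-12))
  expect_error(grand_average(eps, function(l) l$label == "nope"),
               "empty")
  # noiseless target average equals the injected kernel at the peak channel
  tgt <- grand_average(eps, function(l) l$label == "target")
  expect_equal(max(tgt["Pz", ]), 4, tolerance = 1e-9)
})

test_that("signed-r2 is bounded, antisymmetric, and vanishes for permuted labels", {
  rec <- noiseless_recording(list(default_p300(amp = 4)))
  eps <- raw_epochs(rec)
  # add reproducible noise so the map is non-degenerate
  set.seed(5)
  eps$epochs <- eps$epochs + rnorm(length(eps$epochs))
  r2 <- signed_r2_map(eps)
  expect_true(all(r2 >= -1 & r2 <= 1))
  flipped <- signed_r2_map(eps, positive = "nontarget")
  expect_equal(unclass(flipped), -unclass(r2), ignore_attr = TRUE)

  # permutation null: discriminability shrinks with sample size
  null_level <- function(n) {
    e <- eps
    e$epochs <- array(rnorm(n * 4 * 50), c(n, 4, 50))
    e$channel_names <- eps$channel_names[1:4]
    e$labels <- data.frame(label = rep(c("target", "nontarget"),
                                       length.out = n))
    mean(abs(signed_r2_map(e)))
  }
  set.seed(11)
  expect_lt(null_level(400), null_level(40))
  expect_lt(null_level(400), 0.01)
})

test_that("perfectly separated constant epochs give signed-r2 of one", {
  e <- list(epochs = array(rep(c(1, 0), each = 1, times = 10 * 3 * 8),
                           c(20, 3, 8)),
            times = seq(0, by = 1 / 250, length.out = 8),
            sampling_rate = 250, channel_names = c("Cz", "Pz", "Fz"),
            labels = data.frame(label = rep(c("target", "nontarget"), 10)),
            band = c(1, 40))
  class(e) <- "epoch_set"
  e$epochs[] <- rep(c(1, 0), times = 10 * 3 * 8)  # target rows 1, others 0
  r2 <- signed_r2_map(e)
  expect_true(all(abs(r2 - 1) < 1e-12))
})

test_that("zero-variance points map to zero by convention", {
  e <- list(epochs = array(0, c(6, 2, 4)),
            times = seq(0, by = 1 / 250, length.out = 4),
            sampling_rate = 250, channel_names = c("Cz", "Pz"),
            labels = data.frame(label = rep(c("target", "nontarget"), 3)),
            band = c(1, 40))
  class(e) <- "epoch_set"
  expect_true(all(signed_r2_map(e) == 0))
})

test_that("noiseless bootstrap amplitude recovers the injected peak in every replicate", {
  eps <- simulate_epochs(20, list(default_p300(amp = 3.5)),
                         background_sd = 0, seed = 1L)
  amp <- estimate_peak_amplitude(eps, n_boot = 200L, seed = 2L)
  expect_equal(unique(round(amp$samples, 9)), 3.5)
  expect_equal(amp$estimate, 3.5, tolerance = 1e-9)
})

test_that("the peak search respects the 0.2-0.5 s window", {
  late <- erp_component("late", +1, 0.62, 0.45, 0.3, 5,
                        topography = erp_topography("centroparietal"))
  eps <- simulate_epochs(10, list(late), background_sd = 0, seed = 1L)
  amp <- estimate_peak_amplitude(eps, n_boot = 50L, seed = 1L)
  # the kernel is still rising at 0.5 s; the windowed max is its value at
  # the window edge, well below the true peak
  kern <- make_component_waveform(late, 250, 1.2)
  expected <- kern[round(0.5 * 250) + 1L]
  expect_lt(amp$estimate, 4)
  expect_equal(amp$estimate, expected, tolerance = 1e-9)
})

test_that("bootstrap estimators are seed-deterministic and need >= 2 epochs", {
  eps <- simulate_epochs(30, list(default_p300(amp = 3.5)), seed = 4L)
  a1 <- estimate_peak_amplitude(eps, n_boot = 100L, seed = 9L)
  a2 <- estimate_peak_amplitude(eps, n_boot = 100L, seed = 9L)
  expect_identical(a1$samples, a2$samples)
  expect_error(estimate_peak_amplitude(subset_epochs(eps, 1L)),
               "at least 2")
})

test_that("amplitude estimates increase with the injected amplitude", {
  est <- vapply(c(2, 3.5, 5), function(a) {
    eps <- simulate_epochs(60, list(default_p300(amp = a)), seed = 17L)
    estimate_peak_amplitude(eps, n_boot = 300L, seed = 3L)$estimate
  }, 0)
  expect_true(all(diff(est) > 0))
})

test_that("identical target and standard sets never reach significance", {
  eps <- simulate_epochs(30, list(), background_sd = 0, seed = 6L)
  lat <- estimate_onset_latency(eps, eps, n_boot = 50L, seed = 1L)
  expect_equal(lat$n_failed, 50L)
  expect_true(is.na(lat$estimate))
})

test_that("a noiseless step is detected at the first grid time past its onset", {
  nt <- 325L
  times <- seq(-0.1, by = 1 / 250, length.out = nt)
  step <- as.numeric(times >= 0.25)
  base <- list(times = times, sampling_rate = 250,
               channel_names = c("Cz", "Pz"), band = c(1, 40))
  tgt <- base; std <- base
  tgt$epochs <- aperm(array(step, c(nt, 8, 2)), c(2L, 3L, 1L))
  std$epochs <- array(0, c(8, 2, nt))
  tgt$labels <- data.frame(label = rep("target", 8))
  std$labels <- data.frame(label = rep("standard", 8))
  class(tgt) <- class(std) <- "epoch_set"
  lat <- estimate_onset_latency(tgt, std, channels = c("Cz", "Pz"),
                                n_boot = 50L, seed = 2L)
  expect_equal(lat$n_failed, 0L)
  # 0.25 s is off-grid; the first sampled time at or after it is 0.252 s
  expect_equal(unique(lat$samples), 0.252)
})

test_that("defined latency estimates always fall inside the search window", {
  eps_t <- simulate_epochs(40, list(default_p300(amp = 3.5)), seed = 8L)
  eps_s <- simulate_epochs(60, list(), seed = 9L)
  lat <- estimate_onset_latency(eps_t, eps_s, n_boot = 100L, seed = 5L)
  expect_true(all(lat$samples >= 0.2 & lat$samples <= 0.5))
  l2 <- estimate_onset_latency(eps_t, eps_s, n_boot = 100L, seed = 5L)
  expect_identical(lat$samples, l2$samples)
})
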