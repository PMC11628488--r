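test_that("asme4stream default sequence matches the published design", {
  cfg <- asme_paradigm("asme4stream")
  sq <- build_sequence(cfg, seed = 7L)
  expect_equal(nrow(sq), 600L)
  expect_equal(unique(round(diff(sq$onset_s), 10)), 0.15)
  # within-stream SOA is N x t = 0.6 s, exactly, in every stream
  for (s in 1:4) {
    on <- sq$onset_s[sq$stream == s]
    expect_equal(unique(round(diff(on), 10)), 0.6)
    expect_equal(sum(sq$stream == s & sq$role == "standard"), 135L)
    expect_equal(sum(sq$stream == s & sq$role == "deviant"), 15L)
  }
})

test_that("asme2stream default sequence has 300 events at an exact 8:1:1 ratio", {
  sq <- build_sequence(asme_paradigm("asme2stream"), seed = 3L)
  expect_equal(nrow(sq), 300L)
  counts <- table(sq$stimulus_id)
  expect_equal(unname(counts[c("S1", "D1", "D2")]), c(120L, 15L, 15L),
               ignore_attr = TRUE)
  expect_equal(unname(counts[c("S2", "D3", "D4")]), c(120L, 15L, 15L),
               ignore_attr = TRUE)
})

test_that("degenerate and invalid configurations are handled", {
  empty <- build_sequence(asme_paradigm("asme4stream",
                                        n_stimuli_per_trial = 0L), 1L)
  expect_equal(nrow(empty), 0L)
  expect_error(build_sequence(asme_paradigm("asme4stream",
                                            n_stimuli_per_trial = 44L), 1L),
               "not divisible")
})

test_that("sequences are seed-deterministic; seeds move deviants, never counts", {
  cfg <- desk_paradigm("asme4stream")
  a <- build_sequence(cfg, 11L)
  b <- build_sequence(cfg, 11L)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- build_sequence(cfg, 12L)
  expect_false(identical(a$stimulus_id, c$stimulus_id))
  expect_equal(table(a$stimulus_id), table(c$stimulus_id))
  expect_equal(a$onset_s, c$onset_s)
  expect_equal(a$stream, c$stream)
})

test_that("deviant placement respects the slot constraints across seeds", {
  for (name in c("asme4stream", "asme2stream")) {
    cfg <- desk_paradigm(name)
    for (seed in 1:50) {
      sq <- build_sequence(cfg, seed)
      for (s in seq_len(cfg$n_streams)) {
        roles <- sq$role[sq$stream == s]
        dev <- which(roles != "standard")
        expect_true(all(dev > 2L))              # never the first two slots
        if (length(dev) > 1L) expect_true(all(diff(dev) > 1L))
      }
    }
  }
})

test_that("label assignment partitions events with the attended deviant as target", {
  sq4 <- build_sequence(asme_paradigm("asme4stream"), 5L)
  lab4 <- assign_event_labels(sq4, trial_plan(1L, "D1"))
  expect_equal(sum(lab4$label == "target") + sum(lab4$label == "nontarget"),
               nrow(sq4))
  expect_setequal(unique(lab4$stimulus_id[lab4$label == "target"]), "D1")
  expect_setequal(unique(lab4$stimulus_id[lab4$label == "nontarget"]),
                  c("S1", "S2", "S3", "S4", "D2", "D3", "D4"))

  sq2 <- build_sequence(asme_paradigm("asme2stream"), 5L)
  lab2 <- assign_event_labels(sq2, trial_plan(1L, "D1"))
  expect_setequal(unique(lab2$stimulus_id[lab2$label == "target"]), "D1")
  expect_setequal(unique(lab2$stimulus_id[lab2$label == "nontarget"]),
                  c("S1", "S2", "D2", "D3", "D4"))
  # within the attended stream, target:nontarget is 15:135 = 1:9
  in_stream <- lab2[lab2$stream == 1L, ]
  expect_equal(sum(in_stream$label == "target"), 15L)
  expect_equal(sum(in_stream$label == "nontarget"), 135L)
})

test_that("a standard stimulus cannot be the attended target", {
  sq <- build_sequence(asme_paradigm("asme4stream"), 1L)
  expect_error(assign_event_labels(sq, trial_plan(1L, "S1")), "standard")
  expect_error(assign_event_labels(sq, trial_plan(2L, "D1")), "not found")
})

test_that("rendered audio places pure-tone bursts at event onsets", {
  cfg <- asme_paradigm("oddball", n_stimuli_per_trial = 6L)
  sq <- build_sequence(cfg, 2L)[1L, ]          # single 110 Hz burst
  attr(sq, "paradigm") <- cfg
  class(sq) <- c("event_sequence", "data.frame")
  sq$frequency_hz <- 110
  wave <- render_audio(sq, sample_rate = 8000)
  expect_lte(max(abs(wave)), 1)
  padded <- c(as.numeric(wave), numeric(8 * 8000))   # finer FFT grid
  spec <- Mod(fft(padded))[1:(length(padded) %/% 2)]
  f_peak <- (which.max(spec) - 1) / length(padded) * 8000
  expect_lt(abs(f_peak - 110), 1)

  empty <- render_audio(build_sequence(asme_paradigm("oddball",
                                                     n_stimuli_per_trial = 0L),
                                       1L))
  expect_true(all(empty == 0))
})

test_that("tones shorter than the SOA never overlap; longer ones error", {
  cfg <- desk_paradigm("asme4stream")       # SOA 0.15 s
  sq <- build_sequence(cfg, 1L)[1:2, ]
  attr(sq, "paradigm") <- cfg
  class(sq) <- c("event_sequence", "data.frame")
  wave <- render_audio(sq, tone_duration = 0.1, sample_rate = 8000)
  # supports: [0, 0.1) and [0.15, 0.25) -- the gap in between is silent
  gap <- wave[round(0.11 * 8000):round(0.14 * 8000)]
  expect_true(all(gap == 0))
  expect_error(render_audio(sq, tone_duration = 0.2), "overlap")
})

test_that("event sequences round-trip through TSV", {
  sq <- assign_event_labels(build_sequence(desk_paradigm("asme2stream"), 9L),
                            trial_plan(2L, "D3"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sequence_tsv(sq, path)
  back <- read_sequence_tsv(path)
  expect_equal(back$stimulus_id, sq$stimulus_id)
  expect_equal(back$onset_s, sq$onset_s)
  expect_equal(back$label, sq$label)
})
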