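#' Paradigm configurations for auditory stream-segregation ERP experiments
#'
#' Builds the configuration of one of the three supported stimulus designs:
#'
#' * `"asme4stream"`: four interleaved tone streams, each a two-stimulus
#'   oddball (standard `Sn`, deviant `Dn`), overall SOA 0.15 s, 600 stimuli
#'   per trial, per-stream presentation ratio 9:1.
#' * `"asme2stream"`: two interleaved streams, each a three-stimulus oddball
#'   (standard `Sn`, low deviant, high deviant), overall SOA 0.3 s,
#'   300 stimuli per trial, per-stream ratio 8:1:1.
#' * `"oddball"`: a single-stream control oddball (500/1000 Hz), SOA 1.0 s,
#'   ratio 5:1.
#'
#' Streams are interleaved in fixed cyclic order, so the within-stream SOA is
#' `n_streams * soa` (0.6 s for both ASME designs).
#'
#' @param name paradigm name.
#' @param n_stimuli_per_trial number of stimuli in one trial; must divide
#'   evenly into streams and ratio parts. Defaults to the design's standard
#'   value (600 / 300 / 120).
#' @return an object of class `asme_paradigm`: a list with elements `name`,
#'   `n_streams`, `soa` (s), `n_stimuli_per_trial`, `ratio` (integer parts,
#'   standard first), `stimuli` (data.frame: stream, stimulus_id, role,
#'   frequency_hz) and `classes` (data.frame mapping the four decodable
#'   attention targets to deviant stimuli; `NULL` for the oddball control).
#' @export
asme_paradigm <- function(name = c("asme4stream", "asme2stream", "oddball"),
                          n_stimuli_per_trial = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    asme4stream = list(
      n_streams = 4L, soa = 0.15, n_default = 600L, ratio = c(9L, 1L),
      stimuli = data.frame(
        stream = rep(1:4, each = 2L),
        stimulus_id = c("S1", "D1", "S2", "D2", "S3", "D3", "S4", "D4"),
        role = rep(c("standard", "deviant"), 4L),
        frequency_hz = c(110.00, 123.47, 415.30, 466.16,
                         1567.98, 1760.00, 5919.91, 6644.86),
        stringsAsFactors = FALSE)),
    asme2stream = list(
      n_streams = 2L, soa = 0.30, n_default = 300L, ratio = c(8L, 1L, 1L),
      stimuli = data.frame(
        stream = c(1L, 1L, 1L, 2L, 2L, 2L),
        stimulus_id = c("S1", "D1", "D2", "S2", "D3", "D4"),
        role = c("standard", "deviant_low", "deviant_high",
                 "standard", "deviant_low", "deviant_high"),
        frequency_hz = c(523.3, 440.0, 622.3, 3136.0, 2637.0, 3729.3),
        stringsAsFactors = FALSE)),
    oddball = list(
      n_streams = 1L, soa = 1.00, n_default = 120L, ratio = c(5L, 1L),
      stimuli = data.frame(
        stream = c(1L, 1L),
        stimulus_id = c("S1", "D1"),
        role = c("standard", "deviant"),
        frequency_hz = c(500, 1000),
        stringsAsFactors = FALSE)))
  n <- as.integer(n_stimuli_per_trial %||% cfg$n_default)
  classes <- NULL
  if (name %in% c("asme4stream", "asme2stream")) {
    dev <- cfg$stimuli[cfg$stimuli$role != "standard", , drop = FALSE]
    classes <- data.frame(class = seq_len(nrow(dev)),
                          stimulus_id = dev$stimulus_id,
                          stream = dev$stream, stringsAsFactors = FALSE)
  }
  structure(list(name = name, n_streams = cfg$n_streams, soa = cfg$soa,
                 n_stimuli_per_trial = n, ratio = cfg$ratio,
                 stimuli = cfg$stimuli, classes = classes),
            class = "asme_paradigm")
}

#' @export
print.asme_paradigm <- function(x, ...) {
  cat(sprintf("<asme_paradigm> %s: %d stream(s), SOA %.2f s (within-stream %.2f s), %d stimuli/trial, ratio %s\n",
              x$name, x$n_streams, x$soa, x$n_streams * x$soa,
              x$n_stimuli_per_trial, paste(x$ratio, collapse = ":")))
  invisible(x)
}

# Uniform draw of `nd` mutually non-adjacent slot indices in 3:m (deviants
# never occupy a stream's first two slots and never sit back to back).
draw_deviant_slots <- function(m, nd) {
  if (nd == 0L) return(integer(0))
  avail <- m - 2L - (nd - 1L)
  if (avail < nd)
    stop("cannot place ", nd, " non-adjacent deviants in ", m, " slots",
         call. = FALSE)
  sort(sample.int(avail, nd)) + 2L + 0:(nd - 1L)
}

#' Generate one trial's stimulus event sequence
#'
#' Interleaves the paradigm's streams in fixed cyclic order at the overall
#' SOA and places deviants uniformly at random within each stream, subject
#' to: no deviant in a stream's first two slots, and no two deviants of the
#' same stream in adjacent within-stream slots. Per-stream role counts match
#' the configured ratio exactly for every seed.
#'
#' @param config an [asme_paradigm()] object.
#' @param seed integer seed; equal seeds give identical sequences.
#' @return an object of class `event_sequence`: a data.frame with columns
#'   `onset_s`, `stream`, `stimulus_id`, `role`, `frequency_hz`, with the
#'   paradigm and seed stored as attributes.
#' @export
build_sequence <- function(config, seed) {
  stopifnot(inherits(config, "asme_paradigm"))
  n <- config$n_stimuli_per_trial
  N <- config$n_streams
  if (n %% N != 0L)
    stop("n_stimuli_per_trial must be divisible by the number of streams",
         call. = FALSE)
  m <- n %/% N                      # slots per stream
  parts <- config$ratio
  if (n > 0L && m %% sum(parts) != 0L)
    stop("per-stream count ", m, " not divisible by ratio ",
         paste(parts, collapse = ":"), call. = FALSE)
  ids <- with_seed(seed, {
    lapply(seq_len(N), function(s) {
      stim <- config$stimuli[config$stimuli$stream == s, , drop = FALSE]
      std_id <- stim$stimulus_id[stim$role == "standard"]
      dev <- stim[stim$role != "standard", , drop = FALSE]
      counts <- m %/% sum(parts) * parts
      slot_ids <- rep(std_id, m)
      if (m > 0L && sum(counts[-1L]) > 0L) {
        pos <- draw_deviant_slots(m, sum(counts[-1L]))
        kinds <- sample(rep(dev$stimulus_id, counts[-1L]))
        slot_ids[pos] <- kinds
      }
      slot_ids
    })
  })
  # cyclic interleaving: event i -> stream ((i-1) mod N) + 1
  seq_ids <- character(n)
  for (s in seq_len(N))
    if (n > 0L) seq_ids[seq(s, n, by = N)] <- ids[[s]]
  lut <- config$stimuli
  rows <- match(seq_ids, lut$stimulus_id)
  ev <- data.frame(
    onset_s = (seq_len(n) - 1L) * config$soa,
    stream = lut$stream[rows],
    stimulus_id = seq_ids,
    role = lut$role[rows],
    frequency_hz = lut$frequency_hz[rows],
    stringsAsFactors = FALSE)
  if (n == 0L)
    ev <- data.frame(onset_s = numeric(0), stream = integer(0),
                     stimulus_id = character(0), role = character(0),
                     frequency_hz = numeric(0))
  structure(ev, paradigm = config, seed = as.integer(seed),
            class = c("event_sequence", "data.frame"))
}

#' Define the attended target of one trial
#'
#' @param target_stream index of the attended stream.
#' @param target_stimulus_id the attended deviant's stimulus id.
#' @param trial_index,run_index position of the trial in the session layout.
#' @return an object of class `trial_plan`.
#' @export
trial_plan <- function(target_stream, target_stimulus_id,
                       trial_index = 1L, run_index = 1L) {
  structure(list(target_stream = as.integer(target_stream),
                 target_stimulus_id = target_stimulus_id,
                 trial_index = as.integer(trial_index),
                 run_index = as.integer(run_index)),
            class = "trial_plan")
}

#' Label events as target / nontarget given an attended deviant
#'
#' The attended deviant stimuli of the target stream are `target`; every
#' other event — standards of the target stream, unattended deviants of the
#' same stream, and all stimuli of other streams — is `nontarget`. Every
#' event receives exactly one binary label.
#'
#' @param seq an [build_sequence()] event sequence.
#' @param plan a [trial_plan()].
#' @return the sequence with added columns `label` ("target"/"nontarget")
#'   and `tag` (auxiliary role tag: "target-deviant",
#'   "standard-in-target-stream", "deviant-<id>", or "other-stream").
#' @export
assign_event_labels <- function(seq, plan) {
  stopifnot(inherits(seq, "event_sequence"), inherits(plan, "trial_plan"))
  config <- attr(seq, "paradigm")
  stim <- config$stimuli
  hit <- stim$stimulus_id == plan$target_stimulus_id &
    stim$stream == plan$target_stream
  if (!any(hit))
    stop("target stimulus '", plan$target_stimulus_id,
         "' not found in stream ", plan$target_stream, call. = FALSE)
  if (stim$role[hit] == "standard")
    stop("invalid plan: target stimulus '", plan$target_stimulus_id,
         "' is a standard, not a deviant", call. = FALSE)
  is_target <- seq$stimulus_id == plan$target_stimulus_id &
    seq$stream == plan$target_stream
  tag <- ifelse(is_target, "target-deviant",
         ifelse(seq$stream == plan$target_stream & seq$role == "standard",
                "standard-in-target-stream",
         ifelse(seq$stream == plan$target_stream,
                paste0("deviant-", seq$stimulus_id), "other-stream")))
  out <- seq
  out$label <- ifelse(is_target, "target", "nontarget")
  out$tag <- tag
  attr(out, "plan") <- plan
  out
}

#' Render an event sequence as an audio waveform
#'
#' Each event contributes a sine burst at its stimulus frequency, gated by
#' raised-cosine on/off ramps. Tones must not overlap (`tone_duration`
#' strictly less than the overall SOA).
#'
#' @param seq an event sequence.
#' @param tone_duration tone length in seconds (default 0.1).
#' @param ramp raised-cosine ramp length in seconds (default 0.005).
#' @param sample_rate audio rate in Hz (default 44100).
#' @param amplitude per-tone peak amplitude (default 0.9; peak of the mix
#'   stays at or below 1 because tones never overlap).
#' @return numeric waveform vector with attribute `sample_rate`.
#' @export
render_audio <- function(seq, tone_duration = 0.1, ramp = 0.005,
                         sample_rate = 44100, amplitude = 0.9) {
  stopifnot(inherits(seq, "event_sequence"))
  config <- attr(seq, "paradigm")
  if (nrow(seq) > 1L && tone_duration >= config$soa)
    stop("tone_duration (", tone_duration, " s) must be shorter than the SOA (",
         config$soa, " s): tones would overlap", call. = FALSE)
  dur <- if (nrow(seq) == 0L) 0 else max(seq$onset_s) + tone_duration + 0.05
  n <- ceiling(dur * sample_rate)
  wave <- numeric(n)
  if (nrow(seq) > 0L) {
    nt <- round(tone_duration * sample_rate)
    t <- (seq_len(nt) - 1L) / sample_rate
    env <- rep(1, nt)
    nr <- round(ramp * sample_rate)
    if (nr > 0L) {
      r <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
      env[seq_len(nr)] <- r
      env[nt + 1L - seq_len(nr)] <- r
    }
    for (i in seq_len(nrow(seq))) {
      i0 <- round(seq$onset_s[i] * sample_rate)
      tone <- amplitude * env * sin(2 * pi * seq$frequency_hz[i] * t)
      wave[i0 + seq_len(nt)] <- wave[i0 + seq_len(nt)] + tone
    }
  }
  structure(wave, sample_rate = sample_rate)
}

#' Write / read event sequences as TSV
#'
#' Columns: `onset_s`, `stream`, `stimulus_id`, `role`, `frequency_hz` and,
#' if present, `label`. UTF-8, '.' decimal separator.
#'
#' @param seq event sequence (possibly labeled).
#' @param path file path.
#' @return `write_sequence_tsv` returns `path` invisibly;
#'   `read_sequence_tsv` a data.frame.
#' @export
write_sequence_tsv <- function(seq, path) {
  cols <- intersect(c("onset_s", "stream", "stimulus_id", "role",
                      "frequency_hz", "label"), names(seq))
  utils::write.table(as.data.frame(seq)[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_sequence_tsv
#' @export
read_sequence_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' @param wave numeric vector in \[-1, 1\] (clipped otherwise).
#' @param path output path.
#' @param sample_rate rate in Hz; defaults to the waveform's
#'   `sample_rate` attribute.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate = attr(wave, "sample_rate")) {
  stopifnot(!is.null(sample_rate))
  pcm <- as.integer(round(pmax(-1, pmin(1, as.numeric(wave))) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L, 1L + 65536L), con, size = 4, endian = "little") # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(c(2L + 16L * 65536L), con, size = 4, endian = "little") # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
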