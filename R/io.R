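#' Save / load a recording in the package's directory container
#'
#' The container is a directory holding `meta.json` (schema version,
#' sampling rate, channel names, run index), `data.bin` (float64
#' little-endian samples, channel-major interleaved: all channels of sample
#' 1, then sample 2, ...) and `events.tsv`. The round trip is lossless.
#'
#' @param rec an `eeg_recording`.
#' @param path container directory (created if absent).
#' @return `save_recording`: `path`, invisibly. `load_recording`: an
#'   `eeg_recording`.
#' @export
save_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(schema = "asmebci-recording-1",
               sampling_rate = rec$sampling_rate,
               channel_names = rec$channel_names,
               n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               run_index = rec$run_index)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "data.bin"), "wb")
  writeBin(as.numeric(rec$data), con, size = 8, endian = "little")
  close(con)
  utils::write.table(rec$events, file.path(path, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param path container directory or a BrainVision header (`.vhdr`) file.
#' @rdname save_recording
#' @export
load_recording <- function(path) {
  if (grepl("\\.vhdr$", path, ignore.case = TRUE))
    return(read_brainvision(path))
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    stop("not a recording container (missing meta.json): ", path,
         call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$schema, "asmebci-recording-1"))
    stop("unsupported container schema: ", meta$schema %||% "<none>",
         call. = FALSE)
  n_val <- meta$n_channels * meta$n_samples
  bin_path <- file.path(path, "data.bin")
  if (file.info(bin_path)$size != 8 * n_val)
    stop("truncated data.bin: expected ", 8 * n_val, " bytes, found ",
         file.info(bin_path)$size, call. = FALSE)
  con <- file(bin_path, "rb")
  vals <- readBin(con, numeric(), n = n_val, size = 8, endian = "little")
  close(con)
  data <- matrix(vals, meta$n_channels, meta$n_samples,
                 dimnames = list(meta$channel_names, NULL))
  events <- utils::read.table(file.path(path, "events.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  structure(list(data = data, sampling_rate = meta$sampling_rate,
                 channel_names = meta$channel_names, events = events,
                 run_index = meta$run_index, ground_truth = NULL),
            class = "eeg_recording")
}

#' Export / import BrainVision recordings
#'
#' Writes the standard triplet: text header (`.vhdr`), text marker file
#' (`.vmrk`) and multiplexed IEEE float32 binary data (`.eeg`). Import is
#' read-only and supports exactly this layout (float32, multiplexed);
#' samples round-trip within float32 quantisation.
#'
#' @param rec an `eeg_recording`.
#' @param basename output path without extension.
#' @return `write_brainvision`: the `.vhdr` path, invisibly;
#'   `read_brainvision`: an `eeg_recording`.
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "eeg_recording"))
  stem <- basename(basename)
  nch <- nrow(rec$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$sampling_rate, digits = 12)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), rec$channel_names))
  writeLines(hdr, paste0(basename, ".vhdr"), useBytes = FALSE)
  mrk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", stem, ".eeg"),
           "[Marker Infos]",
           "Mk1=New Segment,,1,1,0")
  if (nrow(rec$events) > 0L)
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                          seq_len(nrow(rec$events)) + 1L,
                          paste0("S_", rec$events$stimulus_id),
                          rec$events$sample))
  writeLines(mrk, paste0(basename, ".vmrk"))
  con <- file(paste0(basename, ".eeg"), "wb")
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  close(con)
  invisible(paste0(basename, ".vhdr"))
}

parse_vhdr_section <- function(lines, section) {
  start <- grep(paste0("^\\[", section, "\\]"), lines)
  if (length(start) == 0L) return(character(0))
  rest <- lines[(start[1L] + 1L):length(lines)]
  nxt <- grep("^\\[", rest)
  if (length(nxt) > 0L) rest <- rest[seq_len(nxt[1L] - 1L)]
  rest[grepl("=", rest)]
}

#' @param vhdr_path path to a `.vhdr` header file.
#' @rdname write_brainvision
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path))
    stop("header file not found: ", vhdr_path, call. = FALSE)
  lines <- readLines(vhdr_path, warn = FALSE)
  kv <- function(section) {
    items <- parse_vhdr_section(lines, section)
    vals <- sub("^[^=]*=", "", items)
    stats::setNames(vals, sub("=.*$", "", items))
  }
  common <- kv("Common Infos")
  binary <- kv("Binary Infos")
  if (!identical(toupper(common[["DataOrientation"]]), "MULTIPLEXED") ||
      !identical(toupper(binary[["BinaryFormat"]]), "IEEE_FLOAT_32"))
    stop("only MULTIPLEXED IEEE_FLOAT_32 BrainVision files are supported",
         call. = FALSE)
  nch <- as.integer(common[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(common[["SamplingInterval"]])
  ch <- vapply(kv("Channel Infos"), function(v)
    strsplit(v, ",")[[1L]][1L], "", USE.NAMES = FALSE)
  eeg_path <- file.path(dirname(vhdr_path), common[["DataFile"]])
  sz <- file.info(eeg_path)$size
  if (is.na(sz) || sz %% (4L * nch) != 0)
    stop("corrupt or truncated BrainVision data file: ", eeg_path,
         call. = FALSE)
  con <- file(eeg_path, "rb")
  vals <- readBin(con, numeric(), n = sz / 4, size = 4, endian = "little")
  close(con)
  data <- matrix(vals, nch, dimnames = list(ch, NULL))
  events <- data.frame(sample = integer(0), stimulus_id = character(0))
  vmrk_path <- file.path(dirname(vhdr_path), common[["MarkerFile"]])
  if (!is.na(vmrk_path) && file.exists(vmrk_path)) {
    items <- parse_vhdr_section(readLines(vmrk_path, warn = FALSE),
                                "Marker Infos")
    parts <- strsplit(sub("^[^=]*=", "", items), ",")
    stim <- vapply(parts, function(p) identical(p[1L], "Stimulus"), TRUE)
    events <- data.frame(
      sample = vapply(parts[stim], function(p) as.integer(p[3L]), 0L),
      stimulus_id = vapply(parts[stim], function(p) sub("^S_", "", p[2L]), ""),
      stringsAsFactors = FALSE)
  }
  structure(list(data = data, sampling_rate = fs, channel_names = ch,
                 events = events, run_index = 1L, ground_truth = NULL),
            class = "eeg_recording")
}
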