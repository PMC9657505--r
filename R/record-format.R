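# Bespoke ".spectre" binary container.
#
# Layout (all multi-byte integers little-endian):
#   magic        4 bytes  "SPTR"
#   version      1 byte   (currently 1)
#   reserved     2 bytes  (LED time-slot metadata; written as zero)
#   sample_rate  4 bytes  unsigned
#   start_time   8 bytes  unsigned, milliseconds since Unix epoch (UTC)
#   id_len       1 byte   + device_id bytes (UTF-8)
#   frame_count  4 bytes  unsigned
#   event_count  4 bytes  unsigned
#   frames       frame_count x 12 bytes: ecg, ppg_green, ppg_red, ppg_ir,
#                each a 24-bit two's-complement little-endian count
#   events       event_count x 5 bytes: sample_index (u32) + code (u8)

SPECTRE_MAGIC <- charToRaw("SPTR")
SPECTRE_VERSION <- 1L
FRAME_BYTES <- 12L
SAMPLE_MIN <- -2^23
SAMPLE_MAX <- 2^23 - 1

#' Event marker codes
#'
#' Small-integer codes for event markers stored alongside the sample
#' stream: the start and end of oxygen administration (set by the chamber
#' operator) and a free-form user mark.
#' @export
event_codes <- c(OXYGEN_ONSET = 1L, OXYGEN_OFF = 2L, USER_MARK = 3L)

#' Construct an in-memory recording
#'
#' The data model mirrors the acquisition hardware: every 1 ms sample frame
#' holds four synchronized 24-bit integer counts — one ECG channel and
#' three PPG channels (green, red, infrared) — plus a table of event
#' markers tied to sample indices.
#'
#' @param frames Data frame with integer columns `ecg`, `ppg_green`,
#'   `ppg_red`, `ppg_ir`; one row per 1/`sample_rate` s frame.
#' @param sample_rate Sampling rate, Hz (> 0, default 1000).
#' @param start_time_ms Recording start, integer milliseconds since the
#'   Unix epoch, UTC. Defaults to 0 so that simulated recordings are
#'   reproducible byte-for-byte.
#' @param device_id Device identifier string (at most 255 bytes).
#' @param events Optional data frame with columns `sample_index` (0-based,
#'   `< nrow(frames)`) and `code` (see [event_codes]).
#' @return An object of class `recording`.
#' @export
recording <- function(frames, sample_rate = 1000, start_time_ms = 0,
                      device_id = "", events = NULL) {
  chans <- c("ecg", "ppg_green", "ppg_red", "ppg_ir")
  if (!is.data.frame(frames) || !all(chans %in% names(frames))) {
    stop_param("`frames` must have columns ecg, ppg_green, ppg_red, ppg_ir.")
  }
  frames <- tibble::as_tibble(frames)[chans]
  for (ch in chans) frames[[ch]] <- as.integer(frames[[ch]])
  check_scalar_num(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  check_scalar_num(start_time_ms, "start_time_ms", lower = 0)
  if (nchar(device_id, type = "bytes") > 255) {
    stop_param("`device_id` must be at most 255 bytes.")
  }
  if (is.null(events)) {
    events <- tibble::tibble(sample_index = integer(), code = integer())
  } else {
    if (!all(c("sample_index", "code") %in% names(events))) {
      stop_param("`events` must have columns sample_index and code.")
    }
    events <- tibble::as_tibble(events)[c("sample_index", "code")]
    events$sample_index <- as.integer(events$sample_index)
    events$code <- as.integer(events$code)
    if (nrow(events) && (any(events$sample_index < 0) ||
                         any(events$sample_index >= nrow(frames)))) {
      stop_param("Event sample_index values must lie within the frame range.")
    }
    events <- events[order(events$sample_index), ]
  }
  structure(
    list(sample_rate = sample_rate,
         start_time_ms = as.numeric(start_time_ms),
         device_id = device_id, frames = frames, events = events),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d frames @ %g Hz (%.3f s), device '%s', %d event(s)\n",
    nrow(x$frames), x$sample_rate, nrow(x$frames) / x$sample_rate,
    x$device_id, nrow(x$events)
  ))
  invisible(x)
}

u32_to_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256,
           (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

raw_to_u32 <- function(r) {
  v <- as.numeric(as.integer(r))
  v[1] + 256 * v[2] + 65536 * v[3] + 16777216 * v[4]
}

pack_frames <- function(frames) {
  v <- as.numeric(rbind(frames$ecg, frames$ppg_green,
                        frames$ppg_red, frames$ppg_ir))
  u <- v + (v < 0) * 2^24
  as.raw(rbind(u %% 256, (u %/% 256) %% 256, u %/% 65536))
}

unpack_frames <- function(r, n_frames) {
  m <- matrix(as.integer(r), nrow = 3)
  u <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
  v <- as.integer(u - (u >= 2^23) * 2^24)
  ch <- matrix(v, nrow = 4)
  tibble::tibble(ecg = ch[1, ], ppg_green = ch[2, ],
                 ppg_red = ch[3, ], ppg_ir = ch[4, ])
}

#' Write a recording to a binary .spectre file
#'
#' Serializes the recording in the fixed device-style layout (header,
#' 12-byte packed frames, event table). Channel values outside the 24-bit
#' signed range are rejected before anything is written; write-then-read is
#' bit-exact.
#'
#' @param rec A [recording].
#' @param path Destination file path.
#' @return Invisibly, the number of bytes written.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "recording")) stop_param("`rec` must be a recording.")
  fr <- rec$frames
  rng <- if (nrow(fr)) range(as.matrix(fr)) else c(0, 0)
  if (rng[1] < SAMPLE_MIN || rng[2] > SAMPLE_MAX) {
    stop_param(sprintf(
      "Sample value out of the 24-bit signed range [%d, %d].",
      SAMPLE_MIN, SAMPLE_MAX))
  }
  id_raw <- charToRaw(rec$device_id)
  ms <- rec$start_time_ms
  header <- c(
    SPECTRE_MAGIC,
    as.raw(SPECTRE_VERSION), as.raw(c(0, 0)),
    u32_to_raw(rec$sample_rate),
    u32_to_raw(ms %% 2^32), u32_to_raw(ms %/% 2^32),
    as.raw(length(id_raw)), id_raw,
    u32_to_raw(nrow(fr)),
    u32_to_raw(nrow(rec$events))
  )
  ev_raw <- if (nrow(rec$events)) {
    unlist(lapply(seq_len(nrow(rec$events)), function(i) {
      c(u32_to_raw(rec$events$sample_index[i]), as.raw(rec$events$code[i]))
    }))
  } else {
    raw(0)
  }
  payload <- c(header, pack_frames(fr), ev_raw)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(payload, con)
  invisible(length(payload))
}

read_exact <- function(con, n, what) {
  r <- readBin(con, "raw", n = n)
  if (length(r) != n) {
    stop_io(sprintf("Truncated .spectre file while reading %s (wanted %d bytes, got %d).",
                    what, n, length(r)),
            class = "pttkit_truncation_error")
  }
  r
}

#' Read a recording from a binary .spectre file
#'
#' Exact inverse of [write_recording()]. Raises distinct errors for a bad
#' magic number, an unsupported format version, and a truncated payload; a
#' truncated file never yields a partial recording.
#'
#' @param path Source file path.
#' @return A [recording].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("No such file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))

  magic <- read_exact(con, 4, "magic")
  if (!identical(magic, SPECTRE_MAGIC)) {
    stop_io(sprintf("Not a .spectre recording (bad magic '%s').",
                    rawToChar(magic, multiple = FALSE)),
            class = "pttkit_magic_error")
  }
  version <- as.integer(read_exact(con, 1, "version"))
  if (version != SPECTRE_VERSION) {
    stop_io(sprintf("Unsupported format version %d (this reader supports version %d).",
                    version, SPECTRE_VERSION),
            class = "pttkit_version_error")
  }
  read_exact(con, 2, "reserved bytes")
  sample_rate <- raw_to_u32(read_exact(con, 4, "sample rate"))
  ms_lo <- raw_to_u32(read_exact(con, 4, "start time"))
  ms_hi <- raw_to_u32(read_exact(con, 4, "start time"))
  start_time_ms <- ms_hi * 2^32 + ms_lo
  id_len <- as.integer(read_exact(con, 1, "device id length"))
  device_id <- if (id_len > 0) rawToChar(read_exact(con, id_len, "device id")) else ""
  n_frames <- raw_to_u32(read_exact(con, 4, "frame count"))
  n_events <- raw_to_u32(read_exact(con, 4, "event count"))

  frames <- if (n_frames > 0) {
    unpack_frames(read_exact(con, FRAME_BYTES * n_frames, "frames"), n_frames)
  } else {
    tibble::tibble(ecg = integer(), ppg_green = integer(),
                   ppg_red = integer(), ppg_ir = integer())
  }
  events <- if (n_events > 0) {
    ev <- read_exact(con, 5 * n_events, "events")
    m <- matrix(ev, nrow = 5)
    tibble::tibble(
      sample_index = vapply(seq_len(n_events),
                            function(i) as.integer(raw_to_u32(m[1:4, i])),
                            integer(1)),
      code = as.integer(m[5, ])
    )
  } else {
    tibble::tibble(sample_index = integer(), code = integer())
  }
  trailing <- readBin(con, "raw", n = 1)
  if (length(trailing) != 0) {
    stop_io("Trailing bytes after the event table; file is corrupt.")
  }
  recording(frames, sample_rate = sample_rate, start_time_ms = start_time_ms,
            device_id = device_id, events = events)
}

#' Recording time supported by a flash memory
#'
#' Pure arithmetic: `flash_bits / (sample_rate * frame_bits)` seconds. The
#' reference hardware stores 96-bit frames (4 channels x 24 bit) at 1 kHz
#' in a 1 Gbit flash, which supports about 2.9 h — enough for one standard
#' therapy session of roughly two hours.
#'
#' @param flash_bits Flash capacity, bits.
#' @param sample_rate Sampling rate, Hz.
#' @param frame_bits Bits per sample frame (default 96).
#' @return Recording capacity in seconds.
#' @examples
#' recording_capacity(1e9, 1000, 96) / 3600   # hours
#' @export
recording_capacity <- function(flash_bits = 1e9, sample_rate = 1000,
                               frame_bits = 96) {
  check_scalar_num(flash_bits, "flash_bits", lower = 0, strict_lower = TRUE)
  check_scalar_num(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  check_scalar_num(frame_bits, "frame_bits", lower = 0, strict_lower = TRUE)
  flash_bits / (sample_rate * frame_bits)
}

#' Export a recording to CSV
#'
#' Writes one row per frame with the time in seconds
#' (`sample_index / sample_rate`) and the four integer channel columns.
#' Event markers go to a companion CSV next to the main file (suffix
#' `_events.csv`) when the recording has any.
#'
#' @param rec A [recording].
#' @param path Destination CSV path.
#' @param events_path Companion events CSV path; default derived from `path`.
#' @return Invisibly, the number of data rows written.
#' @export
export_recording_csv <- function(rec, path, events_path = NULL) {
  if (!inherits(rec, "recording")) stop_param("`rec` must be a recording.")
  fr <- rec$frames
  df <- data.frame(
    time_s = (seq_len(nrow(fr)) - 1) / rec$sample_rate,
    ecg = fr$ecg, ppg_green = fr$ppg_green,
    ppg_red = fr$ppg_red, ppg_ir = fr$ppg_ir
  )
  utils::write.csv(df, path, row.names = FALSE)
  if (nrow(rec$events)) {
    if (is.null(events_path)) {
      events_path <- sub("\\.csv$", "_events.csv", path)
      if (identical(events_path, path)) events_path <- paste0(path, "_events.csv")
    }
    ev <- data.frame(
      sample_index = rec$events$sample_index,
      time_s = rec$events$sample_index / rec$sample_rate,
      code = rec$events$code,
      label = names(event_codes)[match(rec$events$code, event_codes)]
    )
    utils::write.csv(ev, events_path, row.names = FALSE)
  }
  invisible(nrow(fr))
}

#' Import a recording from CSV
#'
#' Inverse of [export_recording_csv()] for the channel table; channel
#' values round-trip exactly because they are integer counts.
#'
#' @param path CSV path with columns `time_s`, `ecg`, `ppg_green`,
#'   `ppg_red`, `ppg_ir`.
#' @param sample_rate Sampling rate; inferred from the time column when `NULL`.
#' @param events_path Optional companion events CSV.
#' @return A [recording].
#' @export
import_recording_csv <- function(path, sample_rate = NULL, events_path = NULL) {
  if (!file.exists(path)) stop_io(sprintf("No such file: %s", path))
  df <- utils::read.csv(path)
  need <- c("time_s", "ecg", "ppg_green", "ppg_red", "ppg_ir")
  if (!all(need %in% names(df))) {
    stop_io("CSV must have columns time_s, ecg, ppg_green, ppg_red, ppg_ir.")
  }
  if (is.null(sample_rate)) {
    if (nrow(df) < 2) stop_param("Cannot infer sample_rate from fewer than 2 rows.")
    sample_rate <- round(1 / median(diff(df$time_s)))
  }
  events <- NULL
  if (!is.null(events_path) && file.exists(events_path)) {
    ev <- utils::read.csv(events_path)
    events <- tibble::tibble(sample_index = as.integer(ev$sample_index),
                             code = as.integer(ev$code))
  }
  recording(df[c("ecg", "ppg_green", "ppg_red", "ppg_ir")],
            sample_rate = sample_rate, events = events)
}
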