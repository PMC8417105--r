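# Session recording format. A session file is a small header followed by
# chunks interleaved in timestamp order: analog chunks (a run of int16 codes
# for one channel with its start tick and sample period) and record chunks
# (timestamped digital events, condition transitions, stimulus events and
# network events). Every chunk carries an Adler-32 checksum over its
# payload. The layout is an open format defined here; its fidelity target is
# the information content of the device's storage (interleaved analog data
# and timestamp records), not byte compatibility with any card image.

SESSION_MAGIC <- charToRaw("NLSE")
SESSION_VERSION <- 1L

RECORD_CLASSES <- c(digital_event = 0L, condition_transition = 1L,
                    stimulus_event = 2L, network_event = 3L)

# Adler-32 over a raw vector, computed exactly with vectorized double
# arithmetic (all intermediates stay far below 2^53)
adler32 <- function(raw) {
  b <- as.integer(raw)
  n <- length(b)
  if (n == 0L) return(1)
  s1 <- (1 + sum(b)) %% 65521
  s2 <- (n %% 65521 + sum((n - seq_len(n) + 1) * b)) %% 65521
  s2 * 65536 + s1
}

write_chunk <- function(con, type, payload) {
  writeBin(charToRaw(type), con)
  writeBin(length(payload), con, size = 4, endian = "little")
  writeBin(payload, con)
  writeBin(adler32(payload), con, size = 8, endian = "little")
}

payload_of <- function(build) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  build(con)
  rawConnectionValue(con)
}

#' Session header
#'
#' @param config The [device_config()] snapshot recorded with the session.
#' @param start_tick Session start (ticks, normally 0).
#' @param channel_map Integer channel ids present in the analog stream.
#' @return An object of class `"session_header"`.
#' @export
session_header <- function(config, start_tick = 0, channel_map = integer()) {
  structure(list(format_version = SESSION_VERSION, config = config,
                 start_tick = start_tick,
                 channel_map = as.integer(channel_map),
                 tick_us = config$timebase$tick_us),
            class = "session_header")
}

#' Analog block
#'
#' A run of consecutive samples for one channel.
#'
#' @param channel_id Channel id.
#' @param start_tick Tick of the first sample.
#' @param period_ticks Sample period in ticks.
#' @param codes Integer-valued codes (signed 16-bit range).
#' @return A list of class `"analog_block"`.
#' @export
analog_block <- function(channel_id, start_tick, period_ticks, codes) {
  if (length(codes) && (max(codes) > 32767 || min(codes) < -32768))
    stop("codes outside the signed 16-bit range", call. = FALSE)
  structure(list(channel_id = as.integer(channel_id), start_tick = start_tick,
                 period_ticks = as.integer(period_ticks),
                 codes = as.integer(codes)), class = "analog_block")
}

#' Write a session file
#'
#' Writes the header, then the analog blocks and record chunks merged in
#' timestamp order. Records are split so that each record chunk precedes the
#' analog block that starts after it.
#'
#' @param path Output file path.
#' @param header A [session_header()].
#' @param blocks List of [analog_block()]s, time-ordered per channel.
#' @param records Data frame of timestamp records: `timestamp`, `source`,
#'   `kind` (one of digital_event, condition_transition, stimulus_event,
#'   network_event) and optional integer payload columns `p1`, `p2`.
#' @return `path`, invisibly.
#' @export
write_session <- function(path, header, blocks = list(), records = NULL) {
  stopifnot(inherits(header, "session_header"))
  if (is.null(records))
    records <- data.frame(timestamp = numeric(), source = integer(),
                          kind = character())
  if (!all(records$kind %in% names(RECORD_CLASSES)))
    stop("unknown record class: ",
         paste(setdiff(unique(records$kind), names(RECORD_CLASSES)),
               collapse = ","), call. = FALSE)
  if (is.unsorted(records$timestamp))
    stop("records must be time-ordered", call. = FALSE)
  starts <- vapply(blocks, `[[`, 0, "start_tick")
  if (length(blocks) > 1L) {
    per_chan <- split(seq_along(blocks), vapply(blocks, `[[`, 0L, "channel_id"))
    for (ix in per_chan)
      if (is.unsorted(starts[ix]))
        stop("analog blocks must be time-ordered within channel", call. = FALSE)
  }
  if (is.null(records$p1)) records$p1 <- rep(0L, nrow(records))
  if (is.null(records$p2)) records$p2 <- rep(0L, nrow(records))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(SESSION_MAGIC, con)
  writeBin(SESSION_VERSION, con, size = 4, endian = "little")
  write_chunk(con, "HEAD", serialize(header, NULL, version = 3))

  # merge blocks and record groups by start timestamp
  block_order <- order(starts)
  rec_idx <- 1L; n_rec <- nrow(records)
  emit_records_upto <- function(t) {
    if (rec_idx > n_rec) return(invisible())
    take <- which(records$timestamp[rec_idx:n_rec] <= t)
    if (!length(take)) return(invisible())
    sel <- records[rec_idx:(rec_idx + max(take) - 1L), , drop = FALSE]
    rec_idx <<- rec_idx + max(take)
    write_chunk(con, "RECS", payload_of(function(c2) {
      writeBin(nrow(sel), c2, size = 4, endian = "little")
      writeBin(as.double(sel$timestamp), c2, size = 8, endian = "little")
      writeBin(as.integer(RECORD_CLASSES[sel$kind]), c2, size = 1)
      writeBin(as.integer(sel$source), c2, size = 4, endian = "little")
      writeBin(as.integer(sel$p1), c2, size = 4, endian = "little")
      writeBin(as.integer(sel$p2), c2, size = 4, endian = "little")
    }))
  }
  for (bi in block_order) {
    b <- blocks[[bi]]
    emit_records_upto(b$start_tick)
    write_chunk(con, "ANLG", payload_of(function(c2) {
      writeBin(b$channel_id, c2, size = 4, endian = "little")
      writeBin(as.double(b$start_tick), c2, size = 8, endian = "little")
      writeBin(b$period_ticks, c2, size = 4, endian = "little")
      writeBin(length(b$codes), c2, size = 4, endian = "little")
      writeBin(b$codes, c2, size = 2, endian = "little")
    }))
  }
  emit_records_upto(Inf)
  invisible(path)
}

#' Read a session file
#'
#' Exact inverse of [write_session()]: validates the magic, version and
#' every chunk checksum; a truncated file raises an error naming the last
#' valid byte offset.
#'
#' @param path Session file path.
#' @return List with `header`, `blocks` (list of [analog_block()]s) and
#'   `records` (data frame).
#' @export
read_session <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (!identical(magic, SESSION_MAGIC))
    stop("not a session file (bad magic)", call. = FALSE)
  ver <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(ver, SESSION_VERSION))
    stop("unknown session format version: ", ver, call. = FALSE)
  header <- NULL; blocks <- list(); recs <- list()
  offset <- 8
  repeat {
    type_raw <- readBin(con, "raw", 4)
    if (length(type_raw) == 0L) break
    if (length(type_raw) < 4L)
      stop("truncated file: last valid offset ", offset, call. = FALSE)
    type <- rawToChar(type_raw)
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(len) == 0L)
      stop("truncated file: last valid offset ", offset, call. = FALSE)
    payload <- readBin(con, "raw", len)
    sum_stored <- readBin(con, "double", 1, size = 8, endian = "little")
    if (length(payload) < len || length(sum_stored) == 0L)
      stop("truncated file: last valid offset ", offset, call. = FALSE)
    if (adler32(payload) != sum_stored)
      stop("checksum mismatch in ", type, " chunk at offset ", offset,
           call. = FALSE)
    pc <- rawConnection(payload, "rb")
    if (type == "HEAD") {
      header <- unserialize(payload)
    } else if (type == "ANLG") {
      ch <- readBin(pc, "integer", 1, size = 4, endian = "little")
      st <- readBin(pc, "double", 1, size = 8, endian = "little")
      per <- readBin(pc, "integer", 1, size = 4, endian = "little")
      n <- readBin(pc, "integer", 1, size = 4, endian = "little")
      codes <- readBin(pc, "integer", n, size = 2, signed = TRUE,
                       endian = "little")
      blocks[[length(blocks) + 1L]] <- analog_block(ch, st, per, codes)
    } else if (type == "RECS") {
      n <- readBin(pc, "integer", 1, size = 4, endian = "little")
      ts <- readBin(pc, "double", n, size = 8, endian = "little")
      cls <- readBin(pc, "integer", n, size = 1, signed = FALSE)
      srcv <- readBin(pc, "integer", n, size = 4, endian = "little")
      p1 <- readBin(pc, "integer", n, size = 4, endian = "little")
      p2 <- readBin(pc, "integer", n, size = 4, endian = "little")
      recs[[length(recs) + 1L]] <- data.frame(
        timestamp = ts,
        source = srcv,
        kind = names(RECORD_CLASSES)[match(cls, RECORD_CLASSES)],
        p1 = p1, p2 = p2)
    } else {
      stop("unknown chunk type '", type, "' at offset ", offset, call. = FALSE)
    }
    close(pc)
    offset <- offset + 4 + 4 + len + 8
  }
  if (is.null(header)) stop("missing header chunk", call. = FALSE)
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(timestamp = numeric(), source = integer(), kind = character(),
               p1 = integer(), p2 = integer())
  list(header = header, blocks = blocks, records = records)
}

#' Summarize a session
#'
#' Emulates the interface's summary displays: event counts per event
#' generator, stimulus counts per output pin, per-channel data envelopes
#' (min/max per time bin), and triggered data sweeps from a source channel
#' aligned on a chosen event source.
#'
#' @param session A list from [read_session()] (or a path).
#' @param n_bins Number of envelope bins over the session duration.
#' @param sweep_source Optional generator id (or `"stim"`) to align sweeps
#'   on.
#' @param sweep_channel Channel id providing the sweep data.
#' @param sweep_halfwidth_ticks Half width of each sweep window.
#' @return List with `generator_counts` (named vector, generators 0-7),
#'   `stim_counts` (named vector by output pin), `condition_transitions`,
#'   `network_counts`, `envelopes` (per channel: data frame bin start,
#'   min, max), and `sweeps` (matrix, one row per event) when requested.
#' @export
summarize_session <- function(session, n_bins = 20, sweep_source = NULL,
                              sweep_channel = NULL,
                              sweep_halfwidth_ticks = 1000) {
  if (is.character(session)) session <- read_session(session)
  rec <- session$records
  gev <- rec[rec$kind == "digital_event", , drop = FALSE]
  generator_counts <- vapply(0:7, function(g) sum(gev$source == g), 0)
  names(generator_counts) <- as.character(0:7)
  sev <- rec[rec$kind == "stimulus_event", , drop = FALSE]
  stim_counts <- vapply(0:5, function(p) sum(sev$source == p), 0)
  names(stim_counts) <- as.character(0:5)

  chans <- unique(vapply(session$blocks, `[[`, 0L, "channel_id"))
  envelopes <- list()
  for (ch in chans) {
    bl <- Filter(function(b) b$channel_id == ch, session$blocks)
    codes <- unlist(lapply(bl, `[[`, "codes"))
    t0 <- bl[[1]]$start_tick; per <- bl[[1]]$period_ticks
    t <- t0 + (seq_along(codes) - 1) * per
    bins <- cut(t, breaks = n_bins, labels = FALSE)
    envelopes[[as.character(ch)]] <- data.frame(
      bin = seq_len(n_bins),
      min = vapply(seq_len(n_bins), function(b)
        if (any(bins == b)) min(codes[bins == b]) else NA_real_, 0),
      max = vapply(seq_len(n_bins), function(b)
        if (any(bins == b)) max(codes[bins == b]) else NA_real_, 0))
  }

  sweeps <- NULL
  if (!is.null(sweep_source) && !is.null(sweep_channel)) {
    if (!identical(sweep_source, "stim") && !sweep_source %in% 0:7)
      stop("unknown sweep source ", sweep_source, call. = FALSE)
    ev_ts <- if (identical(sweep_source, "stim")) sev$timestamp
      else gev$timestamp[gev$source == sweep_source]
    bl <- Filter(function(b) b$channel_id == sweep_channel, session$blocks)
    if (!length(bl))
      stop("unknown sweep channel ", sweep_channel, call. = FALSE)
    codes <- unlist(lapply(bl, `[[`, "codes"))
    t0 <- bl[[1]]$start_tick; per <- bl[[1]]$period_ticks
    half_n <- floor(sweep_halfwidth_ticks / per)
    rows <- list()
    for (ts in ev_ts) {
      i0 <- round((ts - t0) / per) + 1
      idx <- (i0 - half_n):(i0 + half_n)
      if (idx[1] >= 1 && idx[length(idx)] <= length(codes))
        rows[[length(rows) + 1L]] <- codes[idx]
    }
    sweeps <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  list(generator_counts = generator_counts,
       stim_counts = stim_counts,
       condition_transitions = sum(rec$kind == "condition_transition"),
       network_counts = sum(rec$kind == "network_event"),
       envelopes = envelopes,
       sweeps = sweeps)
}

#' Export a session to plain-text and flat binary files
#'
#' Writes per-channel flat little-endian int16 files plus a sidecar metadata
#' text file, and the event records as a tab-separated table
#' (timestamp_ticks, source, kind).
#'
#' @param session A list from [read_session()] (or a path).
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of written file paths.
#' @export
export_session <- function(session, dir) {
  if (is.character(session)) session <- read_session(session)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  chans <- unique(vapply(session$blocks, `[[`, 0L, "channel_id"))
  meta <- c("channel\trate_sps\tn_samples\tunits")
  tick_us <- session$header$tick_us
  for (ch in chans) {
    bl <- Filter(function(b) b$channel_id == ch, session$blocks)
    codes <- unlist(lapply(bl, `[[`, "codes"))
    f <- file.path(dir, sprintf("channel_%02d.i16", ch))
    con <- file(f, "wb")
    writeBin(as.integer(codes), con, size = 2, endian = "little")
    close(con)
    out <- c(out, f)
    rate <- 1e6 / (bl[[1]]$period_ticks * tick_us)
    meta <- c(meta, sprintf("%d\t%g\t%d\tadc_code", ch, rate, length(codes)))
  }
  mf <- file.path(dir, "channels.tsv")
  writeLines(meta, mf)
  ef <- file.path(dir, "events.tsv")
  utils::write.table(session$records[, c("timestamp", "source", "kind")],
                     ef, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(out, mf, ef))
}
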