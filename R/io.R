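# Session I/O: flat little-endian binary for the LFP matrix with a
# plain-text key=value sidecar; delimited text for all tables. The
# format is deliberately self-contained (no lab-specific container).

write_keyval <- function(x, path) {
  lines <- vapply(names(x), function(k) {
    v <- x[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 17, scientific = FALSE,
                                       trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
}

read_keyval <- function(path) {
  if (!file.exists(path)) stop("format error: missing sidecar ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(" = ", lines), invert = TRUE)
  out <- lapply(kv, `[[`, 2)
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write an LFP recording
#'
#' Voltage as a flat little-endian float64 binary (sample-major: all
#' channels of sample 1, then sample 2, ...), with `lfp.meta`
#' (key = value) and `channels.tsv` sidecars.
#'
#' @param lfp an [lfp_recording()].
#' @param dir output directory (created if needed).
#' @export
write_lfp <- function(lfp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "lfp.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(lfp$voltage), con, size = 8, endian = "little")
  write_keyval(list(fs = lfp$fs, n_channels = nrow(lfp$voltage),
                    n_samples = ncol(lfp$voltage), dtype = "float64",
                    t0 = lfp$t0),
               file.path(dir, "lfp.meta"))
  write_tsv(data.frame(channel = seq_len(nrow(lfp$voltage)),
                       depth_um = lfp$channel_depth,
                       label = lfp$channel_label),
            file.path(dir, "channels.tsv"))
  invisible(dir)
}

#' Read an LFP recording written by [write_lfp()]
#' @param dir session directory.
#' @return an [lfp_recording()].
#' @export
read_lfp <- function(dir) {
  meta <- read_keyval(file.path(dir, "lfp.meta"))
  nch <- as.integer(meta$n_channels)
  ns <- as.integer(meta$n_samples)
  fsize <- file.info(file.path(dir, "lfp.bin"))$size
  if (is.na(fsize) || fsize != nch * ns * 8)
    stop("format error: lfp.bin size inconsistent with sidecar ",
         "(expected ", nch * ns * 8, " bytes, found ", fsize, ")")
  con <- file(file.path(dir, "lfp.bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = nch * ns, size = 8, endian = "little")
  ch <- read_tsv(file.path(dir, "channels.tsv"))
  lfp_recording(matrix(v, nrow = nch, ncol = ns), fs = as.numeric(meta$fs),
                channel_depth = ch$depth_um, channel_label = ch$label,
                t0 = as.numeric(meta$t0))
}

#' Write / read an event table as delimited text
#'
#' Times are printed at microsecond precision; `read_events(write_events(E))`
#' reproduces `E` (floats to 1e-6 relative).
#'
#' @param events an [event_table()].
#' @param path file path.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  df$peak_time <- sprintf("%.6f", df$peak_time)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read_tsv(path)
  if (nrow(df) == 0)
    return(event_table())
  base <- c("kind", "peak_time", "amplitude", "half_width", "channel_index")
  extra <- df[setdiff(names(df), base)]
  do.call(event_table,
          c(list(kind = df$kind, peak_time = df$peak_time,
                 amplitude = df$amplitude, half_width = df$half_width,
                 channel_index = df$channel_index),
            as.list(extra)))
}

#' Read a session directory
#'
#' Expects `lfp.bin` + sidecars, `spikes.tsv` (unit_id, spike_time,
#' region), `behavior.tsv` (+ `behavior.meta` with track_length) and
#' `stimuli.tsv`. All type invariants are validated on load.
#'
#' @param dir session directory as written by [generate_session()].
#' @return list with elements `lfp`, `spikes`, `behavior`, `stimuli`.
#' @export
read_session <- function(dir) {
  lfp <- if (file.exists(file.path(dir, "lfp.meta")))
    read_lfp(dir) else NULL
  sp <- read_tsv(file.path(dir, "spikes.tsv"))
  spikes <- spike_table(sp$unit_id, sp$spike_time, sp$region,
                        session_id = basename(dir))
  bmeta <- read_keyval(file.path(dir, "behavior.meta"))
  bh <- read_tsv(file.path(dir, "behavior.tsv"))
  behavior <- behavior_trace(bh$t, bh$position, bh$speed,
                             bh$pupil_diameter, bh$pupil_speed,
                             bh$facial_motion,
                             track_length = as.numeric(bmeta$track_length))
  st <- read_tsv(file.path(dir, "stimuli.tsv"))
  stimuli <- stimulus_log(st$onset_time, st$kind, st$duration)
  list(lfp = lfp, spikes = spikes, behavior = behavior, stimuli = stimuli)
}

#' Write the non-LFP parts of a session
#' @param spikes,behavior,stimuli the session tables.
#' @param dir output directory.
#' @export
write_session_tables <- function(spikes, behavior, stimuli, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(as.data.frame(spikes), file.path(dir, "spikes.tsv"))
  write_tsv(as.data.frame(behavior), file.path(dir, "behavior.tsv"))
  write_keyval(list(track_length = track_length(behavior)),
               file.path(dir, "behavior.meta"))
  write_tsv(as.data.frame(stimuli), file.path(dir, "stimuli.tsv"))
  invisible(dir)
}

# matrix as binary + sidecar (posteriors, peri-event tensors)
write_matrix_bin <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(m), con, size = 8, endian = "little")
  write_keyval(list(n_rows = nrow(m), n_cols = ncol(m), dtype = "float64"),
               paste0(path, ".meta"))
  invisible(path)
}

read_matrix_bin <- function(path) {
  meta <- read_keyval(paste0(path, ".meta"))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(),
               n = as.integer(meta$n_rows) * as.integer(meta$n_cols),
               size = 8, endian = "little")
  matrix(v, nrow = as.integer(meta$n_rows))
}
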