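# Fixture writers for the supported EEG file formats. These construct files
# directly from the published format layouts (BrainVision Core Format 1.0,
# EDF/EDF+, GDF 1.25) so reader tests do not depend on the package's own
# writing code.

write_bv_fixture <- function(dir, data_uv, fs, channel_names,
                             events = data.frame(sample = integer(0),
                                                 code = character(0)),
                             binary_format = c("INT_16", "IEEE_FLOAT_32"),
                             resolution = 0.1, stem = "rec") {
  binary_format <- match.arg(binary_format)
  n_ch <- nrow(data_uv)
  vhdr <- file.path(dir, paste0(stem, ".vhdr"))
  vmrk <- paste0(stem, ".vmrk")
  eeg <- paste0(stem, ".eeg")
  res <- if (binary_format == "INT_16") resolution else 1
  ch_lines <- sprintf("Ch%d=%s,,%g,µV", seq_len(n_ch), channel_names,
                      res)
  writeLines(c(
    "BrainVision Data Exchange Header File Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", eeg), paste0("MarkerFile=", vmrk),
    "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / fs, scientific = FALSE)),
    "", "[Binary Infos]", paste0("BinaryFormat=", binary_format),
    "", "[Channel Infos]", ch_lines), vhdr, useBytes = TRUE)
  mk_lines <- c("Mk1=New Segment,,1,1,0")
  if (nrow(events))
    mk_lines <- c(mk_lines,
                  sprintf("Mk%d=Stimulus,%s,%d,1,0",
                          seq_len(nrow(events)) + 1L, events$code,
                          events$sample))
  writeLines(c("BrainVision Data Exchange Marker File, Version 1.0",
               "", "[Common Infos]", "Codepage=UTF-8",
               paste0("DataFile=", eeg),
               "", "[Marker Infos]", mk_lines),
             file.path(dir, vmrk), useBytes = TRUE)
  con <- file(file.path(dir, eeg), "wb")
  on.exit(close(con))
  if (binary_format == "INT_16") {
    writeBin(as.integer(round(as.vector(data_uv) / res)), con, size = 2L,
             endian = "little")
  } else {
    writeBin(as.vector(data_uv), con, size = 4L, endian = "little")
  }
  vhdr
}

pad_field <- function(x, w) {
  s <- substr(as.character(x), 1L, w)
  paste0(s, strrep(" ", w - nchar(s)))
}

write_edf_fixture <- function(path, data_uv, fs, channel_names,
                              events = data.frame(sample = integer(0),
                                                  code = character(0)),
                              record_seconds = 1) {
  n_ch <- nrow(data_uv)
  spr <- as.integer(fs * record_seconds)
  n_rec <- as.integer(ncol(data_uv) / spr)
  stopifnot(ncol(data_uv) == n_rec * spr)
  has_annot <- TRUE
  ns <- n_ch + has_annot
  annot_spr <- 32L                               # 64 bytes of TAL per record
  phys_min <- -3277; phys_max <- 3276.9          # 0.1 uV per digit
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad_field(x, w), con, nchars = w,
                                 eos = NULL)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("EDF+C", 44); wr(n_rec, 8)
  wr(format(record_seconds), 8); wr(ns, 4)
  labs <- c(channel_names, "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(if (i <= n_ch) "uV" else "", 8)
  for (i in seq_len(ns)) wr(if (i <= n_ch) phys_min else -1, 8)
  for (i in seq_len(ns)) wr(if (i <= n_ch) phys_max else 1, 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(if (i <= n_ch) spr else annot_spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round((data_uv - phys_min) / scale + dig_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(n_ch))
      writeBin(as.integer(dig[i, cols]), con, size = 2L, endian = "little")
    # TAL block: record timestamp, then any events starting in this record
    tals <- sprintf("+%g\x14\x14", (r - 1) * record_seconds)
    ev_r <- events[events$sample > (r - 1L) * spr &
                   events$sample <= r * spr, , drop = FALSE]
    if (nrow(ev_r))
      tals <- c(tals, sprintf("+%g\x14%s\x14", (ev_r$sample - 1L) / fs,
                              ev_r$code))
    buf <- unlist(lapply(tals, function(s) c(charToRaw(s), as.raw(0))))
    buf <- c(buf, raw(2L * annot_spr - length(buf)))
    writeBin(buf, con)
  }
  path
}

write_gdf_fixture <- function(path, data_uv, fs, channel_names,
                              events = data.frame(sample = integer(0),
                                                  code = character(0)),
                              record_seconds = 1) {
  n_ch <- nrow(data_uv)
  spr <- as.integer(fs * record_seconds)
  n_rec <- as.integer(ncol(data_uv) / spr)
  stopifnot(ncol(data_uv) == n_rec * spr)
  phys_min <- -3276.8; phys_max <- 3276.7
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(x, w) writeChar(pad_field(x, w), con, nchars = w,
                                    eos = NULL)
  wint64 <- function(v) for (x in v) {
    writeBin(as.integer(x %% 2^32 - ifelse(x %% 2^32 >= 2^31, 2^32, 0)),
             con, size = 4L, endian = "little")
    writeBin(as.integer(floor(x / 2^32)), con, size = 4L, endian = "little")
  }
  wchar("GDF 1.25", 8); wchar("patient X", 80); wchar("recording X", 80)
  wchar("20200101000000", 16)
  wint64(256 + 256 * n_ch)                       # header length
  writeBin(raw(8 + 8 + 8 + 20), con)             # equipment/lab/tech/reserved
  wint64(n_rec)
  writeBin(as.integer(c(record_seconds, 1)), con, size = 4L,
           endian = "little")                    # duration num/den
  writeBin(as.integer(n_ch), con, size = 4L, endian = "little")
  for (l in channel_names) wchar(l, 16)
  for (i in seq_len(n_ch)) wchar("transducer", 80)
  for (i in seq_len(n_ch)) wchar("uV", 8)
  writeBin(rep(phys_min, n_ch), con, size = 8L, endian = "little")
  writeBin(rep(phys_max, n_ch), con, size = 8L, endian = "little")
  wint64(rep(dig_min, n_ch))
  wint64(rep(dig_max, n_ch))
  for (i in seq_len(n_ch)) wchar("none", 80)
  writeBin(rep(spr, n_ch), con, size = 4L, endian = "little")
  writeBin(rep(3L, n_ch), con, size = 4L, endian = "little")  # int16
  writeBin(raw(32L * n_ch), con)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round((data_uv - phys_min) / scale + dig_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(n_ch))
      writeBin(as.integer(dig[i, cols]), con, size = 2L, endian = "little")
  }
  # event table, mode 1: [mode:1][event fs:3][count:4][POS uint32][TYP uint16]
  writeBin(as.raw(1L), con)
  writeBin(raw(3L), con)
  writeBin(as.integer(nrow(events)), con, size = 4L, endian = "little")
  if (nrow(events)) {
    writeBin(as.integer(events$sample), con, size = 4L, endian = "little")
    writeBin(as.integer(as.integer(events$code)), con, size = 2L,
             endian = "little")
  }
  path
}
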