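#' Continuous multichannel recording
#'
#' @param data `channels x samples` matrix in microvolts.
#' @param fs sampling rate (Hz).
#' @param channel_names channel labels.
#' @param events data frame with columns `sample` (1-based sample index of
#'   the event onset) and `code` (character event code); may have zero rows.
#' @return An object of class `eeg_raw`.
#' @export
eeg_raw <- function(data, fs, channel_names, events = NULL) {
  if (!is.matrix(data) || !nrow(data) || !ncol(data))
    stop("`data` must be a non-empty channels x samples matrix")
  storage.mode(data) <- "double"
  if (fs <= 0) stop("fs must be positive")
  if (length(channel_names) != nrow(data))
    stop("channel_names length != channel count")
  if (is.null(events))
    events <- data.frame(sample = integer(0), code = character(0))
  if (nrow(events) &&
      (min(events$sample) < 1L || max(events$sample) > ncol(data)))
    stop("event sample index outside the recording")
  structure(list(data = data, fs = as.numeric(fs),
                 channel_names = as.character(channel_names),
                 events = events), class = "eeg_raw")
}

#' @export
print.eeg_raw <- function(x, ...) {
  cat(sprintf("<eeg_raw> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

#' Read a continuous EEG recording
#'
#' Supported formats: BrainVision triplets (`.vhdr`/`.vmrk`/`.eeg`,
#' multiplexed binary `INT_16` or `IEEE_FLOAT_32`), classic EDF / EDF+
#' (16-bit, with timestamped annotation parsing), and GDF 1.x. Samples are
#' scaled to microvolts using the per-channel calibration stored in the file.
#'
#' @param path path to the header file (`.vhdr`, `.edf`, or `.gdf`).
#' @param format one of `"brainvision"`, `"edf"`, `"gdf"`; inferred from the
#'   extension when omitted.
#' @return An [eeg_raw()] object.
#' @export
read_raw <- function(path, format = c("auto", "brainvision", "gdf", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     vhdr = "brainvision", gdf = "gdf", edf = "edf",
                     stop("cannot infer format from extension of ", path,
                          "; pass `format`"))
  }
  switch(format,
         brainvision = read_brainvision(path),
         gdf = read_gdf(path),
         edf = read_edf(path))
}

unit_to_uv <- function(u) {
  u <- trimws(u)
  if (u %in% c("", "µV", "uV", "μV")) 1
  else if (u == "mV") 1e3
  else if (u == "V") 1e6
  else stop("unsupported physical unit '", u, "' (expected V, mV or uV)")
}

# ---------------------------------------------------------------- BrainVision

parse_ini <- function(lines) {
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- character(0)
    } else if (grepl("=", ln, fixed = TRUE) && !is.null(sec)) {
      kv <- sub("=", "\x01", ln)
      kv <- strsplit(kv, "\x01", fixed = TRUE)[[1L]]
      out[[sec]][trimws(kv[1L])] <- trimws(paste(kv[-1L], collapse = ""))
    }
  }
  out
}

ini_get <- function(ini, section, key, file) {
  v <- ini[[section]][key]
  if (is.null(v) || is.na(v))
    stop("BrainVision header ", file, " lacks [", section, "] ", key)
  unname(v)
}

read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  if (!length(lines) || !grepl("Brain ?Vision", lines[1L], ignore.case = TRUE))
    stop("not a BrainVision header (missing identification line): ",
         vhdr_path)
  ini <- parse_ini(lines)
  dirn <- dirname(vhdr_path)
  data_file <- file.path(dirn, ini_get(ini, "Common Infos", "DataFile",
                                       vhdr_path))
  marker_file <- ini[["Common Infos"]]["MarkerFile"]
  n_ch <- as.integer(ini_get(ini, "Common Infos", "NumberOfChannels",
                             vhdr_path))
  samp_int <- as.numeric(ini_get(ini, "Common Infos", "SamplingInterval",
                                 vhdr_path))          # microseconds
  fs <- 1e6 / samp_int
  orient <- ini_get(ini, "Common Infos", "DataOrientation", vhdr_path)
  if (toupper(orient) != "MULTIPLEXED")
    stop("unsupported DataOrientation '", orient, "' in ", vhdr_path)
  fmt <- ini_get(ini, "Common Infos", "DataFormat", vhdr_path)
  if (toupper(fmt) != "BINARY")
    stop("unsupported DataFormat '", fmt, "' in ", vhdr_path)
  binfmt <- ini_get(ini, "Binary Infos", "BinaryFormat", vhdr_path)

  ch <- ini[["Channel Infos"]]
  if (is.null(ch) || length(ch) < n_ch)
    stop("BrainVision header ", vhdr_path, " lacks Channel Infos for all ",
         n_ch, " channels")
  names_res <- lapply(seq_len(n_ch), function(i) {
    ent <- ch[paste0("Ch", i)]
    if (is.na(ent)) stop("missing Channel Infos entry Ch", i, " in ",
                         vhdr_path)
    parts <- strsplit(ent, ",", fixed = TRUE)[[1L]]
    res <- if (length(parts) >= 3L && nzchar(trimws(parts[3L])))
      as.numeric(parts[3L]) else 1
    unit <- if (length(parts) >= 4L) parts[4L] else ""
    list(name = trimws(parts[1L]), scale = res * unit_to_uv(unit))
  })

  if (!file.exists(data_file)) stop("missing data file ", data_file)
  sz <- file.info(data_file)$size
  bytes <- switch(toupper(binfmt), INT_16 = 2L, IEEE_FLOAT_32 = 4L,
                  stop("unsupported BinaryFormat '", binfmt, "' in ",
                       vhdr_path))
  n_samp <- as.integer(sz %/% (bytes * n_ch))
  if (n_samp < 1L) stop("data file ", data_file, " is truncated or empty")
  con <- file(data_file, "rb")
  on.exit(close(con))
  raw_vals <- if (bytes == 2L)
    readBin(con, "integer", n = n_ch * n_samp, size = 2L, signed = TRUE,
            endian = "little")
  else readBin(con, "double", n = n_ch * n_samp, size = 4L,
               endian = "little")
  if (length(raw_vals) != n_ch * n_samp)
    stop("data file ", data_file, " is truncated")
  data <- matrix(as.numeric(raw_vals), nrow = n_ch)   # multiplexed: ch fastest
  scales <- vapply(names_res, `[[`, numeric(1), "scale")
  data <- data * scales

  events <- data.frame(sample = integer(0), code = character(0))
  if (!is.null(marker_file) && !is.na(marker_file)) {
    mpath <- file.path(dirn, unname(marker_file))
    if (file.exists(mpath)) {
      mk <- parse_ini(readLines(mpath, warn = FALSE))[["Marker Infos"]]
      if (!is.null(mk) && length(mk)) {
        parsed <- lapply(unname(mk), function(ent) {
          parts <- strsplit(ent, ",", fixed = TRUE)[[1L]]
          list(code = trimws(parts[2L]), sample = as.integer(parts[3L]))
        })
        events <- data.frame(
          sample = vapply(parsed, `[[`, integer(1), "sample"),
          code = vapply(parsed, `[[`, character(1), "code"))
      }
    }
  }
  eeg_raw(data, fs, vapply(names_res, `[[`, character(1), "name"), events)
}

# ------------------------------------------------------------------------ EDF

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rchar <- function(n) {
    s <- readBin(con, "raw", n)
    trimws(rawToChar(s[s != as.raw(0)]))
  }
  version <- rchar(8L)
  if (!identical(version, "0"))
    stop("not an EDF file (version field '", version, "'): ", path)
  rchar(80L); rchar(80L); rchar(8L); rchar(8L)       # patient/recording/date
  header_bytes <- as.integer(rchar(8L))
  rchar(44L)
  n_rec <- as.integer(rchar(8L))
  rec_dur <- as.numeric(rchar(8L))
  ns <- as.integer(rchar(4L))
  if (is.na(ns) || ns < 1L) stop("EDF header field ns is invalid in ", path)
  fld <- function(w) vapply(seq_len(ns), function(i) rchar(w), character(1))
  labels <- fld(16L); fld(80L)
  phys_dim <- fld(8L)
  phys_min <- as.numeric(fld(8L)); phys_max <- as.numeric(fld(8L))
  dig_min <- as.numeric(fld(8L)); dig_max <- as.numeric(fld(8L))
  fld(80L)
  spr <- as.integer(fld(8L))
  fld(32L)
  seek(con, header_bytes)

  is_annot <- labels == "EDF Annotations"
  sig <- which(!is_annot)
  if (!length(sig)) stop("EDF file has no signal channels: ", path)
  if (length(unique(spr[sig])) != 1L)
    stop("EDF signals with mixed sampling rates are not supported: ", path)
  if (rec_dur <= 0) stop("EDF header field 'duration of a data record' is ",
                         "invalid in ", path)
  fs <- spr[sig[1L]] / rec_dur
  if (n_rec < 0L) stop("EDF header has unknown record count in ", path)

  per_rec <- sum(spr)
  vals <- readBin(con, "integer", n = per_rec * n_rec, size = 2L,
                  signed = TRUE, endian = "little")
  if (length(vals) != per_rec * n_rec)
    stop("EDF data truncated (expected ", per_rec * n_rec, " samples): ",
         path)
  offs <- c(0L, cumsum(spr))
  data <- matrix(0, length(sig), spr[sig[1L]] * n_rec)
  ann_text <- character(0)
  for (r in seq_len(n_rec)) {
    base <- (r - 1L) * per_rec
    for (j in seq_along(sig)) {
      i <- sig[j]
      x <- vals[(base + offs[i] + 1L):(base + offs[i] + spr[i])]
      data[j, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- x
    }
    for (i in which(is_annot)) {
      x <- vals[(base + offs[i] + 1L):(base + offs[i] + spr[i])]
      b <- writeBin(as.integer(x), raw(), size = 2L, endian = "little")
      # TALs are separated by NUL bytes; keep them apart before decoding
      tal_raw <- split(b, cumsum(b == as.raw(0)))
      ann_text <- c(ann_text, vapply(tal_raw, function(tr)
        rawToChar(tr[tr != as.raw(0)]), character(1)))
    }
  }
  gain <- (phys_max[sig] - phys_min[sig]) / (dig_max[sig] - dig_min[sig])
  uv <- vapply(phys_dim[sig], unit_to_uv, numeric(1))
  data <- (data - dig_min[sig]) * gain + phys_min[sig]
  data <- data * uv

  events <- data.frame(sample = integer(0), code = character(0))
  if (length(ann_text)) {
    tals <- ann_text[nzchar(ann_text)]
    ev <- list()
    for (tal in tals) {
      parts <- strsplit(tal, "\x14", fixed = TRUE)[[1L]]
      onset <- suppressWarnings(as.numeric(sub("\x15.*$", "", parts[1L])))
      if (is.na(onset) || length(parts) < 2L) next
      for (txt in parts[-1L]) {
        txt <- trimws(txt)
        if (nzchar(txt))
          ev[[length(ev) + 1L]] <- list(sample = as.integer(round(onset * fs)) + 1L,
                                        code = txt)
      }
    }
    if (length(ev))
      events <- data.frame(sample = vapply(ev, `[[`, integer(1), "sample"),
                           code = vapply(ev, `[[`, character(1), "code"))
  }
  eeg_raw(data, fs, labels[sig], events)
}

# ------------------------------------------------------------------------ GDF

read_gdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rchar <- function(n) {
    s <- readBin(con, "raw", n)
    trimws(rawToChar(s[s != as.raw(0)]))
  }
  rint64 <- function(n = 1L) {
    # little-endian int64 read as two uint32 words (values here are small)
    lo <- readBin(con, "integer", n * 2L, size = 4L, endian = "little")
    lo <- matrix(lo, 2L)
    ifelse(lo[1L, ] < 0, lo[1L, ] + 2^32, lo[1L, ]) + lo[2L, ] * 2^32
  }
  version <- rchar(8L)
  if (!grepl("^GDF 1\\.", version))
    stop("unsupported GDF version '", version, "' in ", path,
         " (GDF 1.x supported)")
  rchar(80L); rchar(80L); rchar(16L)
  rint64()                                            # header length
  readBin(con, "raw", 8L + 8L + 8L + 20L)             # equipment/lab/tech/res
  n_rec <- rint64()
  dur <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  ns <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (is.na(ns) || ns < 1L) stop("GDF header field ns is invalid in ", path)
  rec_dur <- dur[1L] / dur[2L]

  labels <- vapply(seq_len(ns), function(i) rchar(16L), character(1))
  for (i in seq_len(ns)) rchar(80L)
  phys_dim <- vapply(seq_len(ns), function(i) rchar(8L), character(1))
  phys_min <- readBin(con, "double", ns, size = 8L, endian = "little")
  phys_max <- readBin(con, "double", ns, size = 8L, endian = "little")
  dig_min <- rint64(ns)
  dig_max <- rint64(ns)
  dig_min <- ifelse(dig_min >= 2^63, dig_min - 2^64, dig_min)
  dig_max <- ifelse(dig_max >= 2^63, dig_max - 2^64, dig_max)
  for (i in seq_len(ns)) rchar(80L)
  spr <- readBin(con, "integer", ns, size = 4L, endian = "little")
  ctype <- readBin(con, "integer", ns, size = 4L, endian = "little")
  readBin(con, "raw", 32L * ns)

  if (length(unique(spr)) != 1L)
    stop("GDF signals with mixed sampling rates are not supported: ", path)
  fs <- spr[1L] / rec_dur
  read_rec_ch <- function(type, n) {
    switch(as.character(type),
           "3" = readBin(con, "integer", n, size = 2L, signed = TRUE,
                         endian = "little"),
           "16" = readBin(con, "double", n, size = 4L, endian = "little"),
           "17" = readBin(con, "double", n, size = 8L, endian = "little"),
           stop("unsupported GDF channel type ", type, " in ", path))
  }
  data <- matrix(0, ns, spr[1L] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      x <- read_rec_ch(ctype[i], spr[i])
      if (length(x) != spr[i]) stop("GDF data truncated in ", path)
      data[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- x
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  uv <- vapply(phys_dim, unit_to_uv, numeric(1))
  data <- ((data - dig_min) * gain + phys_min) * uv

  # event table: mode(1), event sample rate (3 bytes), count (uint32),
  # then POS[uint32], TYP[uint16], and for mode 3 also CHN/DUR
  events <- data.frame(sample = integer(0), code = character(0))
  mode <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
  if (length(mode)) {
    readBin(con, "raw", 3L)
    nev <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(nev) && nev > 0L) {
      pos <- readBin(con, "integer", nev, size = 4L, endian = "little")
      typ <- readBin(con, "integer", nev, size = 2L, signed = FALSE,
                     endian = "little")
      if (length(pos) != nev || length(typ) != nev)
        stop("GDF event table truncated in ", path)
      events <- data.frame(sample = as.integer(pos),
                           code = as.character(typ))
    }
  }
  eeg_raw(data, fs, labels, events)
}

# ---------------------------------------------------------------- epoching

#' Extract cue-locked epochs from a continuous recording
#'
#' Cuts one trial per matching cue event, covering the half-open window
#' `[cue + t_start, cue + t_end)` seconds, i.e. exactly
#' `round((t_end - t_start) * fs)` samples starting at the cue sample plus
#' `round(t_start * fs)`.
#'
#' @param raw an [eeg_raw()].
#' @param cue_codes named integer vector mapping event code strings to class
#'   indices (`1..M`); events with other codes are ignored.
#' @param t_start,t_end epoch window in seconds relative to the cue
#'   (`t_end > t_start`).
#' @param class_names optional class names (defaults to the cue code names
#'   in class-index order).
#' @return An [eeg_epochs()].
#' @export
extract_epochs <- function(raw, cue_codes, t_start, t_end,
                           class_names = NULL) {
  stopifnot(inherits(raw, "eeg_raw"))
  if (t_end <= t_start) stop("t_end must exceed t_start")
  if (is.null(names(cue_codes)) || !length(cue_codes))
    stop("cue_codes must be a named vector (code -> class index)")
  hits <- raw$events[raw$events$code %in% names(cue_codes), , drop = FALSE]
  if (!nrow(hits))
    stop("no events match the cue codes (",
         paste(names(cue_codes), collapse = ", "), ")")
  win <- as.integer(round((t_end - t_start) * raw$fs))
  off <- as.integer(round(t_start * raw$fs))
  n_samp_rec <- ncol(raw$data)
  data <- array(0, c(nrow(raw$data), win, nrow(hits)))
  labels <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    a <- hits$sample[i] + off
    b <- a + win - 1L
    if (a < 1L || b > n_samp_rec)
      stop("epoch window for trial ", i, " (samples ", a, "..", b,
           ") exceeds the recording bounds [1, ", n_samp_rec, "]")
    data[, , i] <- raw$data[, a:b]
    labels[i] <- cue_codes[[hits$code[i]]]
  }
  m <- max(cue_codes)
  if (is.null(class_names)) {
    class_names <- vapply(seq_len(m), function(cl) {
      nm <- names(cue_codes)[cue_codes == cl]
      if (length(nm)) nm[1L] else paste0("class", cl)
    }, character(1))
  }
  eeg_epochs(data, labels, raw$fs, class_names, raw$channel_names)
}
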