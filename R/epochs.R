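#' Epoched multichannel EEG
#'
#' An `eeg_epochs` object holds a set of labelled, cue-locked EEG trials that
#' all share one channel layout and one sampling rate. It is the common
#' currency passed between every stage of the pipeline: preprocessing, the
#' domain transforms, cropping and cross-validation all consume and produce
#' this container.
#'
#' @param data numeric array of dimension `channels x samples x trials`,
#'   in microvolts.
#' @param labels integer vector of per-trial class indices in `1..n_classes`.
#' @param fs sampling rate in Hz.
#' @param class_names character vector naming the classes; its length defines
#'   `n_classes`.
#' @param channel_names optional character vector of channel labels; defaults
#'   to `"ch1"`, `"ch2"`, ...
#'
#' @return An object of class `eeg_epochs` with fields `data`, `labels`,
#'   `fs`, `class_names`, `channel_names`.
#' @export
eeg_epochs <- function(data, labels, fs, class_names, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (channels x samples x trials)")
  storage.mode(data) <- "double"
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[3L])
    stop("length(labels) (", length(labels), ") != number of trials (",
         dim(data)[3L], ")")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  class_names <- as.character(class_names)
  m <- length(class_names)
  if (m < 1L) stop("need at least one class name")
  if (length(labels) && (min(labels) < 1L || max(labels) > m))
    stop("labels must lie in 1..", m)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[1L]))
  if (length(channel_names) != dim(data)[1L])
    stop("channel_names length != channel count")
  structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         class_names = class_names,
         channel_names = as.character(channel_names)),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[3L], d[1L], d[2L], x$fs))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names),
                      labels = x$class_names))
  cat("  classes:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname eeg_epochs
#' @param x an `eeg_epochs` object.
#' @export
n_trials <- function(x) dim(x$data)[3L]

#' @rdname eeg_epochs
#' @export
n_channels <- function(x) dim(x$data)[1L]

#' @rdname eeg_epochs
#' @export
n_samples <- function(x) dim(x$data)[2L]

#' Subset trials of an epoch set
#'
#' @param x an `eeg_epochs` object.
#' @param trials integer indices of the trials to keep (in the given order).
#' @return An `eeg_epochs` with only those trials.
#' @export
subset_trials <- function(x, trials) {
  stopifnot(inherits(x, "eeg_epochs"))
  trials <- as.integer(trials)
  if (length(trials) && (min(trials) < 1L || max(trials) > n_trials(x)))
    stop("trial index out of range")
  eeg_epochs(x$data[, , trials, drop = FALSE], x$labels[trials], x$fs,
             x$class_names, x$channel_names)
}

#' Domain representation of an epoch set
#'
#' A `domain_tensor` is an epoch set re-expressed in one of the model's three
#' input domains. The time domain is the (preprocessed) signal itself, the
#' spatial domain is the CSP projection `Z = W E`, and the phase domain is the
#' per-channel instantaneous phase. The tensor keeps the trial/channel/sample
#' geometry of its source so the three domains stay aligned sample for sample.
#'
#' @param data numeric array `channels x samples x trials`.
#' @param domain one of `"time"`, `"spatial"`, `"phase"`.
#' @param fs sampling rate in Hz.
#' @return An object of class `domain_tensor`.
#' @export
domain_tensor <- function(data, domain = c("time", "spatial", "phase"), fs) {
  domain <- match.arg(domain)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array")
  storage.mode(data) <- "double"
  structure(list(data = data, domain = domain, fs = as.numeric(fs)),
            class = "domain_tensor")
}

#' @export
print.domain_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<domain_tensor:%s> %d trials x %d channels x %d samples @ %g Hz\n",
              x$domain, d[3L], d[1L], d[2L], x$fs))
  invisible(x)
}

#' Re-express preprocessed epochs as the time-domain input
#'
#' Identity on the data; tags the tensor so downstream stages can check the
#' three domains are aligned.
#'
#' @param epochs an `eeg_epochs` object.
#' @return A `domain_tensor` with `domain = "time"`.
#' @export
time_domain <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  domain_tensor(epochs$data, "time", epochs$fs)
}

BUNDLE_MAGIC <- "MDBCI-BUNDLE"
BUNDLE_VERSION <- 1L

#' Save / load an epoch set as a single-file bundle
#'
#' The bundle is a gzip-compressed container with a one-line JSON metadata
#' header (format version, sampling rate, class and channel names, labels,
#' tensor dimensions) followed by the raw little-endian doubles of the data
#' tensor. `load_bundle(save_bundle(x))` reproduces every field bit-exactly.
#'
#' @param epochs an `eeg_epochs` object.
#' @param path file path to write / read.
#' @return `save_bundle` returns `path` invisibly; `load_bundle` returns the
#'   reconstructed `eeg_epochs`.
#' @export
save_bundle <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  meta <- list(magic = BUNDLE_MAGIC, version = BUNDLE_VERSION,
               fs = epochs$fs, dims = dim(epochs$data),
               labels = epochs$labels, class_names = epochs$class_names,
               channel_names = epochs$channel_names)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)
  writeLines(as.character(hdr), con)
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("no such bundle file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- tryCatch(readLines(con, n = 1L), error = function(e)
    stop("unreadable bundle header in ", path, ": ", conditionMessage(e)))
  meta <- tryCatch(jsonlite::fromJSON(hdr),
                   error = function(e) stop("corrupt bundle header in ", path))
  if (!identical(meta$magic, BUNDLE_MAGIC))
    stop("not an mdbci bundle: ", path)
  if (!identical(as.integer(meta$version), BUNDLE_VERSION))
    stop("bundle version mismatch: file has version ", meta$version,
         ", this build reads version ", BUNDLE_VERSION)
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  vals <- readBin(con, "double", n = n, size = 8L, endian = "little")
  if (length(vals) != n)
    stop("truncated bundle: expected ", n, " values, got ", length(vals))
  eeg_epochs(array(vals, dims), as.integer(meta$labels), meta$fs,
             meta$class_names, meta$channel_names)
}
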