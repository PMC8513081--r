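#' Frequency-filter specification
#'
#' Describes a Butterworth IIR filter as used in EEG preprocessing: a 4-40 Hz
#' band-pass, a 38 Hz low-pass, or a power-line notch (band-stop). The order
#' is the design order of the one-directional filter; with
#' `zero_phase = TRUE` the filter is applied forward and backward, which
#' doubles the effective magnitude order and cancels the group delay.
#'
#' @param kind `"bandpass"`, `"lowpass"`, or `"notch"`.
#' @param band band edges in Hz: length-2 `(low, high)` for bandpass, a single
#'   cutoff for lowpass, the center frequency for notch.
#' @param order design order (default 4).
#' @param zero_phase apply forward-backward (default `TRUE`).
#' @param notch_halfwidth half-width of the notch stop band in Hz (default 2).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "lowpass", "notch"), band,
                        order = 4L, zero_phase = TRUE, notch_halfwidth = 2) {
  kind <- match.arg(kind)
  if (order < 1L) stop("order must be >= 1")
  band <- as.numeric(band)
  nb <- switch(kind, bandpass = 2L, lowpass = 1L, notch = 1L)
  if (length(band) != nb)
    stop(kind, " filter needs ", nb, " band value(s)")
  if (any(band <= 0)) stop("band edges must be positive")
  if (kind == "bandpass" && band[1L] >= band[2L])
    stop("bandpass low edge must be below the high edge")
  structure(list(kind = kind, band = band, order = as.integer(order),
                 zero_phase = zero_phase, notch_halfwidth = notch_halfwidth),
            class = "filter_spec")
}

# Zero-phase IIR filtering with odd-reflection edge padding. Plain
# forward-backward filtering from rest states rings at both edges; reflecting
# the signal about its endpoints before filtering suppresses the transient.
zero_phase_filter <- function(filt, x) {
  nf <- max(length(filt$b), length(filt$a))
  pad <- min(3L * nf, length(x) - 1L)
  head_pad <- 2 * x[1L] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - pad)]
  xe <- c(head_pad, x, tail_pad)
  y <- signal::filter(filt, xe)
  y <- rev(as.numeric(signal::filter(filt, rev(y))))
  y[(pad + 1L):(pad + length(x))]
}

butter_for <- function(spec, fs) {
  nyq <- fs / 2
  edges <- switch(spec$kind,
    bandpass = spec$band,
    lowpass = spec$band,
    notch = c(spec$band - spec$notch_halfwidth,
              spec$band + spec$notch_halfwidth))
  if (any(edges >= nyq))
    stop("filter edge ", max(edges), " Hz is at or above Nyquist (", nyq,
         " Hz)")
  type <- switch(spec$kind, bandpass = "pass", lowpass = "low",
                 notch = "stop")
  signal::butter(spec$order, edges / nyq, type = type)
}

#' Filter every channel of every trial
#'
#' Designs the Butterworth filter described by `spec` for the epoch sampling
#' rate and applies it along time to each channel of each trial. Zero-phase
#' specs are applied forward-backward (via [signal::filter()] with
#' odd-reflection padding), leaving the passband phase untouched.
#'
#' @param epochs an `eeg_epochs`.
#' @param spec a [filter_spec()].
#' @return The filtered `eeg_epochs` (same shape).
#' @export
apply_filter <- function(epochs, spec) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(spec, "filter_spec"))
  bf <- butter_for(spec, epochs$fs)
  d <- dim(epochs$data)
  out <- epochs$data
  for (i in seq_len(d[3L]))
    for (c in seq_len(d[1L])) {
      x <- epochs$data[c, , i]
      out[c, , i] <- if (spec$zero_phase) zero_phase_filter(bf, x)
                     else as.numeric(signal::filter(bf, x))
    }
  eeg_epochs(out, epochs$labels, epochs$fs, epochs$class_names,
             epochs$channel_names)
}

#' Downsample epochs to a target rate
#'
#' Anti-alias filters (zero-phase 4th-order Butterworth low-pass at 80% of
#' the target Nyquist) and then decimates. The source rate must be an integer
#' multiple of the target rate, which covers the standard 500 to 250 Hz
#' reduction; `target_fs = fs` is the identity.
#'
#' @param epochs an `eeg_epochs`.
#' @param target_fs target sampling rate (Hz), `<= fs`.
#' @return The resampled `eeg_epochs` with `samples * target_fs / fs` samples.
#' @export
resample_epochs <- function(epochs, target_fs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (target_fs <= 0) stop("target_fs must be positive")
  if (target_fs > epochs$fs) stop("target_fs exceeds the current rate")
  if (target_fs == epochs$fs) return(epochs)
  r <- epochs$fs / target_fs
  if (abs(r - round(r)) > 1e-9)
    stop("source rate (", epochs$fs, " Hz) is not an integer multiple of ",
         target_fs, " Hz")
  r <- as.integer(round(r))
  aa <- filter_spec("lowpass", band = 0.8 * target_fs / 2, order = 4L,
                    zero_phase = TRUE)
  low <- apply_filter(epochs, aa)
  idx <- seq(1L, n_samples(epochs), by = r)
  eeg_epochs(low$data[, idx, , drop = FALSE], epochs$labels, target_fs,
             epochs$class_names, epochs$channel_names)
}

#' Per-channel z-score normalization of a domain tensor
#'
#' Scales a domain before it enters the network. Statistics (per-channel mean
#' and standard deviation over all trials and samples) are computed on the
#' fitting set when `stats` is `NULL` and returned, so they can be frozen and
#' re-applied to held-out trials without leaking test data into the scaling.
#' Zero-variance channels are clamped to a small epsilon with a warning.
#'
#' @param tensor a `domain_tensor`.
#' @param stats optional precomputed list with `mean` and `sd` per channel
#'   (as returned by a previous call).
#' @param eps clamp for zero standard deviations.
#' @return A list with `tensor` (normalized) and `stats`.
#' @export
normalize_domain <- function(tensor, stats = NULL, eps = 1e-12) {
  stopifnot(inherits(tensor, "domain_tensor"))
  d <- dim(tensor$data)
  if (is.null(stats)) {
    flat <- matrix(tensor$data, nrow = d[1L])     # channels x (samples*trials)
    mu <- rowMeans(flat)
    sdv <- sqrt(rowMeans((flat - mu)^2))
    if (any(sdv < eps)) {
      warning("zero-variance channel(s): ",
              paste(which(sdv < eps), collapse = ", "),
              "; scale clamped to eps")
      sdv[sdv < eps] <- eps
    }
    stats <- list(mean = mu, sd = sdv)
  }
  out <- (tensor$data - stats$mean) / stats$sd      # recycles over dims 2,3
  list(tensor = domain_tensor(array(out, d), tensor$domain, tensor$fs),
       stats = stats)
}
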