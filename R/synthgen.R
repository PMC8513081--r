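#' Default 31-channel montage
#'
#' The 10-20-system subset used by the recording setup this generator
#' emulates (reference FCz, ground AFz).
#' @return Character vector of 31 channel labels.
#' @export
montage_31 <- function() c(
  "FP1", "FP2", "F3", "F4", "F7", "F8", "FC1", "FC2", "FC5", "FC6",
  "C1", "C2", "C3", "C4", "Cz", "CP1", "CP2", "CP5", "CP6", "P3", "P4",
  "P7", "P8", "Pz", "TP9", "TP10", "O1", "O2", "Oz", "PO9", "PO10")

#' Configuration of the synthetic motor-imagery generator
#'
#' Emulates a three-class lower-limb motor-imagery recording: 31 channels
#' sampled at 500 Hz, 5-s trials, 30 trials per class. Each class adds a
#' narrow-band oscillatory signature (band-limited Gaussian noise, hence
#' randomly phased and amplitude-modulated trial by trial) on class-specific
#' scalp channels over independent 1/f background noise. The `snr_preset`
#' scales the background to mimic wet (low-noise) versus dry (high-noise,
#' high-impedance) electrodes; `dry_ratio` is the dry/wet background RMS
#' ratio.
#'
#' Default signatures sit on central motor-area channels (Cz, C1) and an
#' occipital channel (Oz) for the resting class, with distinct center
#' frequencies in the mu/beta range. `signature_kind = "broadband"` replaces
#' the oscillations by flat-spectrum variance gains on the same channels
#' (class information in power only, none in any particular rhythm).
#'
#' @param n_channels,fs,trial_seconds,n_classes,trials_per_class geometry.
#' @param signatures list (one element per class) of data frames with columns
#'   `channel`, `freq`, `bw`, `amp` (Hz, Hz, microvolt RMS).
#' @param alpha spectral exponent of the 1/f^alpha background.
#' @param background_rms wet-preset background RMS in microvolts.
#' @param snr_preset `"wet"` or `"dry"`.
#' @param dry_ratio dry/wet background RMS ratio (> 1).
#' @param signature_kind `"narrowband"` (default) or `"broadband"`.
#' @param mixing if `TRUE`, apply a random diagonally dominant channel-mixing
#'   matrix (volume-conduction-like spatial spread) to each trial.
#' @param class_names class labels.
#' @param seed RNG seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 31L, fs = 500, trial_seconds = 5,
                         n_classes = 3L, trials_per_class = 30L,
                         signatures = NULL, alpha = 1, background_rms = 10,
                         snr_preset = c("wet", "dry"), dry_ratio = 3,
                         signature_kind = c("narrowband", "broadband"),
                         mixing = FALSE,
                         class_names = c("gait", "sit", "rest"),
                         seed = 1L) {
  snr_preset <- match.arg(snr_preset)
  signature_kind <- match.arg(signature_kind)
  if (dry_ratio <= 1) stop("dry_ratio must exceed 1 (dry is noisier than wet)")
  if (is.null(signatures)) {
    # Cz = 15, C1 = 11, Oz = 29 in montage_31()
    signatures <- list(
      data.frame(channel = 15L, freq = 10, bw = 2, amp = 5),
      data.frame(channel = 11L, freq = 22, bw = 2, amp = 5),
      data.frame(channel = 29L, freq = 14, bw = 2, amp = 5))
  }
  if (length(signatures) != n_classes)
    stop("need one signature set per class")
  if (length(class_names) != n_classes)
    stop("need one class name per class")
  for (sg in signatures) {
    if (any(sg$channel < 1L | sg$channel > n_channels))
      stop("signature channel out of range 1..", n_channels)
    if (any(sg$freq <= 4 | sg$freq >= 40))
      stop("signature frequencies must lie inside (4, 40) Hz")
  }
  structure(list(
    n_channels = as.integer(n_channels), fs = fs,
    trial_seconds = trial_seconds, n_classes = as.integer(n_classes),
    trials_per_class = as.integer(trials_per_class), signatures = signatures,
    alpha = alpha, background_rms = background_rms, snr_preset = snr_preset,
    dry_ratio = dry_ratio, signature_kind = signature_kind, mixing = mixing,
    class_names = class_names, seed = as.integer(seed)),
    class = "synth_config")
}

# 1/f^alpha noise via spectral shaping, normalized to unit RMS
pink_noise <- function(n, alpha) {
  half <- floor(n / 2)
  f <- seq_len(half)                       # bin index; proportionality enough
  mag <- f^(-alpha / 2)
  re <- stats::rnorm(half) * mag
  im <- stats::rnorm(half) * mag
  spec <- complex(real = re, imaginary = im)
  if (n %% 2L == 0L) spec[half] <- complex(real = re[half], imaginary = 0)
  full <- c(0, spec,
            if (n %% 2L == 0L) Conj(rev(spec[-half])) else Conj(rev(spec)))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# band-limited Gaussian noise (hard FFT mask on [f0-bw/2, f0+bw/2]),
# normalized to unit RMS: a randomly phased, amplitude-modulated oscillation
narrowband_noise <- function(n, fs, f0, bw) {
  freqs <- (seq_len(n) - 1L) * fs / n
  freqs <- pmin(freqs, fs - freqs)         # two-sided
  mask <- freqs >= (f0 - bw / 2) & freqs <= (f0 + bw / 2)
  if (!any(mask)) stop("band too narrow for this trial length")
  spec <- stats::fft(stats::rnorm(n)) * mask
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# draws the class-signal and unit-RMS background components for all trials;
# backgrounds are scaled by the caller so wet/dry pairs share the same draw
synth_components <- function(cfg) {
  set.seed(cfg$seed)
  n_samp <- as.integer(round(cfg$trial_seconds * cfg$fs))
  n_tr <- cfg$n_classes * cfg$trials_per_class
  labels <- rep(seq_len(cfg$n_classes), each = cfg$trials_per_class)
  sig <- array(0, c(cfg$n_channels, n_samp, n_tr))
  bg <- array(0, c(cfg$n_channels, n_samp, n_tr))
  mix <- NULL
  if (isTRUE(cfg$mixing)) {
    mix <- diag(cfg$n_channels) +
      matrix(stats::rnorm(cfg$n_channels^2, sd = 0.2 / sqrt(cfg$n_channels)),
             cfg$n_channels)
  }
  for (i in seq_len(n_tr)) {
    for (c in seq_len(cfg$n_channels))
      bg[, , i][c, ] <- pink_noise(n_samp, cfg$alpha)
    sgs <- cfg$signatures[[labels[i]]]
    for (r in seq_len(nrow(sgs))) {
      comp <- if (cfg$signature_kind == "narrowband")
        narrowband_noise(n_samp, cfg$fs, sgs$freq[r], sgs$bw[r])
      else stats::rnorm(n_samp)            # broadband variance gain
      sig[sgs$channel[r], , i] <- sig[sgs$channel[r], , i] + sgs$amp[r] * comp
    }
    if (!is.null(mix)) {
      sig[, , i] <- mix %*% sig[, , i]
      bg[, , i] <- mix %*% bg[, , i]
    }
  }
  list(sig = sig, bg = bg, labels = labels, n_samp = n_samp)
}

#' Generate a synthetic epoched recording
#'
#' See [synth_config()] for what is emulated. Deterministic: the same
#' configuration (including seed) reproduces the output bit for bit.
#'
#' @param cfg a `synth_config`.
#' @return An `eeg_epochs` of `n_classes * trials_per_class` trials.
#' @export
synth_generate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  parts <- synth_components(cfg)
  scale <- cfg$background_rms *
    if (cfg$snr_preset == "dry") cfg$dry_ratio else 1
  chans <- if (cfg$n_channels == 31L) montage_31()
           else paste0("ch", seq_len(cfg$n_channels))
  eeg_epochs(parts$sig + scale * parts$bg, parts$labels, cfg$fs,
             cfg$class_names, chans)
}

#' Generate a matched wet/dry recording pair
#'
#' Both members share identical class signals and background noise draws;
#' only the background RMS differs, by `cfg$dry_ratio`. This isolates the
#' electrode-noise contrast from everything else.
#'
#' @param cfg a `synth_config`.
#' @return A list with elements `wet` and `dry`, each an `eeg_epochs`.
#' @export
synth_generate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  parts <- synth_components(cfg)
  chans <- if (cfg$n_channels == 31L) montage_31()
           else paste0("ch", seq_len(cfg$n_channels))
  wet <- eeg_epochs(parts$sig + cfg$background_rms * parts$bg, parts$labels,
                    cfg$fs, cfg$class_names, chans)
  dry <- eeg_epochs(parts$sig + cfg$background_rms * cfg$dry_ratio * parts$bg,
                    parts$labels, cfg$fs, cfg$class_names, chans)
  list(wet = wet, dry = dry)
}
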