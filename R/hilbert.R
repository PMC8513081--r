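#' Discrete Hilbert transform by direct summation
#'
#' Evaluates the classical parity-split form of the discrete Hilbert
#' transform: for even `k` the sum runs over odd `n`, and vice versa,
#' \deqn{\hat s(k) = (2/\pi) \sum_{n} s(n) / (k - n),}
#' truncated to the available samples. It is O(T^2) and edge-truncated, so it
#' serves as the literal reference construction; [analytic_signal()] with
#' `method = "fft"` is the fast equivalent used in the pipeline.
#'
#' @param s numeric vector of samples.
#' @return Numeric vector `s_hat` of the same length.
#' @export
hilbert_direct <- function(s) {
  if (!length(s)) stop("empty input")
  if (any(!is.finite(s))) stop("non-finite values in input")
  n <- length(s)
  k <- seq_len(n) - 1L                 # 0-based indices carry the parity
  even <- k %% 2L == 0L
  # kernel matrix 1/(k-n) restricted to opposite parity; diagonal parity
  # always differs so k == n never contributes
  km <- outer(k, k, "-")
  inv <- array(0, dim(km))
  off <- km != 0L
  inv[off] <- 1 / km[off]
  parity <- outer(even, !even, "&") | outer(!even, even, "&")
  inv[!parity] <- 0
  (2 / pi) * as.vector(inv %*% s)
}

#' Analytic signal, amplitude and instantaneous phase
#'
#' Builds the complex analytic signal `z(k) = s(k) + i s_hat(k)` of a real
#' signal and derives the instantaneous amplitude `A(k) = |z(k)|` and the
#' wrapped instantaneous phase `phi(k) = atan2(Im z, Re z)` in `(-pi, pi]`.
#' `method = "fft"` uses the discrete analytic-signal construction (negative
#' frequencies zeroed, positive doubled, DC and Nyquist kept); `"direct"`
#' uses the O(T^2) summation of [hilbert_direct()].
#'
#' @param s numeric vector, length >= 4.
#' @param method `"fft"` (default) or `"direct"`.
#' @return A list of class `analytic_signal` with `real`, `imag`,
#'   `amplitude`, `phase`.
#' @export
analytic_signal <- function(s, method = c("fft", "direct")) {
  method <- match.arg(method)
  if (length(s) < 4L) stop("need at least 4 samples")
  if (any(!is.finite(s))) stop("non-finite values in input")
  if (method == "fft") {
    n <- length(s)
    h <- numeric(n)
    if (n %% 2L == 0L) {
      h[c(1L, n / 2L + 1L)] <- 1
      h[2L:(n / 2L)] <- 2
    } else {
      h[1L] <- 1
      h[2L:((n + 1L) / 2L)] <- 2
    }
    z <- stats::fft(stats::fft(s) * h, inverse = TRUE) / n
    sh <- Im(z)
  } else {
    sh <- hilbert_direct(s)
  }
  ph <- atan2(sh, s)
  ph[ph <= -pi] <- pi                  # wrap convention (-pi, pi]
  structure(list(real = as.numeric(s), imag = sh,
                 amplitude = sqrt(s^2 + sh^2), phase = ph),
            class = "analytic_signal")
}

#' Phase-domain representation of an epoch set
#'
#' Replaces every channel of every trial by its wrapped instantaneous phase,
#' obtained from the analytic signal of the full trial. The geometry is
#' preserved, so phase crops stay aligned with the time- and spatial-domain
#' crops of the same trial.
#'
#' @param epochs an `eeg_epochs` (band-limited input expected).
#' @param method passed to [analytic_signal()].
#' @return A `domain_tensor` with `domain = "phase"` holding phase in
#'   radians, wrapped to `(-pi, pi]`.
#' @export
phase_domain <- function(epochs, method = "fft") {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  out <- array(0, d)
  for (i in seq_len(d[3L]))
    for (c in seq_len(d[1L]))
      out[c, , i] <- analytic_signal(epochs$data[c, , i], method)$phase
  domain_tensor(out, "phase", epochs$fs)
}
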