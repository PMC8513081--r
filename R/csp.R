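#' Per-class trial covariance estimates
#'
#' Each trial's spatial covariance is normalized by its trace,
#' `C = X X' / tr(X X')`, which removes trial-to-trial amplitude differences;
#' the class covariance is the mean of its trials' normalized covariances and
#' class priors are the empirical class frequencies.
#'
#' @param epochs an `eeg_epochs` with at least two trials per class.
#' @return A list with `covs` (list of `channels x channels` matrices, one per
#'   class) and `priors` (numeric vector summing to 1).
#' @export
estimate_class_covs <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  m <- length(epochs$class_names)
  counts <- tabulate(epochs$labels, nbins = m)
  if (any(counts < 2L))
    stop("class '", epochs$class_names[which.min(counts)],
         "' has fewer than 2 trials")
  n <- n_channels(epochs)
  covs <- lapply(seq_len(m), function(cl) {
    idx <- which(epochs$labels == cl)
    acc <- matrix(0, n, n)
    for (i in idx) {
      x <- epochs$data[, , i]
      cc <- tcrossprod(x)
      acc <- acc + cc / sum(diag(cc))
    }
    acc / length(idx)
  })
  list(covs = covs, priors = counts / sum(counts))
}

# One sweep of Jacobi-style joint diagonalization (Cardoso-Souloumiac
# rotations) of a list of symmetric matrices; returns the updated matrices
# and the accumulated orthogonal rotation.
jad_sweep <- function(mats, V, tol) {
  n <- nrow(mats[[1L]])
  rotated <- FALSE
  for (p in seq_len(n - 1L)) {
    for (q in (p + 1L):n) {
      # closed-form Givens angle maximizing the summed squared diagonals
      h <- vapply(mats, function(A)
        c(A[p, p] - A[q, q], 2 * A[p, q]), numeric(2))
      G <- tcrossprod(h)               # 2x2
      e <- eigen(G, symmetric = TRUE)
      v <- e$vectors[, 1L]
      if (v[1L] < 0) v <- -v
      cth <- sqrt((v[1L] + 1) / 2)
      sth <- v[2L] / (2 * cth)
      if (abs(sth) > tol) {
        rotated <- TRUE
        R <- matrix(c(cth, sth, -sth, cth), 2L, 2L)   # [[c, -s], [s, c]]
        for (i in seq_along(mats)) {
          A <- mats[[i]]
          A[, c(p, q)] <- A[, c(p, q)] %*% R
          A[c(p, q), ] <- t(R) %*% A[c(p, q), ]
          mats[[i]] <- A
        }
        V[, c(p, q)] <- V[, c(p, q)] %*% R
      }
    }
  }
  list(mats = mats, V = V, rotated = rotated)
}

#' Joint approximate diagonalization of symmetric matrices
#'
#' Finds an orthogonal `V` that simultaneously (approximately) diagonalizes a
#' set of symmetric matrices by sweeps of Givens rotations with the
#' closed-form Cardoso-Souloumiac angle. For two matrices that commute after
#' whitening the result is exact to machine precision.
#'
#' @param mats list of symmetric matrices of equal dimension.
#' @param tol rotation threshold for convergence.
#' @param max_sweeps sweep cap.
#' @return List with the orthogonal matrix `V` and `mats`, the rotated
#'   (near-diagonal) matrices `V' A V`.
#' @export
joint_diag <- function(mats, tol = 1e-12, max_sweeps = 100L) {
  n <- nrow(mats[[1L]])
  V <- diag(n)
  mats <- lapply(mats, function(A) (A + t(A)) / 2)
  for (s in seq_len(max_sweeps)) {
    st <- jad_sweep(mats, V, tol)
    mats <- st$mats; V <- st$V
    if (!st$rotated) break
  }
  list(V = V, mats = mats)
}

#' Fit multiclass CSP by joint approximate diagonalization
#'
#' Whitens by the prior-weighted average class covariance, jointly
#' diagonalizes the whitened class covariances by an orthogonal rotation, and
#' composes the two into the projection `W` (filters in rows, applied as
#' `Z = W E`). Each filter `w_j` is scored by the mutual-information
#' approximation between the class label and its projected signal,
#' \deqn{I_j = -\sum_i P(c_i) \log v_{ji} -
#'   (3/16) \big(\sum_i P(c_i) (v_{ji}^2 - 1)\big)^2,}
#' where `v_ji = w_j' R_i w_j` is the filter's variance under class `i`
#' (whitening makes the prior-weighted mean of `v_ji` equal 1). Filters are
#' ordered by descending score. `mi_variant = "sqrt"` scores with
#' `log sqrt(v)` instead of `log v`.
#'
#' @param covs list of per-class covariance matrices (symmetric PSD).
#' @param priors class prior probabilities (sum to 1).
#' @param ridge diagonal loading added to the average covariance before
#'   whitening when it is near-singular (0 disables).
#' @param mi_variant `"log"` (default) or `"sqrt"`.
#' @return An object of class `csp_model`: `W` (N x N), `covs`, `priors`,
#'   `mi_scores`, `order` (permutation, best filter first), `n_channels`.
#' @export
fit_jad <- function(covs, priors = NULL, ridge = 0, mi_variant = c("log", "sqrt")) {
  mi_variant <- match.arg(mi_variant)
  m <- length(covs)
  if (m < 2L) stop("need at least 2 classes")
  if (is.null(priors)) priors <- rep(1 / m, m)
  if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1")
  n <- nrow(covs[[1L]])
  rbar <- Reduce(`+`, Map(`*`, covs, priors))
  if (ridge > 0) rbar <- rbar + diag(ridge, n)
  e <- eigen((rbar + t(rbar)) / 2, symmetric = TRUE)
  if (min(e$values) < 1e-12 * max(e$values))
    stop("average covariance is singular or near-singular; ",
         "add diagonal loading via `ridge`")
  P <- diag(1 / sqrt(e$values)) %*% t(e$vectors)       # whitener
  wh <- lapply(covs, function(R) {
    S <- P %*% R %*% t(P)
    (S + t(S)) / 2
  })
  jd <- joint_diag(wh)
  W <- t(jd$V) %*% P                                   # filters in rows
  v <- vapply(seq_len(n), function(j) {
    w <- W[j, ]
    vapply(covs, function(R) drop(crossprod(w, R %*% w)), numeric(1))
  }, numeric(m))                                       # m x n
  if (m == 1L) v <- matrix(v, nrow = 1L)
  logv <- if (mi_variant == "log") log(v) else log(sqrt(v))
  mi <- -colSums(priors * logv) -
    (3 / 16) * colSums(priors * (v^2 - 1))^2
  ord <- order(mi, decreasing = TRUE)                  # stable ties by index
  structure(list(W = W, covs = covs, priors = priors, mi_scores = mi,
                 order = ord, n_channels = n, mi_variant = mi_variant),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d channels, %d classes; top filter score %.4f\n",
              x$n_channels, length(x$covs), max(x$mi_scores)))
  invisible(x)
}

#' Fit a CSP model directly from epochs
#'
#' Convenience wrapper: [estimate_class_covs()] then [fit_jad()].
#'
#' @inheritParams estimate_class_covs
#' @inheritParams fit_jad
#' @return A `csp_model`.
#' @export
fit_csp <- function(epochs, ridge = 0, mi_variant = "log") {
  cc <- estimate_class_covs(epochs)
  fit_jad(cc$covs, cc$priors, ridge = ridge, mi_variant = mi_variant)
}

#' Project epochs into the spatial domain
#'
#' Applies the top-`L` CSP filters (by mutual-information order) to every
#' trial: `Z = W_L E`. With `L` equal to the channel count the output keeps
#' the input geometry, so the spatial-domain tensor can be fed to the network
#' alongside the time and phase domains.
#'
#' @param model a fitted `csp_model`.
#' @param epochs an `eeg_epochs` with matching channel count.
#' @param L number of filters to retain (default: all).
#' @return A `domain_tensor` with `domain = "spatial"` and `L` output
#'   channels.
#' @export
apply_csp <- function(model, epochs, L = NULL) {
  stopifnot(inherits(model, "csp_model"), inherits(epochs, "eeg_epochs"))
  n <- model$n_channels
  if (n_channels(epochs) != n)
    stop("epochs have ", n_channels(epochs), " channels but the model was ",
         "fitted on ", n)
  if (is.null(L)) L <- n
  if (L > n) stop("L exceeds the filter count")
  WL <- model$W[model$order[seq_len(L)], , drop = FALSE]
  d <- dim(epochs$data)
  out <- array(0, c(L, d[2L], d[3L]))
  for (i in seq_len(d[3L])) out[, , i] <- WL %*% epochs$data[, , i]
  domain_tensor(out, "spatial", epochs$fs)
}
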