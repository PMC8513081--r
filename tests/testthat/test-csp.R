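offdiag2 <- function(A) sum((A - diag(diag(A)))^2)

# direct evaluation of the mutual-information filter score from class
# variances, used to check invariances independently of fit_jad's internals
mi_score <- function(W, covs, priors) {
  vapply(seq_len(nrow(W)), function(j) {
    v <- vapply(covs, function(R) drop(crossprod(W[j, ], R %*% W[j, ])),
                numeric(1))
    -sum(priors * log(v)) - (3 / 16) * sum(priors * (v^2 - 1))^2
  }, numeric(1))
}

test_that("trial covariances recover a known population covariance", {
  set.seed(41)
  n_tr <- 2000L; n_samp <- 50L
  A <- diag(c(2, 1))                      # true covariance diag(4, 1)
  data <- array(0, c(2, n_samp, n_tr))
  for (i in seq_len(n_tr)) data[, , i] <- A %*% matrix(rnorm(2 * n_samp), 2)
  ep <- eeg_epochs(data, rep(1L, n_tr), 100, "a")
  cc <- estimate_class_covs(ep)
  target <- diag(c(4, 1)) / 5             # trace-normalized
  expect_lt(max(abs(cc$covs[[1]] - target)), 0.02)
})

test_that("identical trials across classes give equal covariances and priors", {
  set.seed(42)
  x <- matrix(rnorm(3 * 40), 3)
  data <- array(rep(x, 6), c(3, 40, 6))
  ep <- eeg_epochs(data, rep(1:3, each = 2), 50, c("a", "b", "c"))
  cc <- estimate_class_covs(ep)
  expect_equal(cc$covs[[1]], cc$covs[[2]])
  expect_equal(cc$covs[[2]], cc$covs[[3]])
  expect_equal(cc$priors, rep(1 / 3, 3))
  ep$labels <- c(1L, 1L, 1L, 1L, 1L, 2L)
  expect_error(estimate_class_covs(ep), "fewer than 2")
})

test_that("two-class joint diagonalization reproduces classical CSP", {
  R1 <- diag(c(4, 1)) / 5
  R2 <- diag(c(1, 4)) / 5
  m <- fit_jad(list(R1, R2), c(0.5, 0.5))
  # independent oracle: generalized eigendecomposition of (R1, R1+R2)
  ge <- eigen(solve(R1 + R2) %*% R1)
  for (j in 1:2) {
    w <- m$W[j, ] / sqrt(sum(m$W[j, ]^2))
    align <- abs(vapply(1:2, function(k) {
      v <- ge$vectors[, k] / sqrt(sum(ge$vectors[, k]^2))
      sum(w * v)
    }, numeric(1)))
    expect_gt(max(align), 1 - 1e-10)      # matches an eigvector up to sign
  }
  expect_lt(offdiag2(m$W %*% R1 %*% t(m$W)), 1e-8)
  expect_lt(offdiag2(m$W %*% R2 %*% t(m$W)), 1e-8)
})

test_that("equal class covariances yield flat scores with zero kurtosis term", {
  R <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  R <- R / sum(diag(R))
  m <- fit_jad(list(R, R, R), rep(1 / 3, 3))
  v <- vapply(seq_len(3), function(j)
    drop(crossprod(m$W[j, ], R %*% m$W[j, ])), numeric(1))
  expect_equal(v, rep(1, 3), tolerance = 1e-10)   # whitened variances
  expect_lt(diff(range(m$mi_scores)), 1e-10)
})

test_that("joint diagonalization beats random rotations on 3-class problems", {
  set.seed(43)
  mk <- function() {
    S <- crossprod(matrix(rnorm(16), 4)) + diag(4)
    S / sum(diag(S))
  }
  covs <- list(mk(), mk(), mk())
  priors <- rep(1 / 3, 3)
  rbar <- Reduce(`+`, Map(`*`, covs, priors))
  e <- eigen(rbar, symmetric = TRUE)
  P <- diag(1 / sqrt(e$values)) %*% t(e$vectors)
  wh <- lapply(covs, function(R) P %*% R %*% t(P))
  resid <- function(V) sum(vapply(wh, function(S)
    offdiag2(t(V) %*% S %*% V), numeric(1)))
  jd <- joint_diag(wh)
  random_best <- min(vapply(seq_len(1000), function(i) {
    resid(qr.Q(qr(matrix(rnorm(16), 4))))
  }, numeric(1)))
  jad_resid <- resid(jd$V)
  expect_lte(jad_resid, random_best)
  # whitening identity holds for the composed projection
  m <- fit_jad(covs, priors)
  wsum <- Reduce(`+`, Map(function(R, p) p * m$W %*% R %*% t(m$W), covs,
                          priors))
  expect_lt(max(abs(wsum - diag(4))), 1e-8)
})

test_that("filter scores are invariant to sign flips and sorted descending", {
  set.seed(44)
  mk <- function(d) {
    S <- crossprod(matrix(rnorm(25), 5)) + diag(d)
    S / sum(diag(S))
  }
  covs <- list(mk(c(5, 1, 1, 1, 1)), mk(c(1, 5, 1, 1, 1)), mk(rep(1, 5)))
  m <- fit_jad(covs, rep(1 / 3, 3))
  expect_equal(mi_score(m$W, covs, m$priors),
               mi_score(-m$W, covs, m$priors))
  expect_equal(mi_score(m$W, covs, m$priors), m$mi_scores,
               tolerance = 1e-10)
  expect_true(all(diff(m$mi_scores[m$order]) <= 1e-12))
  # sqrt variant halves the log term only
  m2 <- fit_jad(covs, rep(1 / 3, 3), mi_variant = "sqrt")
  kurt <- (3 / 16) * vapply(seq_len(5), function(j) {
    v <- vapply(covs, function(R)
      drop(crossprod(m$W[j, ], R %*% m$W[j, ])), numeric(1))
    sum(m$priors * (v^2 - 1))^2
  }, numeric(1))
  expect_equal(m2$mi_scores + kurt, (m$mi_scores + kurt) / 2,
               tolerance = 1e-10)
})

test_that("projection separates class variances as the eigenvalues dictate", {
  set.seed(45)
  n_tr <- 100L; n_samp <- 200L
  A1 <- diag(c(2, 1)); A2 <- diag(c(1, 2))
  data <- array(0, c(2, n_samp, 2 * n_tr))
  for (i in seq_len(n_tr)) {
    data[, , i] <- A1 %*% matrix(rnorm(2 * n_samp), 2)
    data[, , n_tr + i] <- A2 %*% matrix(rnorm(2 * n_samp), 2)
  }
  ep <- eeg_epochs(data, rep(1:2, each = n_tr), 100, c("a", "b"))
  m <- fit_csp(ep)
  z <- apply_csp(m, ep)
  expect_s3_class(z, "domain_tensor")
  expect_equal(z$domain, "spatial")
  expect_equal(dim(z$data), dim(ep$data))
  v1 <- mean(vapply(which(ep$labels == 1), function(i)
    var(z$data[1, , i]), numeric(1)))
  v2 <- mean(vapply(which(ep$labels == 2), function(i)
    var(z$data[1, , i]), numeric(1)))
  # top filter contrasts the classes by about the true 4:1 variance ratio
  expect_gt(max(v1 / v2, v2 / v1), 2.5)
})

test_that("identity projection and L filters keep the expected geometry", {
  ep <- tiny_epochs(n_ch = 4L, n_tr = 8L)
  m <- fit_csp(ep)
  m$W <- diag(4)
  m$order <- 1:4
  z <- apply_csp(m, ep, L = 4L)
  expect_equal(z$data, ep$data)
  z2 <- apply_csp(fit_csp(ep), ep, L = 2L)
  expect_equal(dim(z2$data), c(2L, n_samples(ep), n_trials(ep)))
  bad <- tiny_epochs(n_ch = 5L)
  expect_error(apply_csp(fit_csp(ep), bad, L = 2L), "channels")
})

test_that("fitting scope guards against test-trial leakage", {
  ep <- tiny_epochs(n_ch = 4L, n_tr = 20L, seed = 46)
  train <- subset_trials(ep, 1:16)
  m_train <- fit_csp(train)
  m_all <- fit_csp(ep)
  expect_gt(max(abs(m_train$W - m_all$W)), 1e-6)
})

test_that("singular average covariance asks for regularization", {
  R <- matrix(0, 3, 3); R[1, 1] <- 1
  expect_error(fit_jad(list(R, R), c(0.5, 0.5)), "ridge")
  m <- fit_jad(list(R, R), c(0.5, 0.5), ridge = 1e-3)
  expect_true(all(is.finite(m$W)))
})
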