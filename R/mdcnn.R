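#' Multi-domain network configuration
#'
#' Architecture hyper-parameters of the multi-domain convolutional network.
#' Each branch is a shallow convolutional stack — temporal convolution
#' (`temporal_filters` kernels of length `temporal_kernel`, shared across
#' channels), spatial convolution across all channels and temporal maps,
#' batch normalization, square activation, average pooling
#' (`pool_kernel`/`pool_stride`), log activation, dropout, and a fully
#' connected layer to `feature_dim` features. Every branch gets its own
#' softmax head; branch features are concatenated and fused by a final fully
#' connected softmax (the "multi" head). A max-norm constraint bounds the
#' per-neuron weight norms of all convolutional and fully connected layers.
#'
#' @param n_channels,n_samples,n_classes input geometry (window samples, not
#'   trial samples) and class count.
#' @param temporal_filters,temporal_kernel first (temporal) convolution:
#'   number of kernels and kernel length (defaults 40 and 25).
#' @param spatial_filters second (spatial) convolution kernels (default 40).
#' @param pool_kernel,pool_stride average-pooling geometry (defaults 75/15).
#' @param dropout dropout rate after the log activation (default 0.5).
#' @param feature_dim per-branch fully connected feature width `D`
#'   (default 40).
#' @param maxnorm_conv,maxnorm_fc max-norm radii for convolutional and fully
#'   connected weight vectors (defaults 2 and 0.5).
#' @param loss_weights head loss weights, one per branch plus the multi head
#'   (default all 1).
#' @param branches which domains the model consumes (default
#'   time/spatial/phase; a single branch reduces the model to a standalone
#'   shallow convolutional classifier).
#' @param log_eps clamp inside `log(max(x, eps))`.
#' @param bn_eps,bn_momentum batch-normalization constants.
#' @return An object of class `mdcnn_config`.
#' @export
mdcnn_config <- function(n_channels, n_samples, n_classes,
                         temporal_filters = 40L, temporal_kernel = 25L,
                         spatial_filters = 40L, pool_kernel = 75L,
                         pool_stride = 15L, dropout = 0.5,
                         feature_dim = 40L, maxnorm_conv = 2,
                         maxnorm_fc = 0.5, loss_weights = NULL,
                         branches = c("time", "spatial", "phase"),
                         log_eps = 1e-6, bn_eps = 1e-5, bn_momentum = 0.1) {
  if (temporal_kernel > n_samples)
    stop("temporal_kernel exceeds the window length")
  t1 <- n_samples - temporal_kernel + 1L
  if (pool_kernel > t1)
    stop("pool_kernel (", pool_kernel, ") exceeds the conv map length (", t1,
         ")")
  if (!length(branches)) stop("need at least one branch")
  if (is.null(loss_weights)) loss_weights <- rep(1, length(branches) + 1L)
  if (length(loss_weights) != length(branches) + 1L)
    stop("loss_weights needs one weight per branch plus the multi head")
  if (any(loss_weights < 0) || all(loss_weights == 0))
    stop("loss_weights must be non-negative and not all zero")
  structure(list(
    n_channels = as.integer(n_channels), n_samples = as.integer(n_samples),
    n_classes = as.integer(n_classes),
    temporal_filters = as.integer(temporal_filters),
    temporal_kernel = as.integer(temporal_kernel),
    spatial_filters = as.integer(spatial_filters),
    pool_kernel = as.integer(pool_kernel),
    pool_stride = as.integer(pool_stride),
    dropout = dropout, feature_dim = as.integer(feature_dim),
    maxnorm_conv = maxnorm_conv, maxnorm_fc = maxnorm_fc,
    loss_weights = loss_weights, branches = branches,
    log_eps = log_eps, bn_eps = bn_eps, bn_momentum = bn_momentum),
    class = "mdcnn_config")
}

#' Feature-map geometry implied by a configuration
#'
#' @param cfg an `mdcnn_config`.
#' @return A list: `conv_map` (filters x 1 x samples after both
#'   convolutions), `pooled_len` (temporal length after average pooling),
#'   `flat_dim` (flattened per-branch feature count), `concat_dim`
#'   (fused feature length, branches x `feature_dim`).
#' @export
model_shapes <- function(cfg) {
  stopifnot(inherits(cfg, "mdcnn_config"))
  t1 <- cfg$n_samples - cfg$temporal_kernel + 1L
  t2 <- (t1 - cfg$pool_kernel) %/% cfg$pool_stride + 1L
  list(conv_map = c(cfg$spatial_filters, 1L, t1),
       pooled_len = t2,
       flat_dim = cfg$spatial_filters * t2,
       concat_dim = length(cfg$branches) * cfg$feature_dim)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build (initialize) a multi-domain network
#'
#' Allocates Glorot-uniform weights for every branch and the fusion head.
#'
#' @param cfg an `mdcnn_config`.
#' @param seed RNG seed for the initialization.
#' @return An object of class `mdcnn`: `cfg`, `params`, `bn_state`.
#' @export
mdcnn_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "mdcnn_config"))
  set.seed(seed)
  sh <- model_shapes(cfg)
  f1 <- cfg$temporal_filters; f2 <- cfg$spatial_filters
  branch <- function() list(
    Wt = glorot(f1, cfg$temporal_kernel),
    bt = numeric(f1),
    Ws = glorot(f2, f1 * cfg$n_channels),
    gamma = rep(1, f2), beta = numeric(f2),
    W1 = glorot(cfg$feature_dim, sh$flat_dim),
    b1 = numeric(cfg$feature_dim),
    Wh = glorot(cfg$n_classes, cfg$feature_dim),
    bh = numeric(cfg$n_classes))
  params <- list(
    branches = stats::setNames(
      lapply(cfg$branches, function(b) branch()), cfg$branches),
    fusion = list(
      Wf = glorot(cfg$n_classes, sh$concat_dim),
      bf = numeric(cfg$n_classes)))
  bn_state <- list(branches = stats::setNames(
    lapply(cfg$branches, function(b) list(rmean = numeric(f2),
                                          rvar = rep(1, f2))),
    cfg$branches))
  structure(list(cfg = cfg, params = params, bn_state = bn_state,
                 seed = seed), class = "mdcnn")
}

#' @export
print.mdcnn <- function(x, ...) {
  sh <- model_shapes(x$cfg)
  np <- sum(unlist(lapply(rapply(x$params, length, how = "unlist"),
                          identity)))
  cat(sprintf(
    "<mdcnn> branches: %s | %d ch x %d samples -> conv %dx1x%d -> pooled %d -> D=%d (%d params)\n",
    paste(x$cfg$branches, collapse = "+"), x$cfg$n_channels,
    x$cfg$n_samples, sh$conv_map[1L], sh$conv_map[3L], sh$pooled_len,
    x$cfg$feature_dim, np))
  invisible(x)
}

#' Training configuration
#'
#' @param epochs number of passes over the training crops (default 100).
#' @param batch_size mini-batch size (default 32).
#' @param initial_lr Adam learning rate (default 1e-3).
#' @param lr_reduce_factor multiplier applied to the learning rate when the
#'   monitored loss fails to improve for `lr_patience` epochs (default 0.5).
#' @param lr_patience plateau patience in epochs (default 10).
#' @param checkpoint `"monitor_test_loss"` keeps the weights with the lowest
#'   loss on the evaluation crops (the protocol mirrored from the method this
#'   implements — note it peeks at the test fold); `"monitor_val_loss"`
#'   carves a stratified 10% of the training trials as an inner validation
#'   split and monitors that instead; `"final"` keeps the last epoch.
#' @param val_fraction inner validation fraction for `"monitor_val_loss"`.
#' @param seed RNG seed for shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, initial_lr = 1e-3,
                         lr_reduce_factor = 0.5, lr_patience = 10L,
                         checkpoint = c("monitor_test_loss",
                                        "monitor_val_loss", "final"),
                         val_fraction = 0.1, seed = 1L) {
  checkpoint <- match.arg(checkpoint)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (lr_reduce_factor <= 0 || lr_reduce_factor >= 1)
    stop("lr_reduce_factor must be in (0, 1)")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr,
                 lr_reduce_factor = lr_reduce_factor,
                 lr_patience = as.integer(lr_patience),
                 checkpoint = checkpoint, val_fraction = val_fraction,
                 seed = as.integer(seed)), class = "train_config")
}

# recursive elementwise walk over two parameter trees
tree_map2 <- function(a, b, f) {
  if (is.list(a)) Map(function(x, y) tree_map2(x, y, f), a, b)
  else f(a, b)
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- tree_map2(params, upd, function(p, u) {
    r <- p - u
    attributes(r) <- attributes(p)     # keep vector params dimensionless
    r
  })
  list(params = params, state = state)
}

maxnorm_rows <- function(W, c) {
  nrm <- sqrt(rowSums(W^2))
  over <- nrm > c
  if (any(over)) W[over, ] <- W[over, , drop = FALSE] * (c / nrm[over])
  W
}

apply_maxnorm <- function(params, cfg) {
  for (b in names(params$branches)) {
    p <- params$branches[[b]]
    p$Wt <- maxnorm_rows(p$Wt, cfg$maxnorm_conv)
    p$Ws <- maxnorm_rows(p$Ws, cfg$maxnorm_conv)
    p$W1 <- maxnorm_rows(p$W1, cfg$maxnorm_fc)
    p$Wh <- maxnorm_rows(p$Wh, cfg$maxnorm_fc)
    params$branches[[b]] <- p
  }
  params$fusion$Wf <- maxnorm_rows(params$fusion$Wf, cfg$maxnorm_fc)
  params
}

crop_batch <- function(crops, branches, idx) {
  lapply(crops$domains[branches], function(a) a[, , idx, drop = FALSE])
}

pass_dims <- function(cfg) list(
  K = cfg$temporal_kernel, pool = cfg$pool_kernel, stride = cfg$pool_stride,
  log_eps = cfg$log_eps, bn_eps = cfg$bn_eps, bn_momentum = cfg$bn_momentum,
  dropout = cfg$dropout)

# mean weighted cross-entropy of a crop set under the current weights,
# evaluated in inference mode (running BN stats, no dropout)
eval_loss <- function(model, crops, chunk = 512L) {
  n <- length(crops$labels)
  tot <- 0
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    r <- mdcnn_pass(crop_batch(crops, model$cfg$branches, idx),
                    crops$labels[idx], model$params, model$bn_state,
                    list(), pass_dims(model$cfg), model$cfg$loss_weights,
                    FALSE, FALSE)
    tot <- tot + r$loss * length(idx)
  }
  tot / n
}

#' Train a multi-domain network on cropped examples
#'
#' Adam over shuffled mini-batches of the training crops, minimizing the
#' weighted sum of the four heads' cross-entropies. After every step the
#' max-norm constraint is re-imposed. The learning rate is multiplied by
#' `lr_reduce_factor` whenever the monitored loss has not improved for
#' `lr_patience` epochs, and the returned weights are the checkpoint with the
#' lowest monitored loss (see [train_config()]).
#'
#' @param model an `mdcnn` from [mdcnn_init()].
#' @param train_crops a `crop_set` whose domains cover `cfg$branches`.
#' @param eval_crops optional `crop_set` monitored for checkpointing under
#'   `"monitor_test_loss"`; when absent, the training loss is monitored.
#' @param tcfg a [train_config()].
#' @return The trained `mdcnn`, with a `history` data frame attached (epoch,
#'   lr, train loss, monitored loss).
#' @export
mdcnn_train <- function(model, train_crops, eval_crops = NULL,
                        tcfg = train_config()) {
  stopifnot(inherits(model, "mdcnn"), inherits(train_crops, "crop_set"))
  cfg <- model$cfg
  if (!all(cfg$branches %in% names(train_crops$domains)))
    stop("training crops lack domain(s): ",
         paste(setdiff(cfg$branches, names(train_crops$domains)),
               collapse = ", "))
  set.seed(tcfg$seed)
  monitor_crops <- eval_crops
  fit_crops <- train_crops
  if (tcfg$checkpoint == "monitor_val_loss") {
    # stratified inner split by trial, so crops of one trial never straddle it
    tr_ids <- sort(unique(train_crops$trial_index))
    tr_lab <- train_crops$labels[match(tr_ids, train_crops$trial_index)]
    val_ids <- unlist(lapply(split(tr_ids, tr_lab), function(ids)
      sample(ids, max(1L, round(tcfg$val_fraction * length(ids))))))
    monitor_crops <- subset_crops(train_crops, val_ids)
    fit_crops <- subset_crops(train_crops, setdiff(tr_ids, val_ids))
  }
  n <- length(fit_crops$labels)
  sh <- model_shapes(cfg)
  state <- list(t = 0L, m = tree_zero(model$params),
                v = tree_zero(model$params))
  lr <- tcfg$initial_lr
  best <- Inf
  best_params <- model$params
  best_bn <- model$bn_state
  since_improve <- 0L
  hist <- vector("list", tcfg$epochs)
  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (s in seq(1L, n, by = tcfg$batch_size)) {
      idx <- ord[s:min(s + tcfg$batch_size - 1L, n)]
      masks <- lapply(cfg$branches, function(b)
        matrix(stats::rbinom(sh$flat_dim * length(idx), 1L,
                             1 - cfg$dropout),
               sh$flat_dim, length(idx)))
      r <- mdcnn_pass(crop_batch(fit_crops, cfg$branches, idx),
                      fit_crops$labels[idx], model$params, model$bn_state,
                      masks, pass_dims(cfg), cfg$loss_weights, TRUE, TRUE)
      if (!is.finite(r$loss))
        stop(sprintf(
          "non-finite loss at epoch %d, batch starting %d (lr=%g)",
          ep, s, lr))
      model$bn_state <- r$bn_state
      st <- adam_step(model$params, r$grads, state, lr)
      state <- st$state
      model$params <- apply_maxnorm(st$params, cfg)
      ep_loss <- ep_loss + r$loss * length(idx)
    }
    ep_loss <- ep_loss / n
    mon <- if (is.null(monitor_crops)) ep_loss
           else eval_loss(model, monitor_crops)
    if (mon < best - 1e-12) {
      best <- mon
      since_improve <- 0L
      if (tcfg$checkpoint != "final") {
        best_params <- model$params
        best_bn <- model$bn_state
      }
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= tcfg$lr_patience) {
        lr <- lr * tcfg$lr_reduce_factor
        since_improve <- 0L
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, lr = lr, train_loss = ep_loss,
                             monitored_loss = mon)
  }
  if (tcfg$checkpoint != "final") {
    model$params <- best_params
    model$bn_state <- best_bn
  }
  model$history <- do.call(rbind, hist)
  model$train_config <- tcfg
  model
}

#' Crop-level class probabilities from all heads
#'
#' Runs the network in inference mode (running batch-norm statistics, no
#' dropout) and returns softmax probabilities per crop for each branch head
#' and the fused multi head, along with the crop-to-trial map needed for
#' per-trial vote aggregation.
#'
#' @param object a (trained) `mdcnn`.
#' @param crops a `crop_set`.
#' @param chunk internal batch size.
#' @param ... unused.
#' @return An object of class `prediction_set`: `probs` (named list of
#'   `crops x classes` matrices, one per head incl. `"multi"`),
#'   `trial_index`, `labels`.
#' @export
predict.mdcnn <- function(object, crops, chunk = 256L, ...) {
  stopifnot(inherits(crops, "crop_set"))
  cfg <- object$cfg
  n <- length(crops$labels)
  heads <- c(cfg$branches, "multi")
  out <- lapply(heads, function(h) matrix(0, n, cfg$n_classes))
  names(out) <- heads
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    r <- mdcnn_pass(crop_batch(crops, cfg$branches, idx), integer(0),
                    object$params, object$bn_state, list(),
                    pass_dims(cfg), cfg$loss_weights, FALSE, FALSE)
    for (i in seq_along(heads))
      out[[i]][idx, ] <- t(r$probs[[i]])
  }
  structure(list(probs = out, trial_index = crops$trial_index,
                 labels = crops$labels), class = "prediction_set")
}

#' Per-head trial accuracies of a prediction set
#'
#' @param preds a `prediction_set`.
#' @param trial_labels integer true label per trial (indexed by trial id).
#' @param aggregate passed to [trial_accuracy()].
#' @return Named numeric vector of accuracies (%), one per head.
#' @export
head_accuracies <- function(preds, trial_labels, aggregate = "trial") {
  vapply(preds$probs, function(p)
    trial_accuracy(p, preds$trial_index, trial_labels, aggregate),
    numeric(1))
}

#' Save / load network weights
#'
#' Writes the configuration, weights and batch-norm state as a single JSON
#' checkpoint (text; exact binary round-trip of doubles via base64 is not
#' attempted — values are serialized at full precision).
#'
#' @param model an `mdcnn`.
#' @param path file path.
#' @return `save_mdcnn` returns `path` invisibly; `load_mdcnn` the model.
#' @export
save_mdcnn <- function(model, path) {
  stopifnot(inherits(model, "mdcnn"))
  ser <- list(cfg = unclass(model$cfg), seed = model$seed,
              params = model$params, bn_state = model$bn_state,
              dims = rapply(model$params, function(x)
                if (is.matrix(x)) dim(x) else length(x), how = "list"))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_mdcnn
#' @export
load_mdcnn <- function(path) {
  ser <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  cfg <- do.call(mdcnn_config, ser$cfg[setdiff(names(ser$cfg), character())])
  restore <- function(p, d) {
    if (is.list(d)) return(Map(restore, p, d))
    if (length(d) == 2L) matrix(p, d[1L], d[2L]) else as.numeric(p)
  }
  params <- restore(ser$params, ser$dims)
  bn <- rapply(ser$bn_state, as.numeric, how = "replace")
  structure(list(cfg = cfg, params = params, bn_state = bn,
                 seed = ser$seed), class = "mdcnn")
}
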