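tiny_cfg <- function(...) {
  mdcnn_config(n_channels = 3L, n_samples = 40L, n_classes = 2L,
               temporal_filters = 2L, temporal_kernel = 5L,
               spatial_filters = 2L, pool_kernel = 10L, pool_stride = 5L,
               feature_dim = 3L, ...)
}

rand_inputs <- function(cfg, B, seed = 1L) {
  set.seed(seed)
  x <- lapply(cfg$branches, function(b)
    array(rnorm(cfg$n_channels * cfg$n_samples * B),
          c(cfg$n_channels, cfg$n_samples, B)))
  names(x) <- cfg$branches
  x
}

test_that("feature-map geometry matches the architecture arithmetic", {
  cfg <- mdcnn_config(31, 1000, 3)
  sh <- model_shapes(cfg)
  expect_equal(sh$conv_map, c(40L, 1L, 976L))
  expect_equal(sh$pooled_len, (976L - 75L) %/% 15L + 1L)   # 61
  expect_equal(sh$concat_dim, 3L * 40L)
  expect_error(mdcnn_config(31, 20, 3), "temporal_kernel")
  expect_error(mdcnn_config(31, 60, 3), "pool_kernel")
  expect_error(mdcnn_config(31, 1000, 3, loss_weights = c(0, 0, 0, 0)),
               "loss_weights")
})

test_that("analytic gradients match central differences on every layer", {
  cfg <- tiny_cfg()
  model <- mdcnn_init(cfg, seed = 1)
  B <- 4L
  X <- rand_inputs(cfg, B, seed = 2)
  y <- c(1L, 2L, 1L, 2L)
  sh <- model_shapes(cfg)
  set.seed(3)
  masks <- lapply(seq_along(cfg$branches), function(i)
    matrix(rbinom(sh$flat_dim * B, 1L, 0.5), sh$flat_dim, B))
  dims <- mdbci:::pass_dims(cfg)
  loss_of <- function(params)
    mdbci:::mdcnn_pass(X, y, params, model$bn_state, masks, dims,
                       cfg$loss_weights, TRUE, FALSE)$loss
  r <- mdbci:::mdcnn_pass(X, y, model$params, model$bn_state, masks, dims,
                          cfg$loss_weights, TRUE, TRUE)
  expect_true(is.finite(r$loss))
  set.seed(4)
  worst <- 0
  for (br in c(cfg$branches, "fusion")) {
    pl <- if (br == "fusion") model$params$fusion
          else model$params$branches[[br]]
    gl <- if (br == "fusion") r$grads$fusion
          else r$grads$branches[[match(br, cfg$branches)]]
    for (pn in setdiff(names(pl), "bt")) {   # bt is a BN-cancelled no-op
      for (ii in sample(length(pl[[pn]]), min(3L, length(pl[[pn]])))) {
        eps <- 1e-6
        mod <- function(v) {
          q <- model$params
          if (br == "fusion") q$fusion[[pn]][ii] <- v
          else q$branches[[br]][[pn]][ii] <- v
          q
        }
        base <- pl[[pn]][ii]
        num <- (loss_of(mod(base + eps)) - loss_of(mod(base - eps))) /
          (2 * eps)
        ana <- gl[[pn]][ii]
        worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
      }
    }
  }
  expect_lt(worst, 1e-4)
  # the temporal bias is exactly cancelled by batch normalization
  expect_lt(max(abs(unlist(lapply(r$grads$branches, `[[`, "bt")))), 1e-12)
})

test_that("softmax heads emit probability rows; zero logits are uniform", {
  cfg <- tiny_cfg()
  model <- mdcnn_init(cfg, seed = 5)
  crops <- structure(list(
    domains = rand_inputs(cfg, 6L, seed = 6),
    labels = rep(1:2, 3L), trial_index = rep(1:3, each = 2L),
    fs = 10, window_seconds = 4, step_seconds = 0.1, crops_per_trial = 2L),
    class = "crop_set")
  preds <- predict(model, crops)
  for (h in names(preds$probs))
    expect_equal(rowSums(preds$probs[[h]]), rep(1, 6L), tolerance = 1e-9)
  # zeroed final layers give exactly uniform probabilities
  model$params$fusion$Wf[] <- 0
  model$params$fusion$bf[] <- 0
  for (b in cfg$branches) {
    model$params$branches[[b]]$Wh[] <- 0
    model$params$branches[[b]]$bh[] <- 0
  }
  preds0 <- predict(model, crops)
  for (h in names(preds0$probs))
    expect_equal(preds0$probs[[h]],
                 matrix(0.5, 6L, 2L), tolerance = 1e-12)
})

test_that("permuting domains together with branch weights is a symmetry", {
  cfg <- tiny_cfg()
  model <- mdcnn_init(cfg, seed = 7)
  X <- rand_inputs(cfg, 5L, seed = 8)
  dims <- mdbci:::pass_dims(cfg)
  out1 <- mdbci:::mdcnn_pass(X, integer(0), model$params, model$bn_state,
                             list(), dims, cfg$loss_weights, FALSE, FALSE)
  perm <- c(3L, 1L, 2L)                    # phase, time, spatial
  model2 <- model
  model2$params$branches <- model$params$branches[perm]
  model2$bn_state$branches <- model$bn_state$branches[perm]
  D <- cfg$feature_dim
  blocks <- lapply(seq_along(perm), function(i)
    ((perm[i] - 1L) * D + 1L):(perm[i] * D))
  model2$params$fusion$Wf <- model$params$fusion$Wf[, unlist(blocks)]
  out2 <- mdbci:::mdcnn_pass(X[perm], integer(0), model2$params,
                             model2$bn_state, list(), dims,
                             cfg$loss_weights, FALSE, FALSE)
  nb <- length(cfg$branches)
  expect_equal(out2$probs[[nb + 1L]], out1$probs[[nb + 1L]],
               tolerance = 1e-12)
  # branch heads follow their branch through the permutation
  for (i in seq_len(nb))
    expect_equal(out2$probs[[i]], out1$probs[[perm[i]]], tolerance = 1e-12)
})

make_separable_crops <- function(seed = 1L) {
  ep <- tiny_separable(seed = seed)
  csp <- fit_csp(ep)
  doms <- list(time = time_domain(ep), spatial = apply_csp(csp, ep),
               phase = phase_domain(ep))
  doms <- lapply(doms, function(d) normalize_domain(d)$tensor)
  make_crops(doms, ep$labels, window_seconds = 1, step_seconds = 0.25)
}

test_that("training reaches 95% on separable band-power classes", {
  crops <- make_separable_crops(seed = 81)
  # oracle: a band-power rule (larger variance channel) is already perfect,
  # so the classes are linearly separable in power
  ep <- tiny_separable(seed = 81)
  v1 <- apply(ep$data[1, , ], 2, var)
  v2 <- apply(ep$data[2, , ], 2, var)
  expect_equal(mean(ifelse(v1 > v2, 1L, 2L) == ep$labels), 1)
  cfg <- mdcnn_config(2L, 64L, 2L, temporal_filters = 4L,
                      temporal_kernel = 13L, spatial_filters = 4L,
                      pool_kernel = 20L, pool_stride = 10L,
                      feature_dim = 8L)
  model <- mdcnn_init(cfg, seed = 82)
  model <- mdcnn_train(model, crops,
                       tcfg = train_config(epochs = 40, seed = 82,
                                           checkpoint = "final"))
  preds <- predict(model, crops)
  acc <- head_accuracies(preds, tiny_separable(seed = 81)$labels)
  expect_gte(acc[["multi"]], 95)
  # history is a complete per-epoch record
  expect_equal(nrow(model$history), 40L)
  expect_true(all(is.finite(model$history$train_loss)))
})

test_that("max-norm projection bounds every constrained weight vector", {
  crops <- make_separable_crops(seed = 83)
  cfg <- mdcnn_config(2L, 64L, 2L, temporal_filters = 4L,
                      temporal_kernel = 13L, spatial_filters = 4L,
                      pool_kernel = 20L, pool_stride = 10L,
                      feature_dim = 8L, maxnorm_conv = 0.7,
                      maxnorm_fc = 0.3)
  model <- mdcnn_init(cfg, seed = 84)
  model <- mdcnn_train(model, crops,
                       tcfg = train_config(epochs = 3, seed = 84,
                                           checkpoint = "final"))
  for (b in cfg$branches) {
    p <- model$params$branches[[b]]
    expect_lte(max(sqrt(rowSums(p$Wt^2))), 0.7 + 1e-6)
    expect_lte(max(sqrt(rowSums(p$Ws^2))), 0.7 + 1e-6)
    expect_lte(max(sqrt(rowSums(p$W1^2))), 0.3 + 1e-6)
    expect_lte(max(sqrt(rowSums(p$Wh^2))), 0.3 + 1e-6)
  }
  expect_lte(max(sqrt(rowSums(model$params$fusion$Wf^2))), 0.3 + 1e-6)
})

test_that("training is reproducible under a fixed seed", {
  crops <- make_separable_crops(seed = 85)
  cfg <- mdcnn_config(2L, 64L, 2L, temporal_filters = 2L,
                      temporal_kernel = 13L, spatial_filters = 2L,
                      pool_kernel = 20L, pool_stride = 10L,
                      feature_dim = 4L)
  run <- function() {
    m <- mdcnn_init(cfg, seed = 86)
    mdcnn_train(m, crops, tcfg = train_config(epochs = 4, seed = 86,
                                              checkpoint = "final"))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("zero-weight branch heads receive no gradient updates", {
  crops <- make_separable_crops(seed = 87)
  cfg <- mdcnn_config(2L, 64L, 2L, temporal_filters = 2L,
                      temporal_kernel = 13L, spatial_filters = 2L,
                      pool_kernel = 20L, pool_stride = 10L,
                      feature_dim = 4L, loss_weights = c(0, 0, 0, 1),
                      maxnorm_fc = 1e6)   # disable projection to isolate grads
  model <- mdcnn_init(cfg, seed = 88)
  before <- lapply(model$params$branches, function(p) list(Wh = p$Wh,
                                                           bh = p$bh))
  trained <- mdcnn_train(model, crops,
                         tcfg = train_config(epochs = 2, seed = 88,
                                             checkpoint = "final"))
  for (b in cfg$branches) {
    expect_identical(trained$params$branches[[b]]$Wh, before[[b]]$Wh)
    expect_identical(trained$params$branches[[b]]$bh, before[[b]]$bh)
  }
})

test_that("a single branch reduces to a standalone shallow ConvNet", {
  ep <- tiny_separable(seed = 89)
  dom <- list(time = normalize_domain(time_domain(ep))$tensor)
  crops <- make_crops(dom, ep$labels, 1, 0.25)
  cfg <- mdcnn_config(2L, 64L, 2L, temporal_filters = 4L,
                      temporal_kernel = 13L, spatial_filters = 4L,
                      pool_kernel = 20L, pool_stride = 10L,
                      feature_dim = 8L, branches = "time",
                      loss_weights = c(1, 1))
  model <- mdcnn_init(cfg, seed = 90)
  model <- mdcnn_train(model, crops,
                       tcfg = train_config(epochs = 30, seed = 90,
                                           checkpoint = "final"))
  preds <- predict(model, crops)
  expect_named(preds$probs, c("time", "multi"))
  expect_gte(head_accuracies(preds, ep$labels)[["time"]], 95)
})

test_that("checkpoint and learning-rate schedule react to the monitored loss", {
  crops <- make_separable_crops(seed = 91)
  cfg <- mdcnn_config(2L, 64L, 2L, temporal_filters = 2L,
                      temporal_kernel = 13L, spatial_filters = 2L,
                      pool_kernel = 20L, pool_stride = 10L,
                      feature_dim = 4L)
  model <- mdcnn_init(cfg, seed = 92)
  tcfg <- train_config(epochs = 8, seed = 92, lr_patience = 2,
                       checkpoint = "monitor_val_loss")
  trained <- mdcnn_train(model, crops, tcfg = tcfg)
  expect_true(all(diff(trained$history$lr) <= 0))
  expect_equal(nrow(trained$history), 8L)
})

test_that("weight checkpoints round-trip through save/load", {
  crops <- make_separable_crops(seed = 93)
  cfg <- mdcnn_config(2L, 64L, 2L, temporal_filters = 2L,
                      temporal_kernel = 13L, spatial_filters = 2L,
                      pool_kernel = 20L, pool_stride = 10L,
                      feature_dim = 4L)
  model <- mdcnn_init(cfg, seed = 94)
  model <- mdcnn_train(model, crops,
                       tcfg = train_config(epochs = 2, seed = 94,
                                           checkpoint = "final"))
  path <- withr::local_tempfile(fileext = ".json")
  save_mdcnn(model, path)
  back <- load_mdcnn(path)
  p1 <- predict(model, crops)
  p2 <- predict(back, crops)
  expect_equal(p2$probs, p1$probs, tolerance = 1e-12)
})
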