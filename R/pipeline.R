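#' Leakage-free cross-validated decoding pipeline
#'
#' Runs the full multi-domain decoding protocol on one epoched recording:
#' stratified k-fold split, then per fold (i) CSP fitted on the training
#' trials only, (ii) the three domain tensors built (time, CSP projection,
#' instantaneous phase), (iii) per-channel normalization statistics fitted on
#' the training trials and frozen for the test trials, (iv) sliding-window
#' cropping, (v) network training, and (vi) per-trial accuracy from averaged
#' crop probabilities for each head. The phase transform is per-trial and is
#' computed once; everything fitted (CSP, normalization, network) sees
#' training trials only.
#'
#' @param epochs an `eeg_epochs`, already filtered/resampled (see
#'   [apply_filter()], [resample_epochs()]).
#' @param window_seconds,step_seconds crop geometry (defaults 4 and 0.1 s).
#' @param k number of folds (default 10).
#' @param seed seed controlling folds, initialization, shuffling, dropout.
#' @param L number of CSP filters retained (default: all channels, so the
#'   spatial domain keeps the input geometry).
#' @param csp_ridge diagonal loading for the CSP whitening.
#' @param mi_variant CSP filter scoring variant, see [fit_jad()].
#' @param model_opts named list of overrides for [mdcnn_config()] (e.g.
#'   `temporal_filters`, `feature_dim`, `branches`).
#' @param tcfg a [train_config()].
#' @param out_dir optional directory; when given, the fold reports, history
#'   CSVs and a provenance JSON (config digest, seed, package version) are
#'   written there.
#' @param keep_models keep the trained networks in the result (large).
#' @return A list: `report` (a [cv_report()]), `fold_csp` (per-fold
#'   `csp_model`s), `fold_stats` (per-fold normalization statistics), and
#'   optionally `models`.
#' @export
run_pipeline <- function(epochs, window_seconds = 4, step_seconds = 0.1,
                         k = 10L, seed = 1L, L = NULL, csp_ridge = 0,
                         mi_variant = "log", model_opts = list(),
                         tcfg = train_config(), out_dir = NULL,
                         keep_models = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  labels <- epochs$labels
  folds <- stratified_folds(labels, k, seed)
  win_samples <- as.integer(round(window_seconds * epochs$fs))
  heads <- NULL
  phase_full <- phase_domain(epochs)          # per-trial transform, no fit
  time_full <- time_domain(epochs)
  fold_acc <- NULL
  fold_csp <- vector("list", k)
  fold_stats <- vector("list", k)
  models <- if (keep_models) vector("list", k) else NULL
  for (f in seq_len(k)) {
    tr_ids <- which(folds != f)
    te_ids <- which(folds == f)
    train_ep <- subset_trials(epochs, tr_ids)
    csp <- fit_csp(train_ep, ridge = csp_ridge, mi_variant = mi_variant)
    fold_csp[[f]] <- csp
    spatial_full <- apply_csp(csp, epochs, L)
    doms <- list(time = time_full, spatial = spatial_full,
                 phase = phase_full)
    stats <- list()
    for (d in names(doms)) {
      dt <- doms[[d]]
      fit <- normalize_domain(
        domain_tensor(dt$data[, , tr_ids, drop = FALSE], dt$domain, dt$fs))
      stats[[d]] <- fit$stats
      doms[[d]] <- normalize_domain(dt, fit$stats)$tensor
    }
    fold_stats[[f]] <- stats
    branches <- if (length(model_opts$branches)) model_opts$branches
                else c("time", "spatial", "phase")
    crops <- make_crops(doms[branches], labels, window_seconds, step_seconds)
    tr_crops <- subset_crops(crops, tr_ids)
    te_crops <- subset_crops(crops, te_ids)
    cfg_args <- utils::modifyList(
      list(n_channels = n_channels(epochs), n_samples = win_samples,
           n_classes = length(epochs$class_names), branches = branches),
      model_opts)
    cfg <- do.call(mdcnn_config, cfg_args)
    tcfg_f <- tcfg
    tcfg_f$seed <- tcfg$seed + f
    model <- mdcnn_init(cfg, seed = seed + f)
    model <- mdcnn_train(model, tr_crops, te_crops, tcfg_f)
    preds <- predict(model, te_crops)
    acc <- head_accuracies(preds, labels)
    if (is.null(fold_acc))
      fold_acc <- matrix(NA_real_, k, length(acc),
                         dimnames = list(NULL, names(acc)))
    fold_acc[f, ] <- acc
    if (keep_models) models[[f]] <- model
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(model$history,
                       file.path(out_dir, sprintf("fold%02d_history.csv", f)),
                       row.names = FALSE)
    }
  }
  report <- cv_report(fold_acc, folds, length(epochs$class_names), seed)
  if (!is.null(out_dir)) {
    write_cv_report(report, out_dir)
    cfg_json <- jsonlite::toJSON(
      list(window_seconds = window_seconds, step_seconds = step_seconds,
           k = k, seed = seed, L = L, csp_ridge = csp_ridge,
           mi_variant = mi_variant, model_opts = model_opts,
           train = unclass(tcfg)),
      auto_unbox = TRUE, digits = NA)
    tmp <- file.path(out_dir, "pipeline_config.json")
    writeLines(as.character(cfg_json), tmp)
    prov <- list(config_digest = unname(tools::md5sum(tmp)),
                 seed = seed,
                 package_version = as.character(utils::packageVersion("mdbci")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  out <- list(report = report, fold_csp = fold_csp, fold_stats = fold_stats)
  if (keep_models) out$models <- models
  out
}

#' Single-split training and evaluation
#'
#' A lighter protocol than [run_pipeline()]: one stratified holdout split
#' (per class, a fraction of trials held out for evaluation), same
#' leakage-free fitting rules. Useful for quick experiments such as
#' contrasting wet and dry recordings over several seeds.
#'
#' @inheritParams run_pipeline
#' @param test_fraction per-class fraction of trials held out (default 0.2).
#' @return A list with `acc` (named per-head trial accuracies, %), `csp`,
#'   `model`, `test_ids`.
#' @export
run_split <- function(epochs, test_fraction = 0.2, window_seconds = 4,
                      step_seconds = 0.1, seed = 1L, L = NULL,
                      csp_ridge = 0, model_opts = list(),
                      tcfg = train_config()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  labels <- epochs$labels
  set.seed(seed)
  te_ids <- sort(unlist(lapply(split(seq_along(labels), labels),
                               function(ids)
                                 sample(ids, max(1L, round(test_fraction *
                                                           length(ids)))))))
  tr_ids <- setdiff(seq_along(labels), te_ids)
  csp <- fit_csp(subset_trials(epochs, tr_ids), ridge = csp_ridge)
  branches <- if (length(model_opts$branches)) model_opts$branches
              else c("time", "spatial", "phase")
  doms <- list(time = time_domain(epochs),
               spatial = apply_csp(csp, epochs, L),
               phase = phase_domain(epochs))
  for (d in names(doms)) {
    dt <- doms[[d]]
    fit <- normalize_domain(
      domain_tensor(dt$data[, , tr_ids, drop = FALSE], dt$domain, dt$fs))
    doms[[d]] <- normalize_domain(dt, fit$stats)$tensor
  }
  crops <- make_crops(doms[branches], labels, window_seconds, step_seconds)
  tr_crops <- subset_crops(crops, tr_ids)
  te_crops <- subset_crops(crops, te_ids)
  cfg <- do.call(mdcnn_config, utils::modifyList(
    list(n_channels = n_channels(epochs),
         n_samples = as.integer(round(window_seconds * epochs$fs)),
         n_classes = length(epochs$class_names), branches = branches),
    model_opts))
  model <- mdcnn_init(cfg, seed = seed)
  model <- mdcnn_train(model, tr_crops, te_crops, tcfg)
  preds <- predict(model, te_crops)
  list(acc = head_accuracies(preds, labels), csp = csp, model = model,
       test_ids = te_ids)
}
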