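#' Stratified k-fold assignments
#'
#' Partitions trials into `k` folds while preserving the class proportions:
#' within each class the trials are shuffled and dealt round-robin, so the
#' per-class counts of any two folds differ by at most one.
#'
#' @param labels integer class labels (`1..M`).
#' @param k number of folds (default 10).
#' @param seed integer seed for the shuffle; identical seeds give identical
#'   folds.
#' @return Integer vector of fold ids (`1..k`), one per trial.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  counts <- table(labels)
  if (any(counts < k))
    stop("class ", names(counts)[which.min(counts)], " has fewer trials (",
         min(counts), ") than folds (", k, ")")
  folds <- integer(length(labels))
  rng <- local({ set.seed(seed); lapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    sample(idx, length(idx))
  }) })
  # deal each class round-robin, rotating the starting fold across classes so
  # remainders do not pile onto fold 1
  start <- 0L
  for (idx in rng) {
    folds[idx] <- ((seq_along(idx) - 1L + start) %% k) + 1L
    start <- (start + length(idx)) %% k
  }
  folds
}

#' Per-trial accuracy from crop-level predictions
#'
#' Crop-level class probabilities are averaged per trial (mean of the softmax
#' rows over a trial's crops), the trial is assigned the arg-max class (ties
#' broken toward the lowest class index), and the percentage of correctly
#' assigned trials is returned. Set `aggregate = "crop"` to score crops
#' individually instead.
#'
#' @param probs numeric matrix of crop-level class probabilities
#'   (`crops x classes`).
#' @param trial_index integer vector mapping each crop to its source trial.
#' @param labels integer true class per trial (`1..M`), indexed by trial id.
#' @param aggregate `"trial"` (mean-probability vote, default) or `"crop"`.
#' @param trials integer ids of the trials that must be scored; defaults to
#'   every trial appearing in `trial_index`. A requested trial with no crops
#'   is an error.
#' @return Accuracy as a percentage in `[0, 100]`.
#' @export
trial_accuracy <- function(probs, trial_index, labels,
                           aggregate = c("trial", "crop"), trials = NULL) {
  aggregate <- match.arg(aggregate)
  probs <- as.matrix(probs)
  trial_index <- as.integer(trial_index)
  if (nrow(probs) != length(trial_index))
    stop("probs rows != length(trial_index)")
  ids <- sort(unique(trial_index))
  if (!all(ids %in% seq_along(labels)))
    stop("trial_index refers to trials absent from labels")
  if (aggregate == "crop") {
    pred <- max.col(probs, ties.method = "first")
    return(100 * mean(pred == labels[trial_index]))
  }
  miss <- setdiff(if (is.null(trials)) ids else as.integer(trials), ids)
  if (length(miss))
    stop("trial(s) with zero crops: ", paste(miss, collapse = ", "))
  agg <- rowsum(probs, group = trial_index)            # ordered by trial id
  pred <- max.col(agg, ties.method = "first")
  100 * mean(pred == labels[ids])
}

#' Chance-level confidence limit for classifier accuracy
#'
#' The accuracy a purely random classifier is not expected to exceed at level
#' `alpha`, given the number of evaluation trials. With `p0 = 1/n_classes`,
#' the smallest exceedance count under the binomial normal approximation is
#' `m = ceiling(n p0 + z * sqrt(n p0 (1 - p0)))` with `z = qnorm(1 - alpha/2)`,
#' and the limit is `100 m / n` percent. `method = "binomial"` replaces the
#' normal approximation by the exact binomial quantile.
#'
#' @param n_trials number of evaluation trials.
#' @param n_classes number of classes (>= 2).
#' @param alpha significance level (default 0.05, two-sided z).
#' @param method `"normal"` (default) or `"binomial"`.
#' @return The confidence limit as a percentage.
#' @examples
#' chance_limit(90, 3)   # 43.33 for a 3-class problem on 90 trials
#' chance_limit(288, 4)  # about 30 for a 4-class problem on 288 trials
#' @export
chance_limit <- function(n_trials, n_classes, alpha = 0.05,
                         method = c("normal", "binomial")) {
  method <- match.arg(method)
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  p0 <- 1 / n_classes
  m <- switch(method,
    normal = ceiling(n_trials * p0 +
                     stats::qnorm(1 - alpha / 2) *
                     sqrt(n_trials * p0 * (1 - p0))),
    binomial = stats::qbinom(1 - alpha / 2, n_trials, p0) + 1)
  100 * m / n_trials
}

#' Paired comparison of two accuracy vectors
#'
#' Paired t-test on the per-subject differences plus Cohen's d. By default d
#' is the absolute mean difference over the pooled standard deviation of the
#' two samples, `sqrt((var(a) + var(b)) / 2)`; `d_variant = "paired"` divides
#' by the standard deviation of the differences instead.
#'
#' @param acc_a,acc_b numeric vectors of paired accuracies (%), equal length
#'   >= 2.
#' @param d_variant `"pooled"` (default) or `"paired"`.
#' @return A list with `t`, `p_value`, `cohens_d`, `mean_diff` and
#'   `df`. When the differences have zero variance the t-test is undefined:
#'   `t` and `p_value` are `NA` and the result carries
#'   `zero_variance = TRUE`.
#' @export
paired_stats <- function(acc_a, acc_b, d_variant = c("pooled", "paired")) {
  d_variant <- match.arg(d_variant)
  if (length(acc_a) != length(acc_b)) stop("inputs must have equal length")
  if (length(acc_a) < 2L) stop("need at least two pairs")
  diffs <- acc_a - acc_b
  sd_pool <- sqrt((stats::var(acc_a) + stats::var(acc_b)) / 2)
  denom <- if (d_variant == "pooled") sd_pool else stats::sd(diffs)
  d <- if (denom > 0) abs(mean(diffs)) / denom else if (mean(diffs) == 0) 0 else Inf
  if (stats::sd(diffs) == 0) {
    t0 <- if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
    return(list(t = t0, p_value = NA_real_, cohens_d = d,
                mean_diff = mean(diffs), df = length(diffs) - 1L,
                zero_variance = TRUE))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value, cohens_d = d,
       mean_diff = mean(diffs), df = unname(tt$parameter),
       zero_variance = FALSE)
}

#' Cross-validation report
#'
#' Collects per-fold, per-head trial accuracies together with the chance-level
#' confidence limit for the evaluated problem.
#'
#' @param fold_acc numeric matrix `folds x heads` of accuracies (%), with
#'   column names naming the heads (e.g. time/spatial/phase/multi).
#' @param folds the fold assignment vector used.
#' @param n_classes number of classes.
#' @param seed the fold seed.
#' @param alpha level for the chance limit.
#' @return An object of class `cv_report` with `fold_acc`, `mean`, `sd`,
#'   `chance_limit`, `n_trials`, `n_classes`, `folds`, `seed`.
#' @export
cv_report <- function(fold_acc, folds, n_classes, seed, alpha = 0.05) {
  fold_acc <- as.matrix(fold_acc)
  if (any(fold_acc < 0 | fold_acc > 100)) stop("accuracies must be in [0,100]")
  structure(list(
    fold_acc = fold_acc,
    mean = colMeans(fold_acc),
    sd = apply(fold_acc, 2L, stats::sd),
    chance_limit = chance_limit(length(folds), n_classes, alpha),
    n_trials = length(folds), n_classes = n_classes,
    folds = folds, seed = seed), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds, %d trials, %d classes (chance limit %.2f%%)\n",
              nrow(x$fold_acc), x$n_trials, x$n_classes, x$chance_limit))
  for (h in colnames(x$fold_acc))
    cat(sprintf("  %-8s %.2f%% (sd %.2f)\n", h, x$mean[h], x$sd[h]))
  invisible(x)
}

#' Write a cross-validation report to disk
#'
#' Emits a JSON summary and a tidy CSV (fold, head, accuracy).
#'
#' @param report a `cv_report`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the two paths written.
#' @export
write_cv_report <- function(report, dir, prefix = "cv") {
  stopifnot(inherits(report, "cv_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, paste0(prefix, "_report.json"))
  csv_path <- file.path(dir, paste0(prefix, "_folds.csv"))
  jsonlite::write_json(
    list(mean = as.list(report$mean), sd = as.list(report$sd),
         chance_limit = report$chance_limit, n_trials = report$n_trials,
         n_classes = report$n_classes, seed = report$seed),
    json_path, auto_unbox = TRUE, digits = NA)
  tidy <- data.frame(
    fold = rep(seq_len(nrow(report$fold_acc)), ncol(report$fold_acc)),
    head = rep(colnames(report$fold_acc), each = nrow(report$fold_acc)),
    accuracy = as.vector(report$fold_acc))
  utils::write.csv(tidy, csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}
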