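#' Number of sliding-window crops per trial
#'
#' A window of `window_seconds` slid in steps of `step_seconds` over a trial
#' of `trial_seconds` yields `floor((trial - window) / step) + 1` crops. A 5-s
#' trial cut by a 4-s window at 0.1-s steps gives 11 crops.
#'
#' @param trial_seconds trial duration (s).
#' @param window_seconds crop window length (s), `<= trial_seconds`.
#' @param step_seconds step between crop onsets (s), `> 0`.
#' @return Integer crop count.
#' @export
count_crops <- function(trial_seconds, window_seconds, step_seconds) {
  if (step_seconds <= 0) stop("step_seconds must be > 0")
  if (window_seconds > trial_seconds)
    stop("window (", window_seconds, " s) exceeds trial (", trial_seconds,
         " s)")
  # guard the floor against binary-fraction wobble (e.g. (5-4)/0.1)
  as.integer(floor((trial_seconds - window_seconds) / step_seconds + 1e-9)) + 1L
}

#' Cut aligned sliding-window crops from the three domain tensors
#'
#' Applies the same window offsets to each domain so that crop `j` of trial
#' `i` covers identical sample ranges in the time, spatial and phase tensors.
#' Offsets are `k * step_seconds` for `k = 0, 1, ...`, rounded to the nearest
#' sample. Labels and the crop-to-trial map are replicated per crop so trial
#' level votes can be reassembled after prediction.
#'
#' @param domains a named list of `domain_tensor`s (any non-empty subset of
#'   time/spatial/phase) sharing shape and sampling rate.
#' @param labels integer per-trial class labels.
#' @param window_seconds,step_seconds window geometry; see [count_crops()].
#' @return An object of class `crop_set`: list of per-domain arrays
#'   `channels x window_samples x crops`, plus `labels`, `trial_index`,
#'   `fs`, `window_seconds`, `step_seconds`.
#' @export
make_crops <- function(domains, labels, window_seconds, step_seconds) {
  if (!length(domains)) stop("need at least one domain tensor")
  if (is.null(names(domains)) || any(!nzchar(names(domains))))
    stop("`domains` must be a named list")
  dims <- lapply(domains, function(d) dim(d$data))
  fs <- vapply(domains, function(d) d$fs, numeric(1))
  if (length(unique(dims)) != 1L || length(unique(fs)) != 1L)
    stop("domain tensors disagree in shape or sampling rate")
  fs <- fs[[1L]]
  d <- dims[[1L]]
  n_ch <- d[1L]; n_samp <- d[2L]; n_tr <- d[3L]
  if (length(labels) != n_tr) stop("labels length != trial count")
  trial_seconds <- n_samp / fs
  n_crops <- count_crops(trial_seconds, window_seconds, step_seconds)
  win <- as.integer(round(window_seconds * fs))
  offsets <- as.integer(round((seq_len(n_crops) - 1L) * step_seconds * fs))
  if (max(offsets) + win > n_samp)
    stop("crop window overruns trial end (rounding)")
  total <- n_tr * n_crops
  crop_of <- function(x) {
    out <- array(0, c(n_ch, win, total))
    j <- 0L
    for (i in seq_len(n_tr)) {
      for (o in offsets) {
        j <- j + 1L
        out[, , j] <- x[, (o + 1L):(o + win), i]
      }
    }
    out
  }
  structure(list(
    domains = lapply(domains, function(d) crop_of(d$data)),
    labels = rep(as.integer(labels), each = n_crops),
    trial_index = rep(seq_len(n_tr), each = n_crops),
    fs = fs, window_seconds = window_seconds, step_seconds = step_seconds,
    crops_per_trial = n_crops), class = "crop_set")
}

#' @export
print.crop_set <- function(x, ...) {
  d <- dim(x$domains[[1L]])
  cat(sprintf(
    "<crop_set> %d crops (%d per trial) x %d channels x %d samples @ %g Hz; domains: %s\n",
    d[3L], x$crops_per_trial, d[1L], d[2L], x$fs,
    paste(names(x$domains), collapse = ", ")))
  invisible(x)
}

#' Subset a crop set by trial
#'
#' Keeps every crop whose source trial is in `trials`. Used to carve
#' training/test splits that never separate crops of one trial.
#'
#' @param crops a `crop_set`.
#' @param trials integer trial ids to keep.
#' @return A `crop_set` restricted to those trials.
#' @export
subset_crops <- function(crops, trials) {
  stopifnot(inherits(crops, "crop_set"))
  keep <- crops$trial_index %in% trials
  out <- crops
  out$domains <- lapply(crops$domains, function(a) a[, , keep, drop = FALSE])
  out$labels <- crops$labels[keep]
  out$trial_index <- crops$trial_index[keep]
  out
}
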