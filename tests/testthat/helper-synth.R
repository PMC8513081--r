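# Shared test-scale problem definitions.
#
# Unit tests use `tiny_*` helpers (seconds of runtime). The end-to-end
# checks use the reduced-scale protocol: the generator's default study
# conditions (90 trials x 31 channels x 5 s at 500 Hz), band-passed 4-40 Hz,
# downsampled to 125 Hz, 2-s crops, and a narrow network (8+8 filters,
# D = 20). The methods vignette documents these sizes.

tiny_epochs <- function(n_ch = 3L, n_samp = 64L, n_tr = 12L, fs = 64,
                        n_classes = 2L, seed = 1L) {
  set.seed(seed)
  eeg_epochs(array(rnorm(n_ch * n_samp * n_tr), c(n_ch, n_samp, n_tr)),
             rep(seq_len(n_classes), length.out = n_tr), fs,
             paste0("class", seq_len(n_classes)))
}

# two classes distinguishable by band power on channel 1 vs channel 2
tiny_separable <- function(n_tr = 24L, n_ch = 2L, n_samp = 128L, fs = 64,
                           seed = 1L) {
  set.seed(seed)
  labels <- rep(1:2, length.out = n_tr)
  data <- array(rnorm(n_ch * n_samp * n_tr, sd = 0.5),
                c(n_ch, n_samp, n_tr))
  t <- (seq_len(n_samp) - 1L) / fs
  for (i in seq_len(n_tr)) {
    ch <- labels[i]
    data[ch, , i] <- data[ch, , i] +
      3 * sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi))
  }
  eeg_epochs(data, labels, fs, c("a", "b"))
}

reduced_model_opts <- function() {
  list(temporal_filters = 8L, spatial_filters = 8L, feature_dim = 20L)
}

reduced_preprocess <- function(epochs) {
  resample_epochs(apply_filter(epochs, filter_spec("bandpass", c(4, 40))),
                  125)
}
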