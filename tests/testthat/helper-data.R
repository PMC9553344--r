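# Shared builders for small test fixtures (all generated in code).

# Epochs straight from a numeric array, bypassing file I/O.
make_epochs <- function(arr, labels, fs = 128,
                        montage = eegchansel::montage(paste0("Ch", seq_len(dim(arr)[2])))) {
  structure(list(epochs = arr, labels = as.integer(labels), fs = fs,
                 epoch_length_s = dim(arr)[3] / fs, montage = montage),
            class = "eeg_epochs")
}

# Random epochs: n_ep x n_ch x n_s standard normal, balanced labels.
random_epochs <- function(n_ep = 20, n_ch = 4, n_s = 128, fs = 128, seed = 1) {
  withr::with_seed(seed, {
    arr <- array(rnorm(n_ep * n_ch * n_s), dim = c(n_ep, n_ch, n_s))
    make_epochs(arr, rep(c(0L, 1L), length.out = n_ep), fs = fs)
  })
}

# Feature matrix with an optional channel whose column copies the label.
planted_fm <- function(n = 40, n_ch = 10, planted = 1L, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n * n_ch), n, n_ch)
    if (!is.na(planted)) X[, planted] <- y
    eegchansel::feature_matrix(X, y, paste0("Ch", seq_len(n_ch)), "F")
  })
}

# Reduced-scale synthetic study: 2 subjects x 60 s/state, defaults otherwise.
reduced_synth_spec <- function(seed, ...) {
  eegchansel::synth_spec(n_subjects = 2L, seconds_per_state = 60L, seed = seed, ...)
}

# Epochs (128 Hz, 1 s) from a generated dataset.
dataset_epochs <- function(ds) {
  sets <- lapply(ds$recordings, function(pair) {
    list(eegchansel::epoch_recording(eegchansel::resample_recording(pair$JX, 128), 0L),
         eegchansel::epoch_recording(eegchansel::resample_recording(pair$ZD, 128), 1L))
  })
  eegchansel::bind_epochs(unlist(sets, recursive = FALSE))
}
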