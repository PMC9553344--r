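#' Multichannel EEG recording
#'
#' Container for a continuous recording: a channels-by-samples numeric matrix
#' in microvolts, a sampling rate, a montage, and an opaque subject id.
#'
#' @param data Numeric matrix, channels x samples. Row order must match the
#'   montage channel order.
#' @param fs Sampling rate in Hz (> 0).
#' @param montage An `eeg_montage` (see [montage()]).
#' @param subject_id Identifier string.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, montage = default_montage(), subject_id = "S1") {
  data <- as.matrix(data)
  if (!is.numeric(data)) abort_data("recording data must be numeric")
  if (nrow(data) != length(montage)) {
    abort_config("recording has %d channels but montage has %d",
                 nrow(data), length(montage))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort_config("fs must be a positive scalar (got %s)", format(fs)[1])
  }
  bad <- which(!apply(data, 1L, function(r) all(is.finite(r))))
  if (length(bad)) {
    abort_data("non-finite samples in channel(s): %s",
               paste(montage[bad], collapse = ", "))
  }
  rownames(data) <- unclass(montage)
  structure(list(data = data, fs = fs, montage = montage,
                 subject_id = as.character(subject_id)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Load a recording from file
#'
#' Supports 16-bit EDF/EDF+C (`format = "edf"`) and delimited numeric text
#' (`format = "delimited"`; comma- or tab-separated, channels as columns,
#' one header line of electrode names). Reference electrodes A1/A2, if
#' present, are dropped, and channels are reordered to match the montage.
#'
#' @param path File path.
#' @param format `"edf"` or `"delimited"`.
#' @param montage Target `eeg_montage`, or `"auto"` to take the montage from
#'   the file's channel labels (after dropping A1/A2).
#' @param fs Sampling rate in Hz; required for delimited files (delimited
#'   text carries no rate), ignored for EDF.
#' @param subject_id Identifier; defaults to the file base name.
#' @return An `eeg_recording`.
#' @export
load_recording <- function(path, format = c("edf", "delimited"),
                           montage = "auto", fs = NULL,
                           subject_id = tools::file_path_sans_ext(basename(path))) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_config("file not found: %s", path)
  raw <- switch(format,
    edf = read_edf(path),
    delimited = {
      if (is.null(fs)) abort_config("fs is required for delimited input")
      read_delimited_recording(path, fs)
    })
  # raw: list(data = channels x samples, fs, labels)
  keep <- !(raw$labels %in% REFERENCE_ELECTRODES)
  labels <- raw$labels[keep]
  data <- raw$data[keep, , drop = FALSE]
  if (identical(montage, "auto")) montage <- montage(labels)
  missing <- setdiff(unclass(montage), labels)
  if (length(missing)) {
    abort_config("file %s lacks montage channel(s): %s", path,
                 paste(missing, collapse = ", "))
  }
  data <- data[match(unclass(montage), labels), , drop = FALSE]
  recording(data, raw$fs, montage, subject_id)
}

#' Resample a recording
#'
#' Rate reduction by polyphase FIR resampling (delay-compensated anti-alias
#' low-pass, `signal::resample`). Only downsampling (or the identity) is
#' supported; duration is preserved to within one output sample.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Target rate in Hz, `<= rec$fs`.
#' @return An `eeg_recording` at `target_fs`.
#' @export
resample_recording <- function(rec, target_fs = 128) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs) {
    abort_config("upsampling not supported (%g Hz -> %g Hz)", rec$fs, target_fs)
  }
  if (target_fs == rec$fs) return(rec)
  frac <- ratio_integers(target_fs, rec$fs)
  out <- t(apply(rec$data, 1L, function(x) signal::resample(x, frac[1], frac[2])))
  recording(out, target_fs, rec$montage, rec$subject_id)
}

# Smallest integers p/q with p/q == target/orig (rates may be non-integer).
ratio_integers <- function(target, orig) {
  scale <- 1
  while (abs(target * scale - round(target * scale)) > 1e-9 ||
         abs(orig * scale - round(orig * scale)) > 1e-9) {
    scale <- scale * 10
    if (scale > 1e6) abort_config("cannot express %g/%g as an integer ratio", target, orig)
  }
  p <- round(target * scale); q <- round(orig * scale)
  g <- gcd_int(p, q)
  c(p / g, q / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Labeled fixed-length epochs
#'
#' Cuts a recording into consecutive non-overlapping windows of
#' `epoch_length_s` seconds, all carrying one class label (0 = resting JX,
#' 1 = fatigue ZD). Trailing samples that do not fill a window are dropped.
#'
#' @param rec An `eeg_recording`.
#' @param label Class label, 0 or 1.
#' @param epoch_length_s Window length in seconds (default 1).
#' @return An `eeg_epochs` object: a list with `epochs` (epoch x channel x
#'   sample array), `labels`, `fs`, `epoch_length_s`, `montage`.
#' @export
epoch_recording <- function(rec, label, epoch_length_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!label %in% c(0, 1)) abort_config("label must be 0 (JX) or 1 (ZD)")
  len <- rec$fs * epoch_length_s
  if (abs(len - round(len)) > 1e-9) {
    abort_config("fs * epoch_length_s must be an integer sample count (got %g)", len)
  }
  len <- as.integer(round(len))
  n_ep <- floor(ncol(rec$data) / len)
  if (n_ep < 1L) abort_data("recording shorter than one %gs epoch", epoch_length_s)
  n_ch <- nrow(rec$data)
  arr <- array(NA_real_, dim = c(n_ep, n_ch, len))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- rec$data[, ((e - 1L) * len + 1L):(e * len)]
  }
  structure(list(epochs = arr, labels = rep(as.integer(label), n_ep),
                 fs = rec$fs, epoch_length_s = epoch_length_s,
                 montage = rec$montage),
            class = "eeg_epochs")
}

#' Concatenate epoch sets
#'
#' @param ... `eeg_epochs` objects sharing fs, epoch length and montage.
#' @return A single `eeg_epochs` with epochs stacked in argument order.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "eeg_epochs")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "eeg_epochs")))
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (s$fs != ref$fs || s$epoch_length_s != ref$epoch_length_s ||
        !identical(unclass(s$montage), unclass(ref$montage))) {
      abort_config("epoch sets differ in fs, epoch length, or montage")
    }
  }
  arr <- do.call(abind_first, lapply(sets, `[[`, "epochs"))
  structure(list(epochs = arr, labels = unlist(lapply(sets, `[[`, "labels")),
                 fs = ref$fs, epoch_length_s = ref$epoch_length_s,
                 montage = ref$montage),
            class = "eeg_epochs")
}

# rbind for 3-d arrays along the first (epoch) dimension
abind_first <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, dim = c(sum(vapply(parts, function(p) dim(p)[1], 1L)), d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz (%d JX, %d ZD)\n",
              d[1], d[2], d[3], x$fs, sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}
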