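#' Synthetic two-state EEG specification
#'
#' Describes a generated dataset shaped like a two-state (resting vs
#' fatigue) driving-fatigue study: per subject, one resting and one
#' fatigue recording of `seconds_per_state` seconds at `fs` Hz over
#' `n_channels` electrodes. Every channel carries 1/f-shaped background
#' noise plus alpha-band (8-13 Hz) and theta-band (4-8 Hz) band-limited
#' oscillations. In the informative channels the fatigue state multiplies
#' the theta-band amplitude by `theta_power_shift` (fatigue EEG shows
#' elevated theta power) and becomes more regular by `complexity_shift`
#' (a 6 Hz sinusoid is mixed in and broadband noise damped, lowering fuzzy
#' entropy); all other channels are distributionally identical across
#' states.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param seconds_per_state Seconds recorded per state (default 300).
#' @param fs Sampling rate in Hz (default 1000).
#' @param n_channels Channel count (default 30, the standard montage).
#' @param informative_channels Channel indices carrying the state effect;
#'   default `c(27, 28, 29, 17, 24, 9)` (T6, O1, Oz, T4, P3, FC3 --
#'   temporo-parieto-occipital sites typically sensitive to fatigue).
#' @param theta_power_shift Multiplicative theta-amplitude factor in the
#'   fatigue state of informative channels (default 2).
#' @param complexity_shift Regularity shift in `[0, 1]` for the fatigue
#'   state of informative channels (default 0.4): adds a 6 Hz sinusoid of
#'   amplitude `8 * complexity_shift` microvolts and damps background noise
#'   by `1 - complexity_shift / 2`.
#' @param noise_sd Background (1/f) noise SD in microvolts (default 10).
#' @param seed RNG seed; generation is fully reproducible.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(n_subjects = 10L, seconds_per_state = 300L, fs = 1000,
                       n_channels = 30L,
                       informative_channels = c(27L, 28L, 29L, 17L, 24L, 9L),
                       theta_power_shift = 2, complexity_shift = 0.4,
                       noise_sd = 10, seed = 1L) {
  if (n_subjects < 1L || seconds_per_state < 1L || fs <= 0 || n_channels < 1L) {
    abort_config("subject count, duration, fs, and channel count must be positive")
  }
  if (length(informative_channels) &&
      !all(informative_channels %in% seq_len(n_channels))) {
    abort_config("informative_channels must lie in 1..%d", n_channels)
  }
  if (theta_power_shift <= 0) abort_config("theta_power_shift must be > 0")
  if (complexity_shift < 0 || complexity_shift > 1) {
    abort_config("complexity_shift must be in [0, 1]")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 seconds_per_state = as.integer(seconds_per_state),
                 fs = fs, n_channels = as.integer(n_channels),
                 informative_channels = as.integer(informative_channels),
                 theta_power_shift = theta_power_shift,
                 complexity_shift = complexity_shift,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

# Unit-SD noise confined to [lo, hi) Hz, built by spectral masking of white
# noise. `shape = "pink"` instead applies a 1/sqrt(f) amplitude profile
# over the whole axis (1/f power), with a 1 Hz flattening floor.
spectral_noise <- function(n, fs, lo = NULL, hi = NULL, shape = c("band", "pink")) {
  shape <- match.arg(shape)
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)  # two-sided axis
  amp <- if (shape == "pink") 1 / sqrt(pmax(f_fold, 1)) else
    as.numeric(f_fold >= lo & f_fold < hi)
  amp[1] <- 0  # no DC
  x <- Re(stats::fft(spec * amp, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

# Fixed oscillation amplitudes (microvolts) of the generative model; the
# state effects scale these, they are not themselves exposed as knobs.
SYNTH_ALPHA_SD <- 4
SYNTH_THETA_SD <- 4
SYNTH_REG_AMP <- 8

#' Generate a synthetic two-state dataset
#'
#' @param spec A [synth_spec()].
#' @param montage Montage for the recordings; must match `n_channels`
#'   (default: the standard 30-channel montage when `n_channels` is 30,
#'   otherwise `Ch1..ChN`).
#' @return A `synth_dataset`: list with `recordings` (per subject, a list
#'   with elements `JX` and `ZD`, each an `eeg_recording`), `ground_truth`
#'   (informative channel indices), and `spec`.
#' @export
synth_generate <- function(spec = synth_spec(), montage = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(montage)) {
    montage <- if (spec$n_channels == 30L) default_montage() else
      montage(paste0("Ch", seq_len(spec$n_channels)))
  }
  if (length(montage) != spec$n_channels) {
    abort_config("montage size %d != n_channels %d", length(montage), spec$n_channels)
  }
  n <- spec$seconds_per_state * spec$fs
  t <- (seq_len(n) - 1) / spec$fs
  recordings <- withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(s) {
      one_state <- function(state) {  # state: 0 = JX, 1 = ZD
        data <- matrix(NA_real_, spec$n_channels, n)
        for (ch in seq_len(spec$n_channels)) {
          informative <- state == 1L && ch %in% spec$informative_channels
          theta_amp <- SYNTH_THETA_SD * if (informative) spec$theta_power_shift else 1
          damp <- if (informative) 1 - spec$complexity_shift / 2 else 1
          reg_amp <- if (informative) SYNTH_REG_AMP * spec$complexity_shift else 0
          x <- spec$noise_sd * damp * spectral_noise(n, spec$fs, shape = "pink") +
            SYNTH_ALPHA_SD * spectral_noise(n, spec$fs, 8, 13) +
            theta_amp * spectral_noise(n, spec$fs, 4, 8)
          if (reg_amp > 0) {
            x <- x + reg_amp * sin(2 * pi * 6 * t + stats::runif(1, 0, 2 * pi))
          }
          data[ch, ] <- x
        }
        recording(data, spec$fs, montage, subject_id = sprintf("synth%02d", s))
      }
      list(JX = one_state(0L), ZD = one_state(1L))
    })
  })
  structure(list(recordings = recordings,
                 ground_truth = spec$informative_channels,
                 spec = spec),
            class = "synth_dataset")
}

#' Write a synthetic dataset to disk
#'
#' One file per subject and state (`<subject>_JX.<ext>` / `<subject>_ZD.<ext>`)
#' in delimited or EDF format, plus `manifest.json` recording the spec,
#' seed, and ground-truth channels.
#'
#' @param ds A `synth_dataset` from [synth_generate()].
#' @param dir Output directory (created if missing).
#' @param format `"delimited"` or `"edf"`.
#' @return The manifest path, invisibly.
#' @export
write_synth_dataset <- function(ds, dir, format = c("delimited", "edf")) {
  stopifnot(inherits(ds, "synth_dataset"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "edf") "edf" else "csv"
  files <- list()
  for (pair in ds$recordings) {
    for (state in c("JX", "ZD")) {
      rec <- pair[[state]]
      path <- file.path(dir, sprintf("%s_%s.%s", rec$subject_id, state, ext))
      if (format == "edf") write_edf(rec, path) else write_delimited_recording(rec, path)
      files[[length(files) + 1L]] <- list(path = basename(path),
                                          subject = rec$subject_id,
                                          state = state)
    }
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(spec = unclass(ds$spec), ground_truth = ds$ground_truth,
         format = format, fs = ds$spec$fs, files = files),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
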