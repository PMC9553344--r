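#' Fuzzy-entropy parameters
#'
#' @param m Embedding window length (default 2).
#' @param r Similarity tolerance (default 0.25). With `r_mode = "relative"`
#'   (default) the effective tolerance is `r` times the series' population
#'   standard deviation, making the measure amplitude-invariant; with
#'   `"absolute"` it is used as-is, in signal units.
#' @param n_exp Exponent of the exponential membership function (default 2).
#' @param r_mode `"relative"` or `"absolute"`.
#' @return A `fe_params` object.
#' @export
fe_params <- function(m = 2L, r = 0.25, n_exp = 2, r_mode = c("relative", "absolute")) {
  r_mode <- match.arg(r_mode)
  if (m < 1L) abort_config("m must be >= 1")
  if (r <= 0) abort_config("r must be > 0")
  if (n_exp <= 0) abort_config("n_exp must be > 0")
  structure(list(m = as.integer(m), r = r, n_exp = n_exp, r_mode = r_mode),
            class = "fe_params")
}

#' Fuzzy entropy of a series
#'
#' Complexity measure comparing the similarity of embedded windows of
#' length `m` against windows of length `m + 1`: windows of each length are
#' compared pairwise by Chebyshev distance, distances are mapped to graded
#' memberships `exp(-(d / r_eff)^n_exp)`, memberships are averaged excluding
#' self-comparisons, and the entropy is the log-ratio of the two averages.
#' Higher values mean more irregular series; a constant series has fuzzy
#' entropy exactly 0.
#'
#' @param signal Numeric vector of length at least `m + 2`.
#' @param p A [fe_params()] object.
#' @return Non-negative scalar.
#' @examples
#' set.seed(1)
#' fuzzy_entropy(rnorm(200)) > fuzzy_entropy(sin(2 * pi * (1:200) / 20))
#' @export
fuzzy_entropy <- function(signal, p = fe_params()) {
  stopifnot(inherits(p, "fe_params"))
  if (!all(is.finite(signal))) abort_data("non-finite values in fuzzy_entropy input")
  if (length(signal) < p$m + 2L) {
    abort_config("fuzzy_entropy needs length >= m + 2 = %d (got %d)",
                 p$m + 2L, length(signal))
  }
  fuzzen_cpp(as.numeric(signal), p$m, p$r, p$n_exp, p$r_mode == "relative")
}

#' Fuzzy-entropy features per epoch and channel
#'
#' @param epochs An `eeg_epochs` object.
#' @param p A [fe_params()] object.
#' @return A [feature_matrix()] with one `FE` column per channel.
#' @export
fe_features <- function(epochs, p = fe_params()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$epochs)
  X <- matrix(aperm(epochs$epochs, c(3L, 1L, 2L)), nrow = d[3])
  vals <- fuzzen_cols_cpp(X, p$m, p$r, p$n_exp, p$r_mode == "relative")
  feature_matrix(matrix(vals, nrow = d[1], ncol = d[2]),
                 labels = epochs$labels,
                 channels = unclass(epochs$montage),
                 feature = "FE")
}
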