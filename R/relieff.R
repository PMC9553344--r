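#' ReliefF parameters
#'
#' @param m_iter Number of sampled instances per run (default 80).
#' @param k_nn Nearest hits and nearest misses per sampled instance
#'   (default 10).
#' @param seed RNG seed for instance sampling.
#' @return A `relieff_params` object.
#' @export
relieff_params <- function(m_iter = 80L, k_nn = 10L, seed = 1L) {
  if (m_iter < 1L) abort_config("m_iter must be >= 1")
  if (k_nn < 1L) abort_config("k_nn must be >= 1")
  structure(list(m_iter = as.integer(m_iter), k_nn = as.integer(k_nn),
                 seed = as.integer(seed)),
            class = "relieff_params")
}

#' ReliefF channel weights
#'
#' Two-class ReliefF: columns are min-max scaled to `[0, 1]` (a constant
#' column scales to all zeros, contributing zero weight); `m_iter` instances
#' are sampled uniformly without replacement; for each, the `k_nn` nearest
#' same-class instances (hits) and `k_nn` nearest other-class instances
#' (misses) under Euclidean distance are found; each column's weight is
#' decreased by the mean absolute hit difference and increased by the mean
#' absolute miss difference, both divided by the number of sampled
#' instances. A channel's weight is the mean of its columns' weights (so a
#' fused matrix averages its two features). Ties in the final ordering go
#' to the lower channel index.
#'
#' @param fm A [feature_matrix()] with at least `k_nn + 1` samples per class.
#' @param p A [relieff_params()] object.
#' @return A `channel_ranking`: list with `weights` (per channel, in channel
#'   order), `order` (channel indices, best first), `feature_weights`
#'   (per column), and `channels` (names).
#' @export
relieff_weights <- function(fm, p = relieff_params()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(p, "relieff_params"))
  X <- fm$values
  y <- fm$labels
  n <- nrow(X)
  for (cls in c(0L, 1L)) {
    if (sum(y == cls) < p$k_nn + 1L) {
      abort_config("class %d has %d samples; need > k_nn = %d",
                   cls, sum(y == cls), p$k_nn)
    }
  }
  rng <- apply(X, 2L, function(col) diff(range(col)))
  Xs <- sweep(X, 2L, apply(X, 2L, min), "-")
  Xs <- sweep(Xs, 2L, ifelse(rng > 0, rng, 1), "/")  # constant cols -> 0

  m_used <- min(p$m_iter, n)
  idx <- withr::with_seed(p$seed, sample.int(n, m_used))
  w <- numeric(ncol(X))
  for (i in idx) {
    d2 <- colSums((t(Xs) - Xs[i, ])^2)
    same <- which(y == y[i]); same <- same[same != i]
    other <- which(y != y[i])
    hits <- same[order(d2[same])[seq_len(p$k_nn)]]
    misses <- other[order(d2[other])[seq_len(p$k_nn)]]
    hit_diff <- colMeans(abs(Xs[hits, , drop = FALSE] -
                             matrix(Xs[i, ], p$k_nn, ncol(Xs), byrow = TRUE)))
    miss_diff <- colMeans(abs(Xs[misses, , drop = FALSE] -
                              matrix(Xs[i, ], p$k_nn, ncol(Xs), byrow = TRUE)))
    w <- w - unname(hit_diff) / m_used + unname(miss_diff) / m_used
  }
  cw <- as.numeric(tapply(w, fm$column_map$channel, mean))
  ord <- order(-cw, seq_along(cw))
  structure(list(weights = cw, order = ord, feature_weights = w,
                 channels = fm$channels),
            class = "channel_ranking")
}

#' @export
print.channel_ranking <- function(x, ...) {
  cat("<channel_ranking>\n")
  print(utils::head(ranking_table(x), 10))
  if (length(x$order) > 10) cat(sprintf("... %d more channels\n", length(x$order) - 10))
  invisible(x)
}

#' Ranking table in reporting units
#'
#' Channel number, name, and weight sorted descending, with the weight
#' optionally scaled (e.g. `1e-3` prints weights in units of 10^-3, the
#' convention used for published weight tables).
#'
#' @param ranking A `channel_ranking`.
#' @param unit Weight scale divisor (default 1: raw weights).
#' @return A data.frame with columns `number`, `channel`, `weight`.
#' @export
ranking_table <- function(ranking, unit = 1) {
  stopifnot(inherits(ranking, "channel_ranking"))
  data.frame(number = ranking$order,
             channel = ranking$channels[ranking$order],
             weight = ranking$weights[ranking$order] / unit)
}
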