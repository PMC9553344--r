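#' Channel selection by ReliefF-ordered forward selection
#'
#' The canonical method: rank channels once by ReliefF weight, then grow
#' the channel subset from the empty set by always adding the
#' highest-weighted remaining channel (so the size-n subset is the first n
#' entries of the ranking), scoring every subset size with cross-validated
#' KNN accuracy. The optimal subset is the smallest size attaining the
#' maximum accuracy.
#'
#' @param fm A [feature_matrix()].
#' @param p A [relieff_params()] object.
#' @param ep An [eval_params()] object.
#' @return A `selection_result`: list with `ranking` (a `channel_ranking`),
#'   `accuracy_by_size` (length = channel count), `optimal_size`,
#'   `optimal_channels` (names, in selection order), and `method`.
#' @export
relieff_sfs <- function(fm, p = relieff_params(), ep = eval_params()) {
  ranking <- relieff_weights(fm, p)
  n_ch <- length(ranking$order)
  acc <- vapply(seq_len(n_ch), function(n) {
    knn_cv_accuracy(fm, ranking$order[seq_len(n)], ep)
  }, numeric(1))
  selection_result(ranking, acc, method = "relieff_sfs")
}

#' Channel selection by accuracy-greedy forward selection
#'
#' Classical SFS over channels, provided as a comparison mode: at each step
#' every remaining channel is trialled and the one maximizing
#' cross-validated KNN accuracy joins the subset (accuracy ties go to the
#' lower channel index). Quadratic in the channel count.
#'
#' @inheritParams relieff_sfs
#' @return A `selection_result` (its `ranking` holds the greedy selection
#'   order; greedy step accuracies stand in for weights).
#' @export
greedy_sfs <- function(fm, ep = eval_params()) {
  n_ch <- length(fm$channels)
  chosen <- integer(0)
  acc <- numeric(n_ch)
  remaining <- seq_len(n_ch)
  for (step in seq_len(n_ch)) {
    cand_acc <- vapply(remaining, function(ch) {
      knn_cv_accuracy(fm, c(chosen, ch), ep)
    }, numeric(1))
    best <- remaining[which.max(cand_acc)]  # first max: lower index wins ties
    chosen <- c(chosen, best)
    acc[step] <- max(cand_acc)
    remaining <- setdiff(remaining, best)
  }
  weights <- numeric(n_ch)
  weights[chosen] <- rev(seq_len(n_ch))  # rank surrogate, best first
  ranking <- structure(list(weights = weights, order = chosen,
                            feature_weights = NULL, channels = fm$channels),
                       class = "channel_ranking")
  selection_result(ranking, acc, method = "greedy_sfs")
}

selection_result <- function(ranking, accuracy_by_size, method) {
  optimal_size <- which.max(accuracy_by_size)  # first max = smallest subset
  structure(list(ranking = ranking,
                 accuracy_by_size = accuracy_by_size,
                 optimal_size = optimal_size,
                 optimal_channels = ranking$channels[ranking$order[seq_len(optimal_size)]],
                 method = method),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> (%s)\n", x$method))
  cat(sprintf("  optimal subset: %d of %d channels, accuracy %.2f%%\n",
              x$optimal_size, length(x$accuracy_by_size),
              100 * x$accuracy_by_size[x$optimal_size]))
  cat("  channels:", paste(x$optimal_channels, collapse = ", "), "\n")
  invisible(x)
}

#' Accuracy-by-subset-size table
#'
#' @param result A `selection_result`.
#' @param percent Report accuracy in percent (default TRUE, matching the
#'   usual published table layout).
#' @return data.frame with columns `n_channels`, `accuracy`.
#' @export
accuracy_table <- function(result, percent = TRUE) {
  stopifnot(inherits(result, "selection_result"))
  data.frame(n_channels = seq_along(result$accuracy_by_size),
             accuracy = result$accuracy_by_size * if (percent) 100 else 1)
}
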