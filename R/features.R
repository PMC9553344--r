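#' Labeled feature matrix
#'
#' Epochs-by-columns matrix of per-channel feature values with per-epoch
#' class labels (0 = resting, 1 = fatigue) and a column map recording which
#' (channel, feature) pair each column holds. Columns are channel-major:
#' all of channel 1's features first, then channel 2's, and so on -- for a
#' fused matrix the two features of a channel sit in adjacent columns.
#'
#' @param values Numeric matrix, epochs x (channels * features_per_channel).
#'   For a single feature (`feature` a scalar name), one column per channel.
#' @param labels Integer vector of 0/1, one per epoch.
#' @param channels Character vector of channel names, in channel order.
#' @param feature Feature name(s): length 1 for a single-feature matrix, or
#'   length `features_per_channel` for an interleaved (fused) matrix.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, labels, channels, feature) {
  values <- as.matrix(values)
  labels <- as.integer(labels)
  fpc <- length(feature)
  if (ncol(values) != length(channels) * fpc) {
    abort_config("feature matrix has %d columns; expected %d channels x %d features",
                 ncol(values), length(channels), fpc)
  }
  if (nrow(values) != length(labels)) {
    abort_config("feature matrix has %d rows but %d labels", nrow(values), length(labels))
  }
  if (!all(labels %in% c(0L, 1L))) abort_config("labels must be 0 or 1")
  if (!all(is.finite(values))) abort_data("non-finite feature values")
  column_map <- data.frame(
    channel = rep(seq_along(channels), each = fpc),
    feature = rep(feature, times = length(channels)),
    stringsAsFactors = FALSE)
  colnames(values) <- paste(channels[column_map$channel], column_map$feature, sep = ".")
  structure(list(values = values, labels = labels, channels = as.character(channels),
                 column_map = column_map, features_per_channel = fpc),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d columns (%d channels x %s) [%d JX, %d ZD]\n",
              nrow(x$values), ncol(x$values), length(x$channels),
              paste(unique(x$column_map$feature), collapse = "+"),
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' Fuse two single-feature matrices channel-by-channel
#'
#' Interleaves the columns of `a` and `b` so each channel contributes two
#' adjacent columns (`a`'s feature first). Inputs must share epochs,
#' labels, and channel order.
#'
#' @param a,b `feature_matrix` objects with `features_per_channel = 1`.
#' @return A `feature_matrix` with `features_per_channel = 2`.
#' @export
fuse <- function(a, b) {
  stopifnot(inherits(a, "feature_matrix"), inherits(b, "feature_matrix"))
  if (a$features_per_channel != 1L || b$features_per_channel != 1L) {
    abort_config("fuse expects single-feature matrices")
  }
  if (nrow(a$values) != nrow(b$values) || !identical(a$labels, b$labels) ||
      !identical(a$channels, b$channels)) {
    abort_config("fuse: matrices differ in epochs, labels, or channels")
  }
  nch <- length(a$channels)
  values <- matrix(NA_real_, nrow(a$values), 2L * nch)
  values[, seq(1L, 2L * nch, by = 2L)] <- a$values
  values[, seq(2L, 2L * nch, by = 2L)] <- b$values
  feature_matrix(values, a$labels, a$channels,
                 feature = c(a$column_map$feature[1], b$column_map$feature[1]))
}

#' Columns belonging to a set of channels
#'
#' @param fm A `feature_matrix`.
#' @param channels Integer channel indices.
#' @return Integer column indices into `fm$values`, channel-major.
#' @keywords internal
channel_columns <- function(fm, channels) {
  which(fm$column_map$channel %in% channels)
}

#' Write / read a feature matrix as delimited text
#'
#' Tab-separated with a two-row header (channel name then feature name per
#' column; the first column is `label`). Values are written with 12
#' significant digits, so a round trip reproduces them to that precision.
#'
#' @param fm A `feature_matrix`.
#' @param path File path.
#' @return `read_feature_matrix()` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  ch_row <- c("label", fm$channels[fm$column_map$channel])
  ft_row <- c("label", fm$column_map$feature)
  writeLines(paste(ch_row, collapse = "\t"), con)
  writeLines(paste(ft_row, collapse = "\t"), con)
  body <- cbind(as.character(fm$labels),
                matrix(formatC(fm$values, format = "g", digits = 12),
                       nrow = nrow(fm$values)))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) abort_config("feature matrix file too short: %s", path)
  ch_row <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  ft_row <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  body <- do.call(rbind, strsplit(lines[-(1:2)], "\t", fixed = TRUE))
  labels <- as.integer(body[, 1])
  values <- matrix(as.numeric(body[, -1, drop = FALSE]), nrow = nrow(body))
  channels <- unique(ch_row)
  fpc <- length(ch_row) / length(channels)
  feature_matrix(values, labels, channels, feature = ft_row[seq_len(fpc)])
}
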