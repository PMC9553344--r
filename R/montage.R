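#' Electrode montage
#'
#' A montage is an ordered set of electrode names with 1-based channel
#' numbers. [default_montage()] returns the 30-electrode 10-20 layout used
#' throughout this package (a 32-electrode cap with the two reference
#' electrodes A1/A2 removed): Fp1 (1) through O2 (30).
#'
#' @param labels Character vector of unique electrode names, in channel order.
#' @return An object of class `eeg_montage`: a character vector of labels
#'   whose positions are the channel numbers.
#' @examples
#' m <- default_montage()
#' length(m)          # 30
#' which(m == "T6")   # 27
#' @export
montage <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) abort_config("montage must have at least one electrode")
  if (anyDuplicated(labels)) {
    abort_config("montage labels must be unique (duplicated: %s)",
                 paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(labels, class = "eeg_montage")
}

#' @rdname montage
#' @export
default_montage <- function() {
  montage(c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FT7", "FC3", "FCz",
            "FC4", "FT8", "T3", "C3", "Cz", "C4", "T4", "TP7", "CP3", "CPz",
            "CP4", "TP8", "T5", "P3", "Pz", "P4", "T6", "O1", "Oz", "O2"))
}

#' Read or write a montage file
#'
#' Plain two-column text: electrode name, 1-based channel number. Rows may be
#' in any order; the number column defines the channel order.
#'
#' @param path File path.
#' @param m An `eeg_montage`.
#' @return `read_montage()` returns an `eeg_montage`.
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) abort_config("montage file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, col.names = c("label", "number"),
                           colClasses = c("character", "integer"))
  if (!setequal(tab$number, seq_len(nrow(tab)))) {
    abort_config("montage channel numbers must be 1..%d", nrow(tab))
  }
  montage(tab$label[order(tab$number)])
}

#' @rdname read_montage
#' @export
write_montage <- function(m, path) {
  utils::write.table(data.frame(label = unclass(m), number = seq_along(m)),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels: %s ... %s\n",
              length(x), x[1], x[length(x)]))
  invisible(x)
}

# Reference electrodes dropped on load; not part of any analysis montage.
REFERENCE_ELECTRODES <- c("A1", "A2")
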