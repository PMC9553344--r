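# File I/O: delimited numeric matrices and 16-bit EDF/EDF+C.

# ---- delimited text -------------------------------------------------------

# Returns list(data = channels x samples, fs, labels). Header row of
# electrode names; comma or tab separated (sniffed from the header line).
read_delimited_recording <- function(path, fs) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  mat <- as.matrix(tab)
  if (!is.numeric(mat)) abort_data("non-numeric values in %s", path)
  list(data = t(mat), fs = fs, labels = colnames(tab))
}

#' Write a recording as delimited text
#'
#' Channels as columns, one header line of electrode names. The sampling
#' rate is not stored in the file; pass it again on load.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @param sep Column separator, `","` (default) or `"\t"`.
#' @export
write_delimited_recording <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(t(rec$data), path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = unclass(rec$montage))
  invisible(path)
}

# ---- EDF ------------------------------------------------------------------

# Minimal reader for 16-bit EDF and EDF+ continuous files. Annotation
# channels are dropped. Returns list(data, fs, labels).
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ascii <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- ascii(8L)
  if (version != "0") abort_config("not an EDF file (version field '%s'): %s", version, path)
  ascii(80L); ascii(80L); ascii(8L); ascii(8L)   # patient, recording, date, time
  header_bytes <- as.integer(ascii(8L))
  reserved <- ascii(44L)
  if (nzchar(reserved) && !startsWith(reserved, "EDF+C")) {
    abort_config("only continuous EDF is supported (reserved field '%s')", reserved)
  }
  n_records <- as.integer(ascii(8L))
  record_dur <- as.numeric(ascii(8L))
  ns <- as.integer(ascii(4L))
  field <- function(w) vapply(seq_len(ns), function(i) ascii(w), "")
  labels <- field(16L)
  field(80L); field(8L)                           # transducer, physical dim
  phys_min <- as.numeric(field(8L)); phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L)); dig_max <- as.numeric(field(8L))
  field(80L)                                      # prefiltering
  spr <- as.integer(field(8L))                    # samples per record
  field(32L)                                      # reserved
  stopifnot(header_bytes == 256L * (ns + 1L))

  keep <- !grepl("Annotations", labels, fixed = TRUE)
  data <- vector("list", ns)
  for (i in which(keep)) data[[i]] <- numeric(n_records * spr[i])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      if (keep[i]) {
        data[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- dig
      }
    }
  }
  labels <- trimws(sub("^EEG ", "", labels))
  rates <- spr[keep] / record_dur
  if (length(unique(rates)) != 1L) {
    abort_config("EDF signals have mixed sampling rates: %s",
                 paste(unique(rates), collapse = ", "))
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  mat <- do.call(rbind, lapply(which(keep), function(i) {
    data[[i]] * scale[i] + phys_min[i] - dig_min[i] * scale[i]
  }))
  list(data = mat, fs = rates[1], labels = labels[keep])
}

#' Write a recording as 16-bit EDF
#'
#' One-second data records; trailing samples that do not fill a record are
#' dropped (EDF stores whole records only). Physical units are microvolts.
#'
#' @param rec An `eeg_recording` with integer sampling rate.
#' @param path Output path.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) abort_config("EDF writer needs an integer sampling rate")
  fs <- as.integer(round(fs))
  n_records <- floor(ncol(rec$data) / fs)
  if (n_records < 1L) abort_data("recording shorter than one EDF record (1 s)")
  data <- rec$data[, seq_len(n_records * fs), drop = FALSE]
  ns <- nrow(data)
  amax <- max(1, ceiling(max(abs(data))))
  dig_min <- -32768L; dig_max <- 32767L
  phys_min <- -amax; phys_max <- amax
  dig <- round((data - phys_min) / (phys_max - phys_min) * (dig_max - dig_min) + dig_min)
  storage.mode(dig) <- "integer"

  pad <- function(x, w) {
    s <- as.character(x)
    if (nchar(s) > w) abort_config("EDF header field too wide: '%s'", s)
    formatC(s, width = -w)  # left-justified, space padded
  }
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, eos = NULL)
  put(pad("0", 8L))
  put(pad(rec$subject_id, 80L))
  put(pad("eegchansel", 80L))
  put(pad("01.01.00", 8L)); put(pad("00.00.00", 8L))
  put(pad(256L * (ns + 1L), 8L))
  put(pad("", 44L))
  put(pad(n_records, 8L)); put(pad(1L, 8L)); put(pad(ns, 4L))
  fields <- function(vals, w) for (v in vals) put(pad(v, w))
  fields(unclass(rec$montage), 16L)
  fields(rep("AgAgCl electrode", ns), 80L)
  fields(rep("uV", ns), 8L)
  fields(rep(phys_min, ns), 8L); fields(rep(phys_max, ns), 8L)
  fields(rep(dig_min, ns), 8L); fields(rep(dig_max, ns), 8L)
  fields(rep("", ns), 80L)
  fields(rep(fs, ns), 8L)
  fields(rep("", ns), 32L)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      writeBin(dig[i, ((r - 1L) * fs + 1L):(r * fs)], con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}
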