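#' Write a recording to a delimited matrix with an annotation sidecar
#'
#' The signal is stored as a tab-separated samples x channels matrix with a
#' small commented header (`# fs`, `# channels`). Seizure annotations go to a
#' plain-text sidecar (`<path>.annotations.tsv`), one `start_s<TAB>end_s`
#' interval per line, mirroring the role of the metadata files that accompany
#' public scalp EEG datasets.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path for the signal matrix.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  writeLines(c(sprintf("# fs\t%.10g", rec$fs),
               paste0("# channels\t", paste(rec$channel_names, collapse = "\t"))),
             con)
  close(con)
  data.table::fwrite(data.table::as.data.table(t(rec$data)), path,
                     sep = "\t", col.names = FALSE, append = TRUE)
  ann <- annotation_path(path)
  if (nrow(rec$seizures) > 0) {
    utils::write.table(rec$seizures, ann, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    file.create(ann)
  }
  invisible(path)
}

annotation_path <- function(path) paste0(path, ".annotations.tsv")

#' Read a recording written by [write_recording()]
#'
#' @param path Path to the signal matrix file.
#' @return An [eeg_recording()]. If the annotation sidecar is missing, the
#'   seizure list is empty and a warning is raised.
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 2)
  if (length(hdr) < 2 || !startsWith(hdr[1], "# fs") ||
      !startsWith(hdr[2], "# channels")) {
    stop("malformed recording header at line 1-2 of ", path)
  }
  fs <- as.numeric(strsplit(hdr[1], "\t")[[1]][2])
  channels <- strsplit(hdr[2], "\t")[[1]][-1]
  if (is.na(fs) || length(channels) == 0) {
    stop("malformed recording header at line 1-2 of ", path)
  }
  mat <- data.table::fread(path, sep = "\t", skip = 2, header = FALSE)
  if (ncol(mat) != length(channels)) {
    stop("recording body has ", ncol(mat), " columns but header names ",
         length(channels), " channels (line 3)")
  }
  ann <- annotation_path(path)
  seizures <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (file.exists(ann)) {
    if (file.size(ann) > 0) {
      tab <- utils::read.table(ann, sep = "\t", header = FALSE)
      if (ncol(tab) != 2 || any(is.na(tab))) {
        stop("malformed annotation sidecar: expected start_s<TAB>end_s per line")
      }
      seizures <- stats::setNames(tab, c("start_s", "end_s"))
    }
  } else {
    warning("annotation sidecar not found; assuming no seizures: ", ann)
  }
  eeg_recording(t(as.matrix(mat)), fs, channels, seizures)
}

#' Load an external recording
#'
#' Entry hook for recordings not produced by this package. The native format
#' is the delimited matrix plus annotation sidecar of [write_recording()].
#' EDF is accepted as a format name so callers can wire their own reader, but
#' no EDF parser ships with this package.
#'
#' @param path File path.
#' @param format `"native"` or `"edf"`.
#' @return An [eeg_recording()].
#' @export
load_external_recording <- function(path, format = c("native", "edf")) {
  format <- match.arg(format)
  if (format == "edf") {
    stop("EDF input is a hook only: convert the file to the native ",
         "delimited format (see write_recording) or supply a reader")
  }
  read_recording(path)
}
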