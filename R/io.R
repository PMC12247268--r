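# Recording I/O: a minimal European Data Format (EDF) reader/writer and
# a delimited-text reader/writer. EDF stores 16-bit samples against a
# per-channel physical calibration, so round-trips are exact only up to
# the quantization step. Annotations travel in a sidecar tab-separated
# file (onset_s, duration_s, label) next to the data file; see the
# methods vignette for why no EDF+ annotation channel is written.

annotation_sidecar_path <- function(path) {
  paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".annotations.tsv")
}

write_annotation_sidecar <- function(ann, path) {
  if (is.null(ann) || nrow(ann) == 0L) return(invisible(NULL))
  utils::write.table(ann, annotation_sidecar_path(path), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

read_annotation_sidecar <- function(path) {
  sp <- annotation_sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  ann <- utils::read.table(sp, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  normalize_annotations(ann)
}

pad_ascii <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2, width = 1)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  pad_ascii(s, width)
}

#' Write a recording to disk
#'
#' @param rec an [recording()] object.
#' @param path output file path.
#' @param format `"edf"` (16-bit European Data Format) or `"delimited"`
#'   (comma-separated text, one column per channel, header row of
#'   labels). Annotations, if any, are written to a sidecar
#'   `*.annotations.tsv` file.
#' @return `path`, invisibly.
#' @details EDF quantizes each channel to 16 bits over its observed
#'   physical range; reading the file back reproduces samples within
#'   half a quantization step. EDF requires an integer sampling rate.
#' @export
write_recording <- function(rec, path, format = c("edf", "delimited")) {
  if (!inherits(rec, "svdc_recording")) stop("'rec' must be an svdc_recording")
  if (length(format) == 1L && !format %in% c("edf", "delimited"))
    stop("unsupported format: '", format, "' (use 'edf' or 'delimited')")
  format <- match.arg(format)
  if (format == "edf") write_edf_file(rec, path) else {
    df <- as.data.frame(rec$samples)
    names(df) <- rec$labels
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  write_annotation_sidecar(rec$annotations, path)
  invisible(path)
}

write_edf_file <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate, got fs = ", fs)
  fs <- as.integer(round(fs))
  ns <- ncol(rec$samples)
  n <- nrow(rec$samples)
  n_rec <- n %/% fs
  if (n_rec * fs != n) {
    warning("recording length is not a whole number of 1-s EDF records; ",
            "truncating ", n - n_rec * fs, " trailing sample(s)")
    if (n_rec == 0L) stop("recording shorter than one EDF record (1 s)")
  }
  # physical range per channel, padded so constants are representable
  pmin_ <- apply(rec$samples, 2, min)
  pmax_ <- apply(rec$samples, 2, max)
  span <- pmax_ - pmin_
  pad <- ifelse(span <= 0, pmax(1, abs(pmax_)) * 0.01, span * 0.005)
  pmin_ <- pmin_ - pad
  pmax_ <- pmax_ + pad
  dmin <- -32768
  dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(pad_ascii("0", 8))
  wr(pad_ascii("X X X X", 80))
  wr(pad_ascii("Startdate X X X X", 80))
  wr(pad_ascii("01.01.00", 8))
  wr(pad_ascii("00.00.00", 8))
  wr(pad_ascii(as.character(256L + 256L * ns), 8))
  wr(pad_ascii("", 44))
  wr(pad_ascii(as.character(n_rec), 8))
  wr(pad_ascii("1", 8))
  wr(pad_ascii(as.character(ns), 4))
  wr(paste0(vapply(rec$labels, pad_ascii, "", width = 16), collapse = ""))
  wr(strrep(" ", 80 * ns))                    # transducer
  wr(paste0(rep(pad_ascii("uV", 8), ns), collapse = ""))
  wr(paste0(vapply(pmin_, edf_num, "", width = 8), collapse = ""))
  wr(paste0(vapply(pmax_, edf_num, "", width = 8), collapse = ""))
  wr(paste0(rep(pad_ascii(as.character(dmin), 8), ns), collapse = ""))
  wr(paste0(rep(pad_ascii(as.character(dmax), 8), ns), collapse = ""))
  wr(strrep(" ", 80 * ns))                    # prefiltering
  wr(paste0(rep(pad_ascii(as.character(fs), 8), ns), collapse = ""))
  wr(strrep(" ", 32 * ns))                    # reserved

  # header numbers round-trip through their 8-char ASCII fields, so use
  # the parsed values for the digital scaling
  pmin_h <- as.numeric(vapply(pmin_, edf_num, "", width = 8))
  pmax_h <- as.numeric(vapply(pmax_, edf_num, "", width = 8))
  scale <- (dmax - dmin) / (pmax_h - pmin_h)
  for (r in seq_len(n_rec)) {
    idx <- seq.int((r - 1L) * fs + 1L, r * fs)
    for (j in seq_len(ns)) {
      dig <- round((rec$samples[idx, j] - pmin_h[j]) * scale[j]) + dmin
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a European Data Format (EDF) recording
#'
#' Plain EDF with one sampling rate across channels; physical units of
#' uV, mV or V are converted to uV. If a sidecar `*.annotations.tsv`
#' exists next to the file it is loaded as annotations.
#'
#' @param path path to an EDF file.
#' @return an [recording()] object (samples in uV).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not a valid EDF file (truncated header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) {
    raw <- readBin(con, "raw", nchars)
    trimws(rawToChar(raw))
  }
  rd(8)                     # version
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || is.na(rec_dur) ||
      is.na(header_bytes) || header_bytes != 256L + 256L * ns)
    stop("not a valid EDF file (malformed header): ", path)
  rd_fields <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rd_fields(16)
  rd_fields(80)
  dims <- rd_fields(8)
  pmin_ <- as.numeric(rd_fields(8))
  pmax_ <- as.numeric(rd_fields(8))
  dmin <- as.numeric(rd_fields(8))
  dmax <- as.numeric(rd_fields(8))
  rd_fields(80)
  spr <- as.integer(rd_fields(8))
  rd_fields(32)
  if (anyDuplicated(labels))
    stop("EDF contains duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (length(unique(spr)) != 1L)
    stop("unsupported EDF: channels have mixed per-record sample counts (",
         paste(unique(spr), collapse = ", "), ")")
  fs <- spr[1] / rec_dur
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  unit_mult <- vapply(dims, function(d) {
    switch(tolower(d), "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6, 1)
  }, numeric(1))
  n <- n_rec * spr[1]
  samples <- matrix(0, nrow = n, ncol = ns)
  for (r in seq_len(n_rec)) {
    idx <- seq.int((r - 1L) * spr[1] + 1L, r * spr[1])
    for (j in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[1], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[1]) stop("EDF data truncated at record ", r)
      samples[idx, j] <- (dig - dmin[j]) * scale[j] + pmin_[j]
    }
  }
  samples <- sweep(samples, 2, unit_mult, `*`)
  recording(samples, fs = fs, labels = labels,
            annotations = read_annotation_sidecar(path))
}

#' Read a delimited-text recording
#'
#' Comma-separated numeric table, one column per channel, optional
#' single header row of channel labels.
#'
#' @param path path to the text file.
#' @param fs sampling rate in Hz (required; delimited files carry no
#'   rate).
#' @param labels optional channel labels; when absent, a header row is
#'   used if present.
#' @return an [recording()] object.
#' @export
read_delimited <- function(path, fs, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop("ragged rows: row ", which(widths != widths[1])[1],
         " has ", widths[widths != widths[1]][1], " fields, expected ",
         widths[1])
  first <- suppressWarnings(as.numeric(fields[[1]]))
  has_header <- anyNA(first)
  header <- if (has_header) trimws(fields[[1]]) else NULL
  data_rows <- fields[if (has_header) -1L else TRUE]
  if (!length(data_rows)) stop("no data rows in ", path)
  m <- matrix(suppressWarnings(as.numeric(unlist(data_rows))),
              ncol = widths[1], byrow = TRUE)
  if (!all(is.finite(m))) {
    bad <- which(!apply(is.finite(m), 1, all))[1]
    stop("non-numeric or non-finite value at data row ", bad)
  }
  if (is.null(labels)) labels <- header
  recording(m, fs = fs, labels = labels,
            annotations = read_annotation_sidecar(path))
}
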