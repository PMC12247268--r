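#' Multichannel iEEG recording
#'
#' Container for a multichannel intracranial EEG recording. Samples are
#' stored as a numeric matrix with one column per channel, in microvolts.
#' Time is measured in seconds from the start of the recording; sample
#' `i` (1-based) covers the half-open interval `[(i-1)/fs, i/fs)`.
#'
#' @param samples numeric matrix (or vector for a single channel), one
#'   column per channel, values in microvolts. All values must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param labels character vector of unique channel labels, one per
#'   column. SEEG convention: electrode letter(s) followed by a contact
#'   number, e.g. `"A3"`, `"E10"`.
#' @param start_time offset of the first sample in seconds (default 0).
#' @param annotations data frame with columns `onset_s`, `duration_s`,
#'   `label`, or `NULL` for none.
#'
#' @return an object of class `svdc_recording`: a list with elements
#'   `samples`, `fs`, `labels`, `start_time`, `annotations`.
#' @export
recording <- function(samples, fs, labels = NULL, start_time = 0,
                      annotations = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number (Hz)")
  if (is.null(labels)) {
    labels <- colnames(samples)
    if (is.null(labels)) labels <- paste0("CH", seq_len(ncol(samples)))
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(samples))
    stop("number of labels (", length(labels), ") does not match number of channels (",
         ncol(samples), ")")
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (!all(is.finite(samples)))
    stop("sample values must be finite (no NA/NaN/Inf)")
  colnames(samples) <- labels
  annotations <- normalize_annotations(annotations)
  structure(
    list(samples = samples, fs = fs, labels = labels,
         start_time = start_time, annotations = annotations),
    class = "svdc_recording")
}

normalize_annotations <- function(ann) {
  if (is.null(ann) || (is.data.frame(ann) && nrow(ann) == 0L))
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  ann <- as.data.frame(ann)
  need <- c("onset_s", "duration_s", "label")
  if (!all(need %in% names(ann)))
    stop("annotations need columns onset_s, duration_s, label")
  data.frame(onset_s = as.numeric(ann$onset_s),
             duration_s = as.numeric(ann$duration_s),
             label = as.character(ann$label), stringsAsFactors = FALSE)
}

#' @export
print.svdc_recording <- function(x, ...) {
  cat(sprintf("<svdc_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  cat("  channels:", paste(utils::head(x$labels, 12), collapse = " "),
      if (length(x$labels) > 12) "..." else "", "\n")
  if (nrow(x$annotations))
    cat(sprintf("  %d annotation(s), first: %s @ %.1f s\n",
                nrow(x$annotations), x$annotations$label[1],
                x$annotations$onset_s[1]))
  invisible(x)
}

#' Number of channels and duration of a recording
#' @param rec an `svdc_recording`.
#' @return `n_channels`: integer; `rec_duration`: seconds.
#' @export
n_channels <- function(rec) ncol(rec$samples)

#' @rdname n_channels
#' @export
rec_duration <- function(rec) nrow(rec$samples) / rec$fs

#' Map a half-open time window to sample indices
#'
#' Sample `i` covers `[(i-1)/fs, i/fs)`; the window `[t0, t1)` therefore
#' selects samples whose left edge falls inside it.
#'
#' @param fs sampling rate in Hz.
#' @param t0,t1 window bounds in seconds, `t0 < t1`.
#' @param n total number of samples available (indices are clipped to
#'   `[1, n]`).
#' @return integer vector of sample indices.
#' @keywords internal
sample_range <- function(fs, t0, t1, n) {
  if (!is.finite(t0) || !is.finite(t1) || t1 <= t0)
    stop("invalid window: need t0 < t1")
  first <- ceiling(t0 * fs - 1e-9) + 1L
  last <- ceiling(t1 * fs - 1e-9)
  first <- max(1L, as.integer(first))
  last <- min(as.integer(last), as.integer(n))
  if (last < first) stop("window [", t0, ", ", t1, ") contains no samples")
  seq.int(first, last)
}

#' Parse and format SEEG lead labels
#'
#' A lead label is one or more electrode letters followed by a positive
#' contact number, e.g. `"A3"` is contact 3 on electrode A.
#'
#' @param text a character vector of labels such as `"A3"` or `"E10"`.
#' @return `parse_lead_label`: a data frame with columns `electrode`
#'   (character) and `contact` (integer); `format_lead_label` the
#'   inverse, a character vector.
#' @examples
#' parse_lead_label("A3")
#' format_lead_label("E", 10)
#' @export
parse_lead_label <- function(text) {
  text <- as.character(text)
  ok <- grepl("^[A-Za-z]+[0-9]+$", text)
  if (!all(ok))
    stop("cannot parse lead label(s): ",
         paste(text[!ok], collapse = ", "),
         " (expected letters followed by digits, e.g. 'A3')")
  electrode <- sub("[0-9]+$", "", text)
  contact <- as.integer(sub("^[A-Za-z]+", "", text))
  if (any(contact < 1L)) stop("contact numbers must be >= 1")
  data.frame(electrode = electrode, contact = contact,
             stringsAsFactors = FALSE)
}

#' @rdname parse_lead_label
#' @param electrode electrode letter string(s).
#' @param contact positive integer contact number(s).
#' @export
format_lead_label <- function(electrode, contact) {
  contact <- as.integer(contact)
  if (any(contact < 1L)) stop("contact numbers must be >= 1")
  paste0(electrode, contact)
}

#' Canonical spatial order of leads
#'
#' Fixed ordering used for staged seizure propagation: contact index
#' first, then electrode letter.
#'
#' @param labels character vector of lead labels.
#' @return integer permutation ordering `labels`.
#' @export
lead_order <- function(labels) {
  ll <- parse_lead_label(labels)
  order(ll$contact, ll$electrode)
}
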