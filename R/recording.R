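#' Construct a continuous multichannel EEG recording
#'
#' The central signal container: a channels x time matrix of microvolt
#' values with a sampling rate and channel labels. Time coordinates are
#' seconds from recording start; intervals are half-open `[start, end)`.
#'
#' @param samples numeric matrix, channels x samples (microvolts).
#' @param sampling_rate sampling frequency in Hz (positive; 256 for standard
#'   scalp EEG in the 10-20 system).
#' @param channel_labels character vector, one label per row of `samples`.
#' @param start_time recording start offset in seconds (default 0).
#' @return An object of class `eeg_recording` with fields `samples`,
#'   `sampling_rate`, `channel_labels`, `start_time`, `duration`.
#' @export
recording <- function(samples, sampling_rate = 256,
                      channel_labels = NULL, start_time = 0) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  dimnames(samples) <- NULL
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_labels) != nrow(samples)) {
    stop("one channel label per channel is required")
  }
  rec <- structure(list(
    samples = samples,
    sampling_rate = sampling_rate,
    channel_labels = as.character(channel_labels),
    start_time = start_time,
    duration = ncol(samples) / sampling_rate
  ), class = "eeg_recording")
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels, %.1f s @ %g Hz\n",
              nrow(x$samples), x$duration, x$sampling_rate))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (length(x$channel_labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' Seizure annotations
#'
#' Build a sorted annotation table. Onset/offset are seconds from recording
#' start. `lead` marks seizures separated from the previous one by at least
#' the independence gap (4.5 h by default), the unit of the inclusion rule.
#'
#' @param onset,offset numeric vectors, seconds.
#' @param classification,vigilance,pattern character tags (recycled);
#'   unknown values allowed.
#' @param lead logical; if `NULL`, computed from `independence_gap`.
#' @param independence_gap hours between consecutive seizures for a seizure
#'   to count as lead (default 4.5).
#' @return data.frame of class `seizure_annotations`, sorted by onset.
#' @export
seizure_annotations <- function(onset, offset,
                                classification = "unknown",
                                vigilance = "unknown",
                                pattern = "unknown",
                                lead = NULL,
                                independence_gap = 4.5) {
  if (length(onset) != length(offset)) stop("onset/offset length mismatch")
  if (any(offset <= onset)) stop("offset must exceed onset")
  o <- order(onset)
  ann <- data.frame(
    onset = onset[o], offset = offset[o],
    classification = rep_len(as.character(classification), length(onset))[o],
    vigilance = rep_len(as.character(vigilance), length(onset))[o],
    pattern = rep_len(as.character(pattern), length(onset))[o],
    stringsAsFactors = FALSE
  )
  if (is.null(lead)) {
    gap_s <- independence_gap * 3600
    prev_end <- c(-Inf, ann$offset[-nrow(ann)])
    ann$lead <- (ann$onset - prev_end) >= gap_s
    if (nrow(ann) > 0) ann$lead[1] <- TRUE
  } else {
    ann$lead <- rep_len(as.logical(lead), nrow(ann))[o]
  }
  class(ann) <- c("seizure_annotations", "data.frame")
  ann
}

#' Read an EEG recording from disk
#'
#' Supports 16-bit EDF (continuous, as written by [write_recording()]) and a
#' toy CSV layout (header of channel labels, one column per channel, one row
#' per sample). Seizure annotations are supplied in a JSON sidecar
#' (`<path>.annotations.json` by default) as an array of objects with fields
#' `onset_s`, `offset_s`, `classification`, `vigilance`, `pattern`, `lead`;
#' the sidecar is mandatory when `annotations = TRUE`.
#'
#' @param path file path.
#' @param format "edf" or "csv".
#' @param sampling_rate Hz, used for CSV input (EDF carries its own rate).
#' @param annotations load the JSON sidecar (default TRUE).
#' @param annotation_path sidecar path override.
#' @return list with elements `recording` ([recording()]) and `annotations`
#'   ([seizure_annotations()] or NULL).
#' @export
read_recording <- function(path, format = c("edf", "csv"),
                           sampling_rate = 256, annotations = TRUE,
                           annotation_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- switch(format,
    edf = read_edf(path),
    csv = {
      tab <- utils::read.csv(path, check.names = FALSE)
      if (ncol(tab) < 1) stop("CSV parse error in ", path, ": no columns")
      recording(t(as.matrix(tab)), sampling_rate = sampling_rate,
                channel_labels = colnames(tab))
    }
  )
  ann <- NULL
  if (annotations) {
    ap <- annotation_path
    if (is.null(ap)) ap <- paste0(path, ".annotations.json")
    if (!file.exists(ap)) {
      stop("missing annotation sidecar: ", ap,
           " (annotations are mandatory for pipeline use;",
           " pass annotations = FALSE for signal-only loading)")
    }
    ann <- read_annotations(ap)
  }
  list(recording = rec, annotations = ann)
}

#' Write a recording (EDF or CSV) with optional annotation sidecar
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @param format "edf" or "csv".
#' @param annotations optional `seizure_annotations` to write as JSON sidecar
#'   at `<path>.annotations.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("edf", "csv"),
                            annotations = NULL) {
  format <- match.arg(format)
  if (format == "edf") {
    write_edf(rec, path)
  } else {
    tab <- as.data.frame(t(rec$samples))
    colnames(tab) <- rec$channel_labels
    utils::write.csv(tab, path, row.names = FALSE)
  }
  if (!is.null(annotations)) {
    write_annotations(annotations, paste0(path, ".annotations.json"))
  }
  invisible(path)
}

#' Read / write the JSON annotation sidecar
#'
#' @param path sidecar path.
#' @return [seizure_annotations()] table.
#' @export
read_annotations <- function(path) {
  arr <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(arr) == 0 || NROW(arr) == 0) {
    return(seizure_annotations(numeric(0), numeric(0)))
  }
  seizure_annotations(
    onset = arr$onset_s, offset = arr$offset_s,
    classification = arr$classification %||% "unknown",
    vigilance = arr$vigilance %||% "unknown",
    pattern = arr$pattern %||% "unknown",
    lead = arr$lead %||% NULL
  )
}

#' @rdname read_annotations
#' @param ann a `seizure_annotations` table.
#' @export
write_annotations <- function(ann, path) {
  out <- data.frame(onset_s = ann$onset, offset_s = ann$offset,
                    classification = ann$classification,
                    vigilance = ann$vigilance, pattern = ann$pattern,
                    lead = ann$lead)
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal 16-bit EDF (continuous, 1-second data records) ----------------

edf_pad <- function(x, n) {
  x <- substr(as.character(x), 1, n)
  formatC(x, width = n, flag = "-")
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$samples)
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  spr <- as.integer(fs)                       # samples per 1-s record
  n_rec <- floor(ncol(rec$samples) / spr)
  phys_min <- -3276.8; phys_max <- 3276.7     # 0.1 uV quantisation
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + ns * 256, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) {
    writeChar(paste(vapply(vals, edf_pad, "", n = width), collapse = ""),
              con, eos = NULL)
  }
  fld(rec$channel_labels, 16)
  fld(rep("", ns), 80)                        # transducer
  fld(rep("uV", ns), 8)                       # physical dimension
  fld(rep(phys_min, ns), 8)
  fld(rep(phys_max, ns), 8)
  fld(rep(-32768L, ns), 8)
  fld(rep(32767L, ns), 8)
  fld(rep("", ns), 80)                        # prefiltering
  fld(rep(spr, ns), 8)
  fld(rep("", ns), 32)                        # reserved
  scale <- (32767 - (-32768)) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((rec$samples[ch, idx] - phys_min) * scale) - 32768
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  ver <- rd(8)
  if (!grepl("^0", ver)) stop("EDF parse error in ", path, ": bad version field at byte 0")
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("EDF parse error in ", path, ": bad signal count at byte 252")
  fldv <- function(width) {
    vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  }
  labels <- fldv(16)
  fldv(80); fldv(8)
  phys_min <- as.numeric(fldv(8)); phys_max <- as.numeric(fldv(8))
  dig_min <- as.numeric(fldv(8)); dig_max <- as.numeric(fldv(8))
  fldv(80)
  spr <- as.integer(fldv(8))
  fldv(32)
  if (length(unique(spr)) != 1) stop("EDF reader supports a single common sampling rate")
  seek(con, hdr_bytes)
  out <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      out[ch, idx] <- phys_min[ch] + (dig - dig_min[ch]) * gain[ch]
    }
  }
  recording(out, sampling_rate = spr[1] / rec_dur, channel_labels = labels)
}

# ---- filtering and segmentation --------------------------------------------

#' Zero-phase band-pass and notch filtering
#'
#' A configurable stand-in for heavier artefact-removal front ends: 4th-order
#' Butterworth band-pass applied forward-backward (zero phase) plus 3rd-order
#' Butterworth band-stop notches (+-1.5 Hz around each notch frequency).
#' Notch frequencies at or above Nyquist are silently dropped.
#'
#' @param rec an `eeg_recording`.
#' @param band numeric length 2, pass band in Hz (default `c(0.5, 100)`).
#' @param notch numeric vector of mains frequencies to remove
#'   (default `c(50, 100)`).
#' @return a filtered `eeg_recording` of identical shape; the applied
#'   parameters are attached as attribute `"filter_log"`.
#' @export
basic_denoise <- function(rec, band = c(0.5, 100), notch = c(50, 100)) {
  nyq <- rec$sampling_rate / 2
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq)) {
    stop("pass band must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  }
  bp <- signal::butter(4, band / nyq, type = "pass")
  notch <- notch[notch < nyq - 1]
  stops <- lapply(notch, function(f) {
    signal::butter(3, c(f - 1.5, f + 1.5) / nyq, type = "stop")
  })
  out <- rec$samples
  for (ch in seq_len(nrow(out))) {
    x <- signal::filtfilt(bp, out[ch, ])
    for (st in stops) x <- signal::filtfilt(st, x)
    out[ch, ] <- x
  }
  res <- recording(out, rec$sampling_rate, rec$channel_labels, rec$start_time)
  attr(res, "filter_log") <- list(band = band, notch = notch, order = c(4, 3))
  res
}

#' Segment a recording into non-overlapping epochs
#'
#' Cuts the recording into consecutive `window_length`-second epochs
#' (default 5 s). Epoch `i` covers `[i*w, (i+1)*w)` seconds; a trailing
#' partial window is discarded.
#'
#' @param rec an `eeg_recording`.
#' @param window_length epoch length in seconds (default 5); must give a
#'   whole number of samples.
#' @return object of class `epoch_array`: list with `epochs` (epoch x channel
#'   x sample array), `epoch_start_times` (s), `window_length`,
#'   `sampling_rate`, `channel_labels`, `valid_mask`.
#' @export
segment_epochs <- function(rec, window_length = 5) {
  spw <- window_length * rec$sampling_rate
  if (abs(spw - round(spw)) > 1e-9) {
    stop("window_length x sampling_rate must be a whole number of samples")
  }
  spw <- as.integer(round(spw))
  n_ep <- floor(ncol(rec$samples) / spw)
  if (n_ep == 0) {
    message("recording shorter than one window; empty epoch array")
  }
  ep <- array(0, dim = c(n_ep, nrow(rec$samples), spw))
  for (i in seq_len(n_ep)) {
    ep[i, , ] <- rec$samples[, ((i - 1) * spw + 1):(i * spw), drop = FALSE]
  }
  structure(list(
    epochs = ep,
    epoch_start_times = rec$start_time + (seq_len(n_ep) - 1) * window_length,
    window_length = window_length,
    sampling_rate = rec$sampling_rate,
    channel_labels = rec$channel_labels,
    valid_mask = rep(TRUE, n_ep)
  ), class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  cat(sprintf("<epoch_array> %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$window_length, x$sampling_rate))
  invisible(x)
}
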