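# Minimal EDF/EDF+ reader and writer (16-bit, one optional annotation
# channel).  Covers what polysomnography-style corpora actually use: a
# 256-byte fixed header, field-major per-signal headers, int16
# little-endian data records, and EDF+ time-stamped annotation lists
# (TALs) for cue events.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- formatC(x, width = -1, format = "fg")
  if (nchar(s) > width) s <- substr(formatC(x, digits = width - 2, format = "g"),
                                    1, width)
  edf_pad(s, width)
}

#' Write signals and annotations to an EDF+ file
#'
#' Signals are scaled per channel to the full 16-bit digital range; the
#' quantization step is `(max - min) / 65535` of each channel's physical
#' range.  Annotations are stored in an "EDF Annotations" signal as
#' time-stamped annotation lists.
#'
#' @param signals Numeric matrix `n_channels x n_samples`, physical units
#'   (microvolts), with channel labels as row names.
#' @param fs Sampling rate in Hz (one data record per second is written, so
#'   `fs` must be a positive integer).
#' @param path Output file path.
#' @param annotations Optional tibble/data.frame with `onset` (s), `duration`
#'   (s) and `code` (character) columns.
#' @param patient_id,recording_id Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path, annotations = NULL,
                      patient_id = "X", recording_id = "X") {
  stopifnot(is.matrix(signals), fs == as.integer(fs), fs > 0)
  labels <- rownames(signals)
  if (is.null(labels)) labels <- paste0("CH", seq_len(nrow(signals)))
  ns_sig <- nrow(signals)
  n_samp <- ncol(signals)
  n_rec <- ceiling(n_samp / fs)
  if (n_rec < 1L) n_rec <- 1L
  pad <- n_rec * fs - n_samp
  if (pad > 0) signals <- cbind(signals, matrix(0, ns_sig, pad))

  has_ann <- !is.null(annotations)
  if (has_ann) {
    annotations <- as.data.frame(annotations)
    stopifnot(all(c("onset", "duration", "code") %in% names(annotations)))
    if (nrow(annotations) > 1 && is.unsorted(annotations$onset)) {
      stop("annotation onsets must be non-decreasing", call. = FALSE)
    }
    bad <- annotations$onset + annotations$duration > n_rec + 1e-9
    if (any(bad)) stop("annotation extends past the end of the record",
                       call. = FALSE)
  }

  # physical range per channel, padded so constant channels stay writable
  pmin <- apply(signals, 1, min)
  pmax <- apply(signals, 1, max)
  flat <- pmax - pmin < 1e-6
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # pad the range slightly, then digitize against the 8-character ASCII form
  # actually written, so the reader's reconstruction matches to the
  # quantization step and no sample is clamped by header rounding
  pad_r <- 0.001 * (pmax - pmin)
  pmin <- as.numeric(vapply(pmin - pad_r, edf_num, character(1), width = 8))
  pmax <- as.numeric(vapply(pmax + pad_r, edf_num, character(1), width = 8))
  dmin <- -32768; dmax <- 32767

  # annotation TALs: every record gets a NUL-terminated timestamp TAL, and
  # record 0 additionally carries one NUL-terminated TAL per event
  ann_bytes <- NULL
  if (has_ann) {
    recs <- lapply(seq_len(n_rec) - 1L, function(r) {
      out <- c(charToRaw(sprintf("+%d\x14\x14", r)), as.raw(0))
      if (r == 0L && nrow(annotations) > 0) {
        for (k in seq_len(nrow(annotations))) {
          ev <- sprintf("+%s\x15%s\x14%s\x14",
                        format(annotations$onset[k], trim = TRUE,
                               scientific = FALSE),
                        format(annotations$duration[k], trim = TRUE,
                               scientific = FALSE),
                        annotations$code[k])
          out <- c(out, charToRaw(ev), as.raw(0))
        }
      }
      out
    })
    ann_len <- max(lengths(recs))
    ann_len <- ann_len + ann_len %% 2L                  # int16 alignment
    ann_bytes <- vapply(recs, function(x) c(x, raw(ann_len - length(x))),
                        raw(ann_len))
  }

  ns_total <- ns_sig + as.integer(has_ann)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x) writeChar(x, con, nchars = nchar(x, type = "bytes"),
                              eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad(patient_id, 80))
  wr(edf_pad(recording_id, 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_num(256 * (ns_total + 1), 8))
  wr(edf_pad(if (has_ann) "EDF+C" else "", 44))
  wr(edf_num(n_rec, 8))
  wr(edf_num(1, 8))
  wr(edf_num(ns_total, 4))

  all_labels <- c(labels, if (has_ann) "EDF Annotations")
  for (l in all_labels) wr(edf_pad(l, 16))
  for (i in seq_len(ns_total)) wr(edf_pad("", 80))                # transducer
  for (i in seq_len(ns_total)) wr(edf_pad(if (i <= ns_sig) "uV" else "", 8))
  wr(paste0(vapply(pmin, edf_num, character(1), width = 8), collapse = ""))
  if (has_ann) wr(edf_num(-1, 8))
  wr(paste0(vapply(pmax, edf_num, character(1), width = 8), collapse = ""))
  if (has_ann) wr(edf_num(1, 8))
  for (i in seq_len(ns_total)) wr(edf_num(dmin, 8))
  for (i in seq_len(ns_total)) wr(edf_num(dmax, 8))
  for (i in seq_len(ns_total)) wr(edf_pad("", 80))                # prefilter
  spr <- rep(fs, ns_sig)
  if (has_ann) spr <- c(spr, nrow(ann_bytes) / 2)
  for (v in spr) wr(edf_num(v, 8))
  for (i in seq_len(ns_total)) wr(edf_pad("", 32))

  # digital conversion: dig = (phys - pmin) / (pmax - pmin) * range + dmin
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns_sig)) {
      dig <- round((signals[i, cols] - pmin[i]) * scale[i] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
    if (has_ann) writeBin(ann_bytes[, r], con)
  }
  invisible(path)
}

#' Read an EDF or EDF+ file
#'
#' Returns the physical-unit signals, channel labels, sampling rates and any
#' EDF+ annotations.  Only ordinary (non-discontinuous) files with a common
#' record layout are supported, which covers the motor-imagery corpus this
#' package targets.
#'
#' @param path Path to an `.edf` file.
#' @return List with `signals` (`n_channels x n_samples` matrix, annotation
#'   channel excluded), `labels`, `fs` (per-channel sampling rate vector),
#'   `n_records`, `record_duration`, and `annotations` (tibble with `onset`,
#'   `duration`, `code`).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) {
    out <- readChar(con, nc, useBytes = TRUE)
    if (length(out) == 0) stop("truncated EDF header in ", path, call. = FALSE)
    out
  }
  rd(8)                                          # version
  rd(80); rd(80); rd(8); rd(8)                   # ids, date, time
  rd(8)                                          # header bytes
  rd(44)                                         # reserved / EDF+C
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header in ", path, call. = FALSE)

  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  for (i in seq_len(ns)) rd(80)                  # transducer
  for (i in seq_len(ns)) rd(8)                   # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)                  # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)                  # reserved

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  sig_data <- lapply(sig_idx, function(i) numeric(n_rec * spr[i]))
  ann_raw <- raw(0)

  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", spr[i] * 2L))
      } else {
        v <- readBin(con, "integer", spr[i], size = 2, endian = "little")
        if (length(v) < spr[i]) {
          stop("truncated EDF data record in ", path, call. = FALSE)
        }
        j <- match(i, sig_idx)
        sig_data[[j]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- v
      }
    }
  }

  signals <- matrix(0, length(sig_idx), if (length(sig_idx)) n_rec * spr[sig_idx[1]] else 0L)
  for (j in seq_along(sig_idx)) {
    i <- sig_idx[j]
    scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    signals[j, ] <- (sig_data[[j]] - dmin[i]) * scale + pmin[i]
  }
  rownames(signals) <- labels[sig_idx]

  list(signals = signals, labels = labels[sig_idx],
       fs = spr[sig_idx] / rec_dur, n_records = n_rec,
       record_duration = rec_dur,
       annotations = parse_tals(ann_raw))
}

# Parse EDF+ time-stamped annotation lists.  TALs are separated by NUL;
# within a TAL, "\x14" separates onset[\x15duration] from the texts.  The
# per-record bare timestamp TALs (no text) are dropped.
parse_tals <- function(ann_raw) {
  empty <- tibble::tibble(onset = numeric(), duration = numeric(),
                          code = character())
  if (length(ann_raw) == 0) return(empty)
  zeros <- which(ann_raw == as.raw(0))
  starts <- c(1L, zeros + 1L)
  ends <- c(zeros - 1L, length(ann_raw))
  tals <- unlist(Map(function(s, e) {
    if (s <= e) rawToChar(ann_raw[s:e]) else ""
  }, starts, ends), use.names = FALSE)
  rows <- list()
  for (tal in tals) {
    if (tal == "") next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2 || all(parts[-1] == "")) next   # bare timestamp
    od <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- as.numeric(od[1])
    duration <- if (length(od) > 1) as.numeric(od[2]) else 0
    for (code in parts[-1]) {
      if (code == "") next
      rows[[length(rows) + 1L]] <- tibble::tibble(onset = onset,
                                                  duration = duration,
                                                  code = code)
    }
  }
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)
}
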