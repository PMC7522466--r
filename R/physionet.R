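#' Run-to-task key for the motor-imagery runs
#'
#' In the 14-run session layout of the public motor-imagery corpus, the cue
#' codes T1/T2 mean different tasks depending on the run: in imagery runs 4,
#' 8 and 12 they cue left/right fist, in runs 6, 10 and 14 both fists/both
#' feet.  T0 is rest everywhere.  (Odd runs hold executed movement and the
#' two baselines; they are not motor imagery and are absent from this table.)
#'
#' @return Tibble with columns `run`, `T1`, `T2` (task names).
#' @export
mi_run_table <- function() {
  tibble::tibble(
    run = c(4L, 8L, 12L, 6L, 10L, 14L),
    T1 = rep(c("left_fist", "both_fists"), each = 3L),
    T2 = rep(c("right_fist", "both_feet"), each = 3L))
}

#' Map a cue annotation code to a motor-imagery task
#'
#' @param run_id Integer run number.
#' @param code Cue code `"T0"`, `"T1"` or `"T2"`.
#' @param run_table Run key, by default [mi_run_table()].
#' @return Task name (see [task_levels()]), or `NA` for the rest code `"T0"`.
#' @examples
#' map_annotation_to_task(4, "T1")   # "left_fist"
#' map_annotation_to_task(6, "T2")   # "both_feet"
#' @export
map_annotation_to_task <- function(run_id, code, run_table = mi_run_table()) {
  stopifnot(length(run_id) == 1L, length(code) == 1L)
  if (code == "T0") return(NA_character_)
  if (!code %in% c("T1", "T2")) {
    stop("unknown cue code: ", code, call. = FALSE)
  }
  row <- which(run_table$run == run_id)
  if (!length(row)) {
    stop("run ", run_id, " is not in the configured motor-imagery run table",
         call. = FALSE)
  }
  run_table[[code]][row]
}

# "Fc3." -> "FC3": strip the corpus' trailing-dot padding, uppercase.
normalize_channel_label <- function(labels) {
  toupper(gsub("\\.+$", "", labels))
}

#' Subjects with known-irregular records in the public corpus
#'
#' A handful of subjects have runs with deviant sampling rates or lengths.
#' They are not excluded by default; pass this set as a blocklist explicitly
#' if matching trial counts matters more than completeness.
#'
#' @return Character vector of subject ids.
#' @export
irregular_subjects <- function() c("S088", "S092", "S100")

#' Read one subject-run recording from an EDF(+) file
#'
#' Reads the signals, normalizes channel labels to canonical upper-case
#' 10-10 names (the corpus pads labels with trailing dots), and parses the
#' cue annotations.  Subject and run are taken from a `S###R##.edf`-style
#' file name unless given explicitly.
#'
#' @param path Path to the EDF file.
#' @param subject_id,run_id Optional overrides for the identity parsed from
#'   the file name.
#' @return An object of class `eeg_recording`: list with `subject_id`,
#'   `run_id`, `signals` (`n_channels x n_samples`, microvolts), `labels`,
#'   `fs`, `annotations` (tibble: onset, duration, code).
#' @export
read_recording <- function(path, subject_id = NULL, run_id = NULL) {
  base <- basename(path)
  m <- regmatches(base, regexec("^(.*)R(\\d+)\\.edf$", base,
                                ignore.case = TRUE))[[1]]
  if (is.null(subject_id)) {
    subject_id <- if (length(m) == 3L) m[2] else tools::file_path_sans_ext(base)
  }
  if (is.null(run_id)) run_id <- if (length(m) == 3L) as.integer(m[3]) else NA_integer_
  edf <- read_edf(path)
  if (length(unique(edf$fs)) > 1L) {
    stop("mixed per-channel sampling rates in ", path, call. = FALSE)
  }
  if (!is.na(run_id) && run_id %in% mi_run_table()$run &&
      nrow(edf$annotations) == 0L) {
    stop("no cue annotations found in task run ", run_id, " (", path, ")",
         call. = FALSE)
  }
  labels <- normalize_channel_label(edf$labels)
  rownames(edf$signals) <- labels
  structure(list(subject_id = subject_id, run_id = run_id,
                 signals = edf$signals, labels = labels,
                 fs = edf$fs[1], annotations = edf$annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording>", x$subject_id, "run", x$run_id, ":",
      nrow(x$signals), "channels x", ncol(x$signals), "samples @", x$fs,
      "Hz;", nrow(x$annotations), "annotations\n")
  invisible(x)
}

#' Cut fixed-length task trials from a recording
#'
#' One trial per imagery cue (codes T1/T2; T0 rest cues are skipped): a
#' half-open window `[window_start, window_start + window_len)` from the cue
#' onset, starting at sample `floor(onset * fs)`.  Trials that would run past
#' the end of the record are dropped with a message.
#'
#' @param rec An `eeg_recording` from [read_recording()].
#' @param window_start_s Window start relative to cue onset, seconds.
#' @param window_len_s Window length, seconds; `fs * window_len_s` must be a
#'   whole number of samples (4 s at 160 Hz gives the canonical 640).
#' @param trial_index_offset Added to the within-recording trial numbering,
#'   for concatenating several runs of one subject.
#' @param run_table Run key, by default [mi_run_table()].
#' @return Trials tibble: `subject_id`, `trial_index`, `task`, `run`,
#'   `onset`, and a `data` list-column of `n_samples x n_channels` matrices.
#' @export
extract_trials <- function(rec, window_start_s = 0, window_len_s = 4,
                           trial_index_offset = 0L,
                           run_table = mi_run_table()) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_want <- rec$fs * window_len_s
  if (abs(n_want - round(n_want)) > 1e-9) {
    stop("window length times sampling rate must be an integer sample count",
         call. = FALSE)
  }
  n_want <- as.integer(round(n_want))
  empty <- tibble::tibble(subject_id = character(), trial_index = integer(),
                          task = factor(character(), levels = task_levels()),
                          run = integer(), onset = numeric(), data = list())
  ann <- rec$annotations
  if (is.null(ann) || nrow(ann) == 0L) return(empty)

  rows <- list()
  dropped <- 0L
  for (k in seq_len(nrow(ann))) {
    task <- map_annotation_to_task(rec$run_id, ann$code[k], run_table)
    if (is.na(task)) next
    start <- floor(ann$onset[k] * rec$fs) + round(window_start_s * rec$fs) + 1L
    end <- start + n_want - 1L
    if (start < 1L || end > ncol(rec$signals)) {
      dropped <- dropped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      subject_id = rec$subject_id,
      trial_index = NA_integer_,
      task = factor(task, levels = task_levels()),
      run = rec$run_id,
      onset = ann$onset[k],
      data = list(t(rec$signals[, start:end, drop = FALSE])))
  }
  if (dropped > 0L) {
    message(sprintf("dropped %d trial(s) truncated by end of record in %s run %s",
                    dropped, rec$subject_id, rec$run_id))
  }
  if (!length(rows)) return(empty)
  out <- dplyr::bind_rows(rows)
  out$trial_index <- seq_len(nrow(out)) + as.integer(trial_index_offset)
  out
}

#' Extract and pool trials from all imagery runs of one subject
#'
#' Reads every `S###R##.edf` imagery-run file found for a subject, extracts
#' trials in run order with consecutive indexing, and optionally caps the
#' trial count per class (the sessions yield 21-24 cues per class; the
#' canonical count is 21, i.e. 84 trials per subject).
#'
#' @param paths EDF file paths for one subject's imagery runs.
#' @param cap_per_class Keep only the first this-many trials per class in
#'   run/onset order (`NULL` keeps all); dropped counts are messaged.
#' @param ... Passed to [extract_trials()].
#' @return Trials tibble.
#' @export
extract_subject_trials <- function(paths, cap_per_class = 21L, ...) {
  trials <- list()
  offset <- 0L
  for (p in paths) {
    rec <- read_recording(p)
    tr <- extract_trials(rec, trial_index_offset = offset, ...)
    offset <- offset + nrow(tr)
    trials[[length(trials) + 1L]] <- tr
  }
  out <- dplyr::bind_rows(trials)
  if (!is.null(cap_per_class) && nrow(out) > 0L) {
    out <- cap_trials_per_class(out, cap_per_class)
  }
  out
}

# Keep the first `cap` trials of each (subject, class) in trial order.
cap_trials_per_class <- function(trials, cap) {
  keep <- trials |>
    dplyr::group_by(.data$subject_id, .data$task) |>
    dplyr::mutate(.rank = dplyr::row_number()) |>
    dplyr::ungroup()
  n_drop <- sum(keep$.rank > cap)
  if (n_drop > 0L) {
    message(sprintf("capping to %d trials per class: dropping %d surplus trial(s)",
                    cap, n_drop))
  }
  out <- keep[keep$.rank <= cap, , drop = FALSE]
  out$.rank <- NULL
  out
}
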