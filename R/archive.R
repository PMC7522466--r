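# Plain-text trial archive: a directory with a JSON descriptor, a manifest
# CSV (one row per trial), and one signal CSV per subject in long layout
# (trial_index, sample, one column per channel).  Versioned so later layout
# changes stay readable.

ARCHIVE_VERSION <- "1"

#' Write a trial set to a plain-text archive
#'
#' @param trials Trials tibble (see [extract_trials()] or
#'   [generate_dataset()]).
#' @param dir Target directory (created if needed).
#' @param overwrite Refuse to touch an existing archive unless `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_trial_archive <- function(trials, dir, overwrite = FALSE) {
  stopifnot(nrow(trials) > 0L)
  if (file.exists(file.path(dir, "archive.json")) && !overwrite) {
    stop("archive already exists at ", dir, " (use overwrite = TRUE)",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- colnames(trials$data[[1]])

  manifest <- dplyr::select(trials, -"data")
  manifest$task <- as.character(manifest$task)
  manifest$file <- paste0("signals_", manifest$subject_id, ".csv")
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)

  for (sid in unique(trials$subject_id)) {
    sub <- trials[trials$subject_id == sid, , drop = FALSE]
    n_s <- nrow(sub$data[[1]])
    long <- do.call(rbind, sub$data)
    colnames(long) <- channels
    tab <- tibble::as_tibble(long)
    tab <- dplyr::bind_cols(
      tibble::tibble(trial_index = rep(sub$trial_index, each = n_s),
                     sample = rep(seq_len(n_s), times = nrow(sub))),
      tab)
    readr::write_csv(tab, file.path(dir, paste0("signals_", sid, ".csv")),
                     progress = FALSE)
  }

  jsonlite::write_json(
    list(version = ARCHIVE_VERSION, channels = channels,
         n_trials = nrow(trials),
         subjects = unique(trials$subject_id)),
    file.path(dir, "archive.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a trial archive written by [write_trial_archive()]
#'
#' @param dir Archive directory.
#' @return Trials tibble.
#' @export
read_trial_archive <- function(dir) {
  desc_path <- file.path(dir, "archive.json")
  if (!file.exists(desc_path)) {
    stop("no trial archive at ", dir, call. = FALSE)
  }
  desc <- jsonlite::read_json(desc_path, simplifyVector = TRUE)
  if (!identical(as.character(desc$version), ARCHIVE_VERSION)) {
    stop("unsupported archive version: ", desc$version, call. = FALSE)
  }
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE, progress = FALSE)
  manifest$task <- factor(manifest$task, levels = task_levels())
  channels <- desc$channels

  data_col <- vector("list", nrow(manifest))
  for (sid in unique(manifest$subject_id)) {
    rows <- which(manifest$subject_id == sid)
    tab <- readr::read_csv(file.path(dir, paste0("signals_", sid, ".csv")),
                           show_col_types = FALSE, progress = FALSE)
    for (r in rows) {
      block <- tab[tab$trial_index == manifest$trial_index[r], channels,
                   drop = FALSE]
      data_col[[r]] <- as.matrix(block)
    }
  }
  manifest$file <- NULL
  manifest$data <- data_col
  tibble::as_tibble(manifest)
}
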