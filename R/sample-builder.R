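#' The nine symmetric electrode pairs over the motor cortex
#'
#' Mirror-symmetric 10-10-system sites about the Fpz-Cz-Iz sagittal line:
#' FC5-FC6, FC3-FC4, FC1-FC2, C5-C6, C3-C4, C1-C2, CP5-CP6, CP3-CP4,
#' CP1-CP2.  Odd indices are left hemisphere, even are right.
#'
#' @return Tibble with columns `left`, `right`, `pair`.
#' @export
electrode_pairs <- function() {
  left <- c("FC5", "FC3", "FC1", "C5", "C3", "C1", "CP5", "CP3", "CP1")
  right <- c("FC6", "FC4", "FC2", "C6", "C4", "C2", "CP6", "CP4", "CP2")
  tibble::tibble(left = left, right = right, pair = paste0(left, "-", right))
}

check_pairs <- function(pairs) {
  if (is.character(pairs)) {
    pairs <- dplyr::filter(electrode_pairs(), .data$pair %in% !!pairs)
  }
  stopifnot(is.data.frame(pairs), all(c("left", "right") %in% names(pairs)))
  if (!"pair" %in% names(pairs)) pairs$pair <- paste0(pairs$left, "-", pairs$right)
  pairs
}

#' Cut electrode-pair samples from trials
#'
#' For every trial and every pair, extracts the `n_samples x 2` slice of the
#' trial's signal matrix — left-hemisphere electrode in column 1, right in
#' column 2 — with values copied untouched.  These 640 x 2 slices are the
#' unit the network classifies.
#'
#' @param trials Trials tibble with `subject_id`, `trial_index`, `task` and a
#'   `data` list-column of `n_samples x n_channels` matrices with channel
#'   labels as column names.
#' @param pairs Pair tibble (see [electrode_pairs()]) or character vector of
#'   pair labels such as `"C3-C4"`.
#' @return Samples tibble: `subject_id`, `trial_index`, `task`, `pair`, and a
#'   `data` list-column of `n_samples x 2` matrices.
#' @export
build_pair_samples <- function(trials, pairs = electrode_pairs()) {
  pairs <- check_pairs(pairs)
  if (nrow(pairs) == 0L || nrow(trials) == 0L) {
    return(tibble::tibble(subject_id = character(), trial_index = integer(),
                          task = factor(character(), levels = task_levels()),
                          pair = character(), data = list()))
  }
  labs <- colnames(trials$data[[1]])
  missing <- setdiff(unique(c(pairs$left, pairs$right)), labs)
  if (length(missing)) {
    stop("channel(s) not present in trials: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  # trial-major, pair-minor order: all of a trial's samples are adjacent
  out <- trials[rep(seq_len(nrow(trials)), each = nrow(pairs)),
                c("subject_id", "trial_index", "task")]
  out$pair <- rep(pairs$pair, times = nrow(trials))
  idx_l <- match(rep(pairs$left, times = nrow(trials)), labs)
  idx_r <- match(rep(pairs$right, times = nrow(trials)), labs)
  tr_of <- rep(seq_len(nrow(trials)), each = nrow(pairs))
  dl <- trials$data
  out$data <- lapply(seq_len(nrow(out)), function(i) {
    m <- dl[[tr_of[i]]][, c(idx_l[i], idx_r[i]), drop = FALSE]
    colnames(m) <- strsplit(out$pair[i], "-", fixed = TRUE)[[1]]
    m
  })
  tibble::as_tibble(out)
}

#' Assemble a multi-trial, multi-pair sample set
#'
#' Builds one sample per (trial, pair) — so `nrow(samples) = n_trials *
#' n_pairs` always — and records provenance.  Duplicate (subject, trial)
#' identities are an integrity error.
#'
#' @inheritParams build_pair_samples
#' @return Samples tibble (see [build_pair_samples()]) with a `provenance`
#'   attribute listing subjects and pairs.
#' @export
assemble_dataset <- function(trials, pairs = electrode_pairs()) {
  stopifnot(nrow(trials) > 0L)
  pairs <- check_pairs(pairs)
  key <- paste(trials$subject_id, trials$trial_index)
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, trial_index) in trials", call. = FALSE)
  }
  samples <- build_pair_samples(trials, pairs)
  attr(samples, "provenance") <- list(subjects = unique(trials$subject_id),
                                      pairs = pairs$pair,
                                      n_trials = nrow(trials))
  samples
}

#' Trial-wise stratified k-fold plan
#'
#' Assigns every trial to one of `k` folds, stratified per subject and task
#' class: within each (subject, class) cell the trials are shuffled, then
#' dealt round-robin into the folds starting at a random offset.  With 21
#' trials per class and `k = 10`, nine folds receive 2 trials of that class
#' and one fold receives 3; `trim_extra = TRUE` drops the 21st trial of each
#' cell instead (with a message), restoring exactly 2 per class per fold.
#' Splitting is by whole trial, so all pair-samples of a trial always land in
#' the same fold.
#'
#' @param trials Trials tibble.
#' @param k Number of folds.
#' @param seed Integer seed; the plan is deterministic given it.
#' @param mode `"group_level"` (one plan over all subjects, folds usable for
#'   pooled cross-validation) or `"within_subject"` (same stratified
#'   assignment, intended for per-subject cross-validation runs).
#' @param trim_extra Drop the remainder trials that would give one fold an
#'   extra trial per class.
#' @return Fold-plan tibble: `subject_id`, `trial_index`, `fold`, with
#'   attributes `k`, `seed`, `mode`.
#' @export
make_fold_plan <- function(trials, k = 10L, seed = 1L,
                           mode = c("group_level", "within_subject"),
                           trim_extra = FALSE) {
  mode <- match.arg(mode)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  counts <- dplyr::count(trials, .data$subject_id, .data$task)
  if (any(counts$n < k) && !trim_extra) {
    stop(sprintf("every subject needs at least k = %d trials per class", k),
         call. = FALSE)
  }
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)

  plan <- trials |>
    dplyr::select("subject_id", "trial_index", "task") |>
    dplyr::group_by(.data$subject_id, .data$task) |>
    dplyr::group_modify(function(df, key) {
      m <- nrow(df)
      ord <- sample.int(m)
      if (trim_extra && m > k * (m %/% k)) {
        keep_n <- k * (m %/% k)
        ord <- ord[seq_len(keep_n)]
        df <- df[ord, , drop = FALSE]
        message(sprintf("trimmed %d trial(s) of %s/%s to balance folds",
                        m - keep_n, key$subject_id, key$task))
      } else {
        df <- df[ord, , drop = FALSE]
      }
      start <- sample.int(k, 1L)
      df$fold <- ((start - 1L + seq_len(nrow(df)) - 1L) %% k) + 1L
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select("subject_id", "trial_index", "fold") |>
    dplyr::arrange(.data$subject_id, .data$trial_index)
  attr(plan, "k") <- as.integer(k)
  attr(plan, "seed") <- as.integer(seed)
  attr(plan, "mode") <- mode
  plan
}

#' Normalize a train/test split with training-set statistics
#'
#' Z-scores each electrode column using the mean and standard deviation
#' pooled over all training samples and time points of that column; the same
#' affine map is applied to the test set, so no test information leaks into
#' the normalization.  `method = "per_sample"` instead standardizes each
#' sample's columns by its own moments (no cross-set statistics at all).
#'
#' @param train,test Samples tibbles (test may be `NULL`).
#' @param method `"train_stats"` (default) or `"per_sample"`.
#' @param eps Guard added to a zero standard deviation (with a warning).
#' @return List with `train`, `test`, and `stats` (tibble: column, mean, sd).
#' @export
normalize_split <- function(train, test = NULL,
                            method = c("train_stats", "per_sample"),
                            eps = 1e-8) {
  method <- match.arg(method)
  stopifnot(nrow(train) > 0L)
  n_col <- ncol(train$data[[1]])
  if (method == "per_sample") {
    std1 <- function(s) {
      lapply(s, function(m) {
        z <- scale(m)
        attr(z, "scaled:center") <- NULL
        attr(z, "scaled:scale") <- NULL
        z
      })
    }
    train$data <- std1(train$data)
    if (!is.null(test)) test$data <- std1(test$data)
    return(list(train = train, test = test, stats = NULL))
  }
  big <- do.call(rbind, train$data)
  mu <- colMeans(big)
  sd_ <- apply(big, 2L, stats::sd)
  if (any(sd_ < eps)) {
    warning("near-zero variance column(s) guarded with eps", call. = FALSE)
    sd_ <- pmax(sd_, eps)
  }
  apply_stats <- function(s) {
    lapply(s, function(m) sweep(sweep(m, 2L, mu), 2L, sd_, "/"))
  }
  train$data <- apply_stats(train$data)
  if (!is.null(test)) test$data <- apply_stats(test$data)
  list(train = train, test = test,
       stats = tibble::tibble(column = seq_len(n_col), mean = mu, sd = sd_))
}
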