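# Cheap shared fixtures built in code.

quiet_spec <- function(...) synthetic_spec(...)

# A tiny trial set with deterministic content for bookkeeping tests.
tiny_trials <- function(n_per_class = 2L, subjects = "S001",
                        channels = c("FC3", "FC4", "C3", "C4"),
                        n_samples = 16L, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (sid in subjects) {
    tasks <- rep(task_levels(), each = n_per_class)
    for (i in seq_along(tasks)) {
      m <- matrix(rnorm(n_samples * length(channels)), n_samples)
      colnames(m) <- channels
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sid, trial_index = i,
        task = factor(tasks[i], levels = task_levels()), data = list(m))
    }
  }
  dplyr::bind_rows(rows)
}

# Repository root (tests run from tests/testthat).
root_dir <- function() normalizePath(file.path(testthat::test_path(), "..", ".."))
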