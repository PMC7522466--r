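test_that("EDF write-then-read round trips signals within format quantization", {
  set.seed(6)
  sig <- matrix(rnorm(3 * 480, sd = 40), 3, 480)
  rownames(sig) <- c("Fc3.", "Fc4.", "Cz..")     # corpus label dialect
  f <- tempfile(fileext = ".edf")
  write_edf(sig, 160, f)
  r <- read_edf(f)
  quantum <- max(apply(sig, 1, function(v) diff(range(v)))) / 65535
  expect_lt(max(abs(r$signals - sig)), 2 * quantum)
  expect_equal(r$fs, rep(160, 3))
  expect_equal(nrow(r$annotations), 0)           # zero annotations, no error
})

test_that("recordings normalize the channel-label dialect and expose 160 Hz", {
  set.seed(7)
  sig <- matrix(rnorm(2 * 960), 2, 960)
  rownames(sig) <- c("Fc3.", "C4..")
  f <- file.path(withr::local_tempdir(), "S042R04.edf")
  write_edf(sig, 160, f,
            annotations = tibble::tibble(onset = 0, duration = 4, code = "T1"))
  rec <- read_recording(f)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(rec$subject_id, "S042")
  expect_equal(rec$run_id, 4L)
  expect_equal(rec$labels, c("FC3", "C4"))
  expect_equal(rec$fs, 160)
})

test_that("missing files and annotation-less task runs are loud errors", {
  expect_error(read_edf("/nonexistent/file.edf"), "cannot read")
  sig <- matrix(0, 1, 320)
  rownames(sig) <- "C3"
  f <- file.path(withr::local_tempdir(), "S001R04.edf")
  write_edf(sig, 160, f)                         # no annotation channel
  expect_error(read_recording(f), "no cue annotations")
  # truncated file
  f2 <- tempfile(fileext = ".edf")
  write_edf(sig, 160, f2)
  raw_all <- readBin(f2, "raw", file.size(f2))
  writeBin(raw_all[1:(length(raw_all) - 100)], f2)
  expect_error(read_edf(f2), "truncated")
})

test_that("the run table decodes both cue meanings and rejects unknown runs", {
  expect_equal(map_annotation_to_task(4, "T1"), "left_fist")
  expect_equal(map_annotation_to_task(8, "T2"), "right_fist")
  expect_equal(map_annotation_to_task(6, "T1"), "both_fists")
  expect_equal(map_annotation_to_task(6, "T2"), "both_feet")
  expect_true(is.na(map_annotation_to_task(4, "T0")))
  expect_true(is.na(map_annotation_to_task(14, "T0")))
  expect_error(map_annotation_to_task(3, "T1"), "not in the configured")
  expect_error(map_annotation_to_task(4, "T9"), "unknown cue")
})

test_that("trial extraction cuts 640-sample windows and drops truncated trials", {
  spec <- synthetic_spec()
  set.seed(9)
  # five cues, the last starting 1 s before the record ends
  n_total <- 160 * 26
  sig <- matrix(rnorm(2 * n_total, sd = 10), 2, n_total)
  rownames(sig) <- c("C3", "C4")
  ann <- tibble::tibble(onset = c(0, 6, 12, 18, 25),
                        duration = rep(4, 5),
                        code = c("T1", "T2", "T1", "T2", "T1"))
  f <- file.path(withr::local_tempdir(), "S003R04.edf")
  # write annotations that extend past the record on purpose: clamp duration
  ann$duration[5] <- 1
  write_edf(sig, 160, f, ann)
  rec <- read_recording(f)
  expect_message(tr <- extract_trials(rec), "dropped 1")
  expect_equal(nrow(tr), 4)
  expect_true(all(vapply(tr$data, nrow, integer(1)) == 640L))
  expect_equal(as.character(tr$task),
               c("left_fist", "right_fist", "left_fist", "right_fist"))
  # window content: trial 2 starts at sample floor(6*160)+1
  expect_equal(tr$data[[2]][, "C3"],
               as.vector(read_edf(f)$signals[1, 961:1600]),
               tolerance = 1e-6)
  # non-integer sample count is a parameter error
  expect_error(extract_trials(rec, window_len_s = 4.0001), "integer")
  # empty annotation list gives an empty trial set
  f0 <- tempfile(fileext = ".edf")
  write_edf(sig[, 1:320, drop = FALSE], 160, f0,
            tibble::tibble(onset = numeric(), duration = numeric(),
                           code = character()))
  rec0 <- read_recording(f0, subject_id = "S003", run_id = 99L)
  expect_equal(nrow(extract_trials(rec0)), 0)
})

test_that("per-class capping keeps the first trials in run order", {
  tr <- tiny_trials(n_per_class = 6, subjects = "S001")
  expect_message(capped <- paircnn:::cap_trials_per_class(tr, 4), "dropping 8")
  expect_equal(nrow(capped), 16)
  per <- table(capped$task)
  expect_true(all(per == 4))
  first_lf <- tr$trial_index[tr$task == "left_fist"][1:4]
  expect_equal(capped$trial_index[capped$task == "left_fist"], first_lf)
})

test_that("trial archives round-trip data, labels and identity", {
  spec <- synthetic_spec()
  ds <- generate_dataset(spec, n_per_class = 2, seed = 3, n_subjects = 2)
  d <- file.path(withr::local_tempdir(), "arch")
  write_trial_archive(ds$trials, d)
  expect_error(write_trial_archive(ds$trials, d), "exists")
  back <- read_trial_archive(d)
  expect_equal(nrow(back), nrow(ds$trials))
  expect_equal(as.character(back$task), as.character(ds$trials$task))
  i <- 7
  expect_equal(back$data[[i]], ds$trials$data[[i]], ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_error(read_trial_archive(file.path(tempdir(), "nowhere")),
               "no trial archive")
})
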