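test_that("the default electrode-pair universe is the nine motor-cortex pairs", {
  ep <- electrode_pairs()
  expect_equal(nrow(ep), 9)
  expect_setequal(ep$pair, c("FC5-FC6", "FC3-FC4", "FC1-FC2", "C5-C6",
                             "C3-C4", "C1-C2", "CP5-CP6", "CP3-CP4",
                             "CP1-CP2"))
  # mirror symmetry: same prefix, odd left index, even right index
  expect_true(all(sub("\\d$", "", ep$left) == sub("\\d$", "", ep$right)))
  expect_true(all(as.integer(sub("^\\D+", "", ep$left)) %% 2 == 1))
  expect_true(all(as.integer(sub("^\\D+", "", ep$right)) %% 2 == 0))
})

test_that("pair samples are untouched copies in (left, right) column order", {
  tr <- tiny_trials(n_per_class = 1)
  tr$data[[1]][, "FC3"] <- 7
  tr$data[[1]][, "FC4"] <- -7
  s <- build_pair_samples(tr, c("FC3-FC4", "C3-C4"))
  expect_equal(nrow(s), nrow(tr) * 2)
  fc <- s[s$pair == "FC3-FC4" & s$trial_index == 1 &
            s$subject_id == "S001", ]$data[[1]]
  expect_equal(unique(fc[, 1]), 7)
  expect_equal(unique(fc[, 2]), -7)
  expect_equal(colnames(fc), c("FC3", "FC4"))
  # all 1,280 values of a 640 x 2 sample, for a full-size trial
  spec <- synthetic_spec()
  set.seed(2)
  m <- generate_trial(spec, "left_fist")
  full <- tibble::tibble(subject_id = "X", trial_index = 1L,
                         task = factor("left_fist", task_levels()),
                         data = list(m))
  sf <- build_pair_samples(full, "C3-C4")
  expect_equal(dim(sf$data[[1]]), c(640L, 2L))
  expect_equal(length(sf$data[[1]]), 1280L)
  expect_identical(sf$data[[1]][, 1], m[, "C3"])
})

test_that("empty pair lists and missing channels are handled", {
  tr <- tiny_trials(n_per_class = 1)
  expect_equal(nrow(build_pair_samples(tr, character(0))), 0)
  expect_error(build_pair_samples(tr, "CP5-CP6"), "CP5")
})

test_that("dataset assembly conserves |trials| x |pairs| and rejects duplicates", {
  tr <- tiny_trials(n_per_class = 3, subjects = c("S001", "S002"))
  s <- assemble_dataset(tr, c("FC3-FC4", "C3-C4"))
  expect_equal(nrow(s), nrow(tr) * 2)
  expect_equal(nrow(assemble_dataset(tr[1, ], "C3-C4")), 1)
  prov <- attr(s, "provenance")
  expect_setequal(prov$subjects, c("S001", "S002"))
  dup <- dplyr::bind_rows(tr, tr[1, ])
  expect_error(assemble_dataset(dup, "C3-C4"), "duplicate")
  # no (subject, trial, pair) triple appears twice
  expect_equal(anyDuplicated(paste(s$subject_id, s$trial_index, s$pair)), 0)
})

test_that("fold plans are deterministic, stratified partitions that never split a trial", {
  tr <- tiny_trials(n_per_class = 10, subjects = c("S001", "S002"))
  p1 <- make_fold_plan(tr, k = 5, seed = 3)
  p2 <- make_fold_plan(tr, k = 5, seed = 3)
  expect_identical(p1, p2)
  p3 <- make_fold_plan(tr, k = 5, seed = 4)
  expect_false(identical(p1$fold, p3$fold))
  # partition of all trials
  expect_setequal(paste(p1$subject_id, p1$trial_index),
                  paste(tr$subject_id, tr$trial_index))
  expect_equal(nrow(p1), nrow(tr))
  # stratification: each fold holds exactly 2 per class per subject
  joined <- dplyr::left_join(p1, dplyr::select(tr, "subject_id",
                                               "trial_index", "task"),
                             by = c("subject_id", "trial_index"))
  counts <- dplyr::count(joined, .data$subject_id, .data$task, .data$fold)
  expect_true(all(counts$n == 2))
  expect_error(make_fold_plan(tr, k = 1), "at least 2")
  expect_error(make_fold_plan(tiny_trials(n_per_class = 3), k = 5),
               "at least")
})

test_that("21 trials per class deal 2 per fold with one fold taking the extra; trimming restores balance", {
  tr <- tiny_trials(n_per_class = 21, subjects = "S001")
  plan <- make_fold_plan(tr, k = 10, seed = 2)
  joined <- dplyr::left_join(plan, dplyr::select(tr, "subject_id",
                                                 "trial_index", "task"),
                             by = c("subject_id", "trial_index"))
  per <- dplyr::count(joined, .data$task, .data$fold)
  expect_true(all(per$n %in% c(2, 3)))
  expect_equal(sum(per$n == 3), 4)          # one overfull fold per class
  fold_sizes <- dplyr::count(plan, .data$fold)$n
  expect_true(all(fold_sizes %in% 8:12))
  expect_equal(sum(fold_sizes), 84)
  # trimmed plan: exactly 2 per class per fold, 8 test trials per fold
  expect_message(pt <- make_fold_plan(tr, k = 10, seed = 2, trim_extra = TRUE),
                 "trimmed")
  expect_equal(nrow(pt), 80)
  expect_true(all(dplyr::count(pt, .data$fold)$n == 8))
})

test_that("normalization uses train statistics only and behaves as an affine map", {
  spec <- synthetic_spec()
  ds <- generate_dataset(spec, n_per_class = 10, seed = 21)
  s <- ds$samples
  train <- s[1:30, ]; test <- s[31:40, ]
  ns <- normalize_split(train, test)
  big <- do.call(rbind, ns$train$data)
  expect_true(all(abs(colMeans(big)) < 1e-6))
  expect_true(all(abs(apply(big, 2, sd) - 1) < 1e-3))
  # test columns are NOT zero mean (no leakage of test statistics)
  bigt <- do.call(rbind, ns$test$data)
  expect_false(all(abs(colMeans(bigt)) < 1e-8))
  # constant test column maps to (c - mu)/sd
  test2 <- test
  test2$data[[1]][, 1] <- 5
  ns2 <- normalize_split(train, test2)
  expect_equal(unique(ns2$test$data[[1]][, 1]),
               unname((5 - ns2$stats$mean[1]) / ns2$stats$sd[1]))
  # idempotence to tolerance: renormalizing normalized data changes little
  ns3 <- normalize_split(ns$train)
  expect_lt(max(abs(ns3$train$data[[5]] - ns$train$data[[5]])), 1e-2)
  # standard-normal columns pass through nearly unchanged
  mk <- function() {
    m <- matrix(rnorm(640 * 2), 640, 2)
    tibble::tibble(subject_id = "Z", trial_index = 1L,
                   task = factor("left_fist", task_levels()), data = list(m))
  }
  set.seed(31)
  tr31 <- dplyr::bind_rows(lapply(1:50, function(i) {
    x <- mk(); x$trial_index <- i; x
  }))
  nsn <- normalize_split(tr31)
  expect_lt(max(abs(nsn$train$data[[1]] - tr31$data[[1]])), 0.05)
  # zero-variance guard
  flat <- tr31[1:3, ]
  for (i in 1:3) flat$data[[i]][, 2] <- 3
  expect_warning(normalize_split(flat), "variance")
})

test_that("per-sample normalization standardizes each sample independently", {
  tr <- tiny_trials(n_per_class = 1, n_samples = 64L)
  ns <- normalize_split(tr, method = "per_sample")
  for (m in ns$train$data) {
    expect_true(all(abs(colMeans(m)) < 1e-10))
    expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-10))
  }
})
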