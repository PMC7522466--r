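#' Specification of the synthetic motor-imagery EEG generator
#'
#' Describes a two-hemisphere event-related-desynchronization (ERD) model for
#' 4 s, 160 Hz epochs: each channel is the sum of 1/f ("pink") background
#' noise, white sensor noise, and stochastic narrowband mu (8-12 Hz) and beta
#' (18-26 Hz) oscillations whose amplitude is attenuated by the imagined task
#' in a lateralized way:
#'
#' * left fist  -> mu attenuated by `erd_depth` on right-hemisphere channels
#'   (contralateral ERD),
#' * right fist -> mu attenuated on left-hemisphere channels,
#' * both fists -> mu attenuated on both,
#' * both feet  -> beta attenuated on both, mu intact (a non-physiological
#'   shorthand that keeps the four classes distinct in band power).
#'
#' Oscillations are band-limited Gaussian noise (randomized phase and
#' naturally varying envelope), not deterministic sinusoids, so no two trials
#' are alike and classifiers cannot key on phase.
#'
#' @param fs Sampling rate in Hz.
#' @param duration Epoch length in seconds (`fs * duration` must be integer).
#' @param mu_band,beta_band Frequency bands in Hz.
#' @param baseline_mu_amp,baseline_beta_amp RMS amplitude (microvolts) of the
#'   unattenuated oscillations.
#' @param erd_depth Attenuation fraction in `[0, 1]`; 0 makes all classes
#'   identically distributed, 1 removes the band entirely.
#' @param pink_exponent Spectral slope of the background (PSD ~ 1/f^a).
#' @param pink_sd,white_sd RMS amplitude (microvolts) of background and
#'   sensor noise.
#' @param pair Default two-electrode montage (left, right hemisphere).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(fs = 160, duration = 4, mu_band = c(8, 12),
                           beta_band = c(18, 26), baseline_mu_amp = 6,
                           baseline_beta_amp = 4, erd_depth = 0.8,
                           pink_exponent = 1, pink_sd = 6, white_sd = 3,
                           pair = c("C3", "C4")) {
  n <- fs * duration
  if (abs(n - round(n)) > 1e-9) stop("fs * duration must be an integer",
                                     call. = FALSE)
  stopifnot(erd_depth >= 0, erd_depth <= 1, length(pair) == 2L)
  structure(list(fs = fs, duration = duration, n_samples = as.integer(round(n)),
                 mu_band = mu_band, beta_band = beta_band,
                 baseline_mu_amp = baseline_mu_amp,
                 baseline_beta_amp = baseline_beta_amp,
                 erd_depth = erd_depth, pink_exponent = pink_exponent,
                 pink_sd = pink_sd, white_sd = white_sd, pair = pair),
            class = "synthetic_spec")
}

#' The four motor-imagery task labels
#'
#' @return Factor levels used throughout the package, in cue-code order
#'   (T1 = left fist, T2 = right fist, T3 = both fists, T4 = both feet).
#' @export
task_levels <- function() c("left_fist", "right_fist", "both_fists", "both_feet")

# Filtered Gaussian noise via FFT shaping.  `amp_fun(f)` gives the spectral
# amplitude at frequency f (Hz); output is scaled so its expected RMS is
# `target_rms` while trial-to-trial power still fluctuates naturally.
shaped_noise <- function(n, fs, amp_fun, target_rms) {
  if (target_rms <= 0) return(numeric(n))
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  A <- amp_fun(f)
  A[1] <- 0                                 # no DC
  x <- stats::rnorm(n)
  z <- Re(stats::fft(stats::fft(x) * A, inverse = TRUE)) / n
  scale <- target_rms / sqrt(mean(A^2))
  z * scale
}

pink_amp <- function(expo) function(f) ifelse(f > 0, f^(-expo / 2), 0)
band_amp <- function(band) function(f) as.numeric(f >= band[1] & f <= band[2])

# Which hemispheres see mu attenuation for a task (left, right indicator).
mu_attenuation_map <- function(task) {
  switch(task,
         left_fist = c(0, 1),    # contralateral: right hemisphere
         right_fist = c(1, 0),
         both_fists = c(1, 1),
         both_feet = c(0, 0),
         stop("unknown task: ", task, call. = FALSE))
}

hemisphere_of <- function(label) {
  digit <- suppressWarnings(as.integer(sub("^.*?(\\d+)$", "\\1", label)))
  if (is.na(digit)) stop("channel label has no site index: ", label,
                         call. = FALSE)
  if (digit %% 2L == 1L) "left" else "right"
}

gen_channel <- function(spec, task, hemisphere) {
  att <- mu_attenuation_map(task)
  mu_scale <- 1 - spec$erd_depth * if (hemisphere == "left") att[1] else att[2]
  beta_scale <- 1 - spec$erd_depth * as.numeric(task == "both_feet")
  n <- spec$n_samples
  shaped_noise(n, spec$fs, pink_amp(spec$pink_exponent), spec$pink_sd) +
    stats::rnorm(n, sd = spec$white_sd) +
    shaped_noise(n, spec$fs, band_amp(spec$mu_band),
                 spec$baseline_mu_amp * mu_scale) +
    shaped_noise(n, spec$fs, band_amp(spec$beta_band),
                 spec$baseline_beta_amp * beta_scale)
}

#' Generate one synthetic motor-imagery epoch
#'
#' @param spec A [synthetic_spec()].
#' @param task One of [task_levels()].
#' @param channels Channel labels to synthesize (hemisphere read from the
#'   trailing site index: odd = left, even = right); defaults to the spec's
#'   electrode pair.
#' @return Numeric matrix `n_samples x length(channels)` in microvolts, with
#'   channel labels as column names.  Uses the global RNG.
#' @export
generate_trial <- function(spec, task, channels = spec$pair) {
  task <- match.arg(task, task_levels())
  out <- vapply(channels,
                function(ch) gen_channel(spec, task, hemisphere_of(ch)),
                numeric(spec$n_samples))
  colnames(out) <- channels
  out
}

#' Generate a balanced labeled synthetic dataset
#'
#' Produces `n_per_class` trials per task for each of `n_subjects` synthetic
#' subjects, plus the electrode-pair samples cut from them, deterministically
#' under `seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param n_per_class Trials per task per subject.
#' @param seed Integer seed.
#' @param n_subjects Number of synthetic subjects.
#' @param pairs Electrode pairs to cut samples for, as a tibble with `left`,
#'   `right` (see [electrode_pairs()]); `NULL` uses the spec's single pair.
#'   Channels synthesized are the union of the pairs' members.
#' @return List with `trials` (tibble: subject_id, trial_index, task, data
#'   list-column) and `samples` (tibble from [assemble_dataset()]).
#' @export
generate_dataset <- function(spec, n_per_class, seed = 1L, n_subjects = 1L,
                             pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- tibble::tibble(left = spec$pair[1], right = spec$pair[2],
                            pair = paste(spec$pair, collapse = "-"))
  }
  channels <- unique(c(pairs$left, pairs$right))
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)

  tasks <- rep(task_levels(), each = n_per_class)
  rows <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    ord <- sample.int(length(tasks))
    dat <- lapply(tasks[ord], function(tk) generate_trial(spec, tk, channels))
    rows[[s]] <- tibble::tibble(
      subject_id = sprintf("SYN%03d", s),
      trial_index = seq_along(tasks),
      task = factor(tasks[ord], levels = task_levels()),
      data = dat)
  }
  trials <- dplyr::bind_rows(rows)
  list(trials = trials, samples = assemble_dataset(trials, pairs))
}

#' Band-power features for a set of epochs
#'
#' Mean periodogram power (microvolts squared) in the mu and beta bands for
#' each channel of each epoch — the classical ERD feature set.  Used as an
#' independent, non-neural reference classifier's input when validating the
#' synthetic generator's class separability.
#'
#' @param data_list List of `n_samples x n_channels` matrices (e.g. the
#'   `data` column of a trials or samples tibble).
#' @param fs Sampling rate in Hz.
#' @param mu_band,beta_band Frequency bands in Hz.
#' @return Tibble with `log` band powers, columns `mu_1`, `beta_1`, `mu_2`,
#'   `beta_2`, ... per channel.
#' @export
bandpower_features <- function(data_list, fs = 160, mu_band = c(8, 12),
                               beta_band = c(18, 26)) {
  n <- nrow(data_list[[1]])
  f <- (seq_len(n %/% 2)) * fs / n
  in_mu <- f >= mu_band[1] & f <= mu_band[2]
  in_beta <- f >= beta_band[1] & f <= beta_band[2]
  feats <- t(vapply(data_list, function(m) {
    sp <- abs(stats::mvfft(as.matrix(m)))^2 / n
    sp <- sp[1 + seq_len(n %/% 2), , drop = FALSE]   # positive frequencies
    as.vector(rbind(log(colMeans(sp[in_mu, , drop = FALSE])),
                    log(colMeans(sp[in_beta, , drop = FALSE]))))
  }, numeric(2L * ncol(data_list[[1]]))))
  cn <- as.vector(rbind(paste0("mu_", seq_len(ncol(data_list[[1]]))),
                        paste0("beta_", seq_len(ncol(data_list[[1]])))))
  colnames(feats) <- cn
  tibble::as_tibble(feats)
}

# Reverse lookup: which cue code encodes `task` in run `run_id`.
task_to_code <- function(task, run_id, run_table = mi_run_table()) {
  row <- which(run_table$run == run_id)
  if (!length(row)) stop("run ", run_id, " not in run table", call. = FALSE)
  if (run_table$T1[row] == task) return("T1")
  if (run_table$T2[row] == task) return("T2")
  stop(sprintf("task %s cannot be cued in run %d", task, run_id),
       call. = FALSE)
}

#' Write trials to a cue-annotated EDF+ fixture file
#'
#' Lays the trials out sequentially -- each followed by a rest gap -- with
#' one cue annotation per trial, producing a file that exercises the whole
#' EDF reading / epoching path end-to-end.  All trials must belong to the
#' task pair that the given run number can cue.
#'
#' @param trials Trials tibble; `data` matrices share one channel set.
#' @param path Output `.edf` path.
#' @param run_id Run number that determines the cue coding (see
#'   [mi_run_table()]).
#' @param fs Sampling rate in Hz.
#' @param rest_s Gap between trials, seconds.
#' @return `path`, invisibly.
#' @export
write_fixture_edf <- function(trials, path, run_id, fs = 160, rest_s = 2) {
  if (nrow(trials) == 0L) {
    sig <- matrix(0, 2, fs)
    rownames(sig) <- c("C3", "C4")
    return(write_edf(sig, fs, path,
                     annotations = tibble::tibble(onset = numeric(),
                                                  duration = numeric(),
                                                  code = character())))
  }
  n_s <- nrow(trials$data[[1]])
  slot <- n_s + as.integer(round(rest_s * fs))
  channels <- colnames(trials$data[[1]])
  total <- slot * nrow(trials)
  sig <- matrix(0, length(channels), total)
  rownames(sig) <- channels
  onset <- numeric(nrow(trials))
  code <- character(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    a <- (i - 1L) * slot
    sig[, (a + 1L):(a + n_s)] <- t(trials$data[[i]])
    onset[i] <- a / fs
    code[i] <- task_to_code(as.character(trials$task[i]), run_id)
  }
  write_edf(sig, fs, path,
            annotations = tibble::tibble(onset = onset,
                                         duration = n_s / fs, code = code),
            patient_id = trials$subject_id[1],
            recording_id = sprintf("synthetic run %d", run_id))
  invisible(path)
}

#' Write a full synthetic subject as per-run EDF+ fixtures
#'
#' Splits the subject's trials over the six imagery runs the corpus layout
#' uses -- left/right fist over runs 4, 8, 12; both fists/feet over runs 6,
#' 10, 14 -- and writes one annotated EDF+ file per run.
#'
#' @param trials Trials tibble for one subject.
#' @param dir Output directory.
#' @param fs Sampling rate in Hz.
#' @return Character vector of the written file paths, invisibly.
#' @export
write_subject_fixture <- function(trials, dir, fs = 160) {
  stopifnot(length(unique(trials$subject_id)) == 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sid <- trials$subject_id[1]
  groups <- list(lr = c("left_fist", "right_fist"),
                 ff = c("both_fists", "both_feet"))
  runs <- list(lr = c(4L, 8L, 12L), ff = c(6L, 10L, 14L))
  paths <- character(0)
  for (g in names(groups)) {
    sub <- trials[trials$task %in% groups[[g]], , drop = FALSE]
    if (nrow(sub) == 0L) next
    # deal trials round-robin over the three runs of this task pair
    run_of <- runs[[g]][((seq_len(nrow(sub)) - 1L) %% 3L) + 1L]
    for (r in unique(run_of)) {
      p <- file.path(dir, sprintf("%sR%02d.edf", sid, r))
      write_fixture_edf(sub[run_of == r, , drop = FALSE], p, run_id = r,
                        fs = fs)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
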