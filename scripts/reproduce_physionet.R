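#!/usr/bin/env Rscript

# Optional full-corpus protocol (NOT part of the test suite): reproduces the
# group-level cross-validation on the real 109-subject motor-imagery corpus.
#
# Requires the PhysioNet "EEG Motor Movement/Imagery Dataset" (~3.4 GB)
# downloaded locally, e.g.:
#   wget -r -N -c -np https://physionet.org/files/eegmmidb/1.0.0/
# and then:
#   Rscript scripts/reproduce_physionet.R <edf_root> <out_dir> [n_subjects]
#
# With 10-fold cross-validation and 2,000 Adam iterations per fold this is
# hours of CPU; results are stochastic at the level of a fraction of a
# percentage point across seeds.

suppressPackageStartupMessages(library(paircnn))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 2) {
  stop("usage: reproduce_physionet.R <edf_root> <out_dir> [n_subjects]")
}
edf_root <- args[1]
out_dir <- args[2]
n_subjects <- if (length(args) >= 3) as.integer(args[3]) else 20L

cfg <- list(
  data = list(source = "edf", path = edf_root,
              subjects = sprintf("S%03d", seq_len(n_subjects)),
              trials_per_class = 21),
  pairs = electrode_pairs()$pair,
  folds = list(k = 10),
  train = list(iterations = 2000, learning_rate = 1e-5, batch_size = 64),
  output_dir = out_dir,
  seed = 1)

cmd_prepare(cfg, force = TRUE)
cv <- cmd_train(cfg)
print(glance(cv))
cmd_evaluate(cfg, preset = "per_pair")
cmd_evaluate(cfg, preset = "ablation")
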