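#!/usr/bin/env Rscript
# Step 1: build the synthetic FAERS-dialect quarterly package that the rest
# of the analysis runs on. The world emulates a newly approved myelofibrosis
# drug: 50,000 reports over ten quarters, a planted 4-fold diarrhoea signal
# plus a 2-fold fatigue signal and a null term, FAERS-like duplicate and
# deleted cases, ~82% missing demographics, and a log-normal onset profile
# with median 27 days of which ~24% are computable.
#
# The package files land in scratch/ (they are bulky regenerable inputs);
# the ground truth summary lands in results/.

library(faersignal)
library(data.table)

cfg <- faers_gen_config(
  n_reports = 50000L, seed = 1L,
  planted_signals = c(Diarrhoea = 4, Fatigue = 2, Headache = 1),
  duplicate_rate = 0.05, deleted_rate = 0.02)

dir.create("scratch", showWarnings = FALSE)
pkg_dir <- "scratch/synth_faers"
synth <- generate_package(cfg, pkg_dir)

gt <- synth$ground_truth$reports
cat("wrote", pkg_dir, "with", nrow(gt), "cases across",
    length(cfg$quarters), "quarters\n")
cat("  duplicated cases:", gt[duplicated == TRUE, .N],
    "| deleted cases:", gt[deleted == TRUE, .N], "\n")
cat("  target primary-suspect cases (ground truth cohort):",
    gt[target_ps == TRUE & deleted == FALSE, .N], "\n")

dir.create("results", showWarnings = FALSE)
write_analysis_tables(list(
  ground_truth_planted = synth$ground_truth$planted,
  ground_truth_case_counts = data.table(
    what = c("cases", "duplicated", "deleted", "target_ps_cohort"),
    n = c(nrow(gt), gt[duplicated == TRUE, .N], gt[deleted == TRUE, .N],
          gt[target_ps == TRUE & deleted == FALSE, .N]))),
  "results")
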