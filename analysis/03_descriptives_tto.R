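#!/usr/bin/env Rscript
# Step 3: descriptive profile of the cohort (with explicit missing-data
# denominators) and the time-to-onset analysis: median/IQR on day-precision
# date pairs only, binned into <=1 month, 1-3 months, 3-12 months, >1 year.

library(faersignal)
library(data.table)

target <- c("pacritinib", "Vonjo")
pkg <- read_faers_package("scratch/synth_faers")
cohort <- build_cohort(pkg, target)
inco <- cohort$reports$primaryid %in% cohort$cohort_primaryids

summ <- summarize_cohort(cohort$reports[inco],
                         cohort$outc[primaryid %in%
                                       cohort$cohort_primaryids])
print(summ)

onset <- compute_tto(cohort$reports[inco],
                     cohort$drug[primaryid %in% cohort$cohort_primaryids],
                     target)
print(onset)
cat("exclusions by reason:\n"); print(onset$excluded)

dir.create("results", showWarnings = FALSE)
write_analysis_tables(list(
  descriptives = descriptives_table(summ),
  descriptive_denominators = summ$denominators,
  tto_bins = onset$bins,
  tto_exclusions = onset$excluded,
  tto_summary = data.table(
    n_evaluable = onset$n_evaluable, median_days = onset$median_days,
    iqr_lo = onset$iqr_lo, iqr_hi = onset$iqr_hi)),
  "results")
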