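#!/usr/bin/env Rscript
# Step 2: ingest the quarterly package and apply the report-selection
# funnel: deduplicate by CASEID (keep the largest PRIMARYID), drop deleted
# cases, then keep reports naming the target drug as primary suspect via
# fuzzy name matching. Writes the stage-by-stage record counts.

library(faersignal)
library(data.table)

pkg <- read_faers_package("scratch/synth_faers")
print(pkg)

cohort <- build_cohort(pkg, target_names = c("pacritinib", "Vonjo"))
funnel <- data.table(stage = names(cohort$funnel),
                     n = as.integer(cohort$funnel))
print(funnel)
cat("primary-suspect cohort:", length(cohort$cohort_primaryids),
    "reports\n")

dir.create("results", showWarnings = FALSE)
write_analysis_tables(list(cohort_funnel = funnel), "results")
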