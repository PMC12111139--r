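#!/usr/bin/env Rscript
# Stage 2: apply the inclusion/exclusion cascade and diagnostic grouping.
#
# Gates run in order: age (>= 18.0 at 2012-01-01 and 18-40 during 2015),
# index claim (a "CNS other" drug dispensed in 2015), flumazenil-only.
# Retained patients are assigned F90 / non-F90 from any F90-prefixed
# ICD-10 code over the whole window. Recovery is checked against the
# generator's labels.

library(adhere)

cs <- read_claims("results/synthetic_claims.csv")
labels <- read.csv("results/synthetic_labels.csv", stringsAsFactors = FALSE)

cohort <- build_cohort(cs)
gates <- gate_summary(cohort)
write.csv(cohort, "results/cohort_report.csv", row.names = FALSE)
write.csv(gates, "results/gate_summary.csv", row.names = FALSE)

print(as.data.frame(gates), row.names = FALSE)
m <- merge(cohort, labels, by = "patient_id")
cat(sprintf("status recovery vs generator labels: %.1f%%\n",
            100 * mean(m$status == m$status_true)))
cat(sprintf("group  recovery vs generator labels: %.1f%%\n",
            100 * mean(m$group == m$group_true)))
inc <- cohort[cohort$status == "INCLUDED", ]
cat(sprintf("included: %d (F90 %d / non-F90 %d)\n", nrow(inc),
            sum(inc$group == "F90"), sum(inc$group == "NON_F90")))
cat("-> results/cohort_report.csv, results/gate_summary.csv\n")
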