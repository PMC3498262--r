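#!/usr/bin/env Rscript
# Cohort composition tables.
#
# The published cohort reports 59 patients with thalamic or basal ganglia
# tumors, typed from the three-line geometry on the foramen-of-Monro slice:
# 6 type 1, 6 type 2, 7 type 3a, 5 type 3b, 17 type 4a, 6 type 4b, 3 type 5
# and 9 type 6. This driver feeds those counts through summarize_cohort()
# and writes the per-type shares and the line-based aggregate groups.
#
# Finding: type 4a (posterior-medial, beyond line 3) dominates at 28.81%;
# tumors lateral of line 1 (types 3 and 5) make up 25.42% of the cohort,
# those anterior of line 2 (types 2, 5, 6) 30.5%, and those mainly beyond
# line 3 (types 3a and 4a) 40.68%.

suppressMessages(library(ptclock))
dir.create("results", showWarnings = FALSE)

counts <- c(T1 = 6, T2 = 6, T3A = 7, T3B = 5, T4A = 17, T4B = 6, T5 = 3,
            T6 = 9)
s <- summarize_cohort(counts, digits = 2)

per_type <- data.frame(type = tumor_types(),
                       n = as.integer(s$counts),
                       share_pct = unname(s$percent),
                       predicted_pt_sector = predict_sector(tumor_types()))
write.csv(per_type, "results/cohort_per_type.csv", row.names = FALSE)

aggregates <- data.frame(group = names(s$aggregates),
                         n = as.integer(s$aggregates),
                         share_pct = unname(s$aggregate_percent))
write.csv(aggregates, "results/cohort_aggregates.csv", row.names = FALSE)

cat("cohort n =", s$n, "\n")
print(per_type, row.names = FALSE)
print(aggregates, row.names = FALSE)
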