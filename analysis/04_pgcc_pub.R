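#!/usr/bin/env Rscript
# Stage 4: PGCC quantification, PUB scoring and diagnostic performance.
#
# Flags PGCCs (nuclear area >= 3x the tumor's median), computes per-field
# density and the abundance flag (>= 1 per 40x field), combines abundance
# with the UBE2C grade into the 0-2 PUB score, and cross-tabulates PUB=2
# against the FISH ploidy call. Writes results/pub.csv and
# results/performance.json.

library(hccploidy)

nuclei <- validate_table("results/cohort/nuclei.csv", "nuclei")
ihc <- validate_table("results/cohort/ihc.csv", "ihc")
profiles <- validate_table("results/tumor_profiles.csv", "tumor_profiles")

pub <- pub_table(pgcc_cohort(nuclei), ihc)
readr::write_csv(pub, "results/pub.csv")
message(sprintf("PUB scores: %d x 0, %d x 1, %d x 2",
                sum(pub$pub_score == 0), sum(pub$pub_score == 1),
                sum(pub$pub_score == 2)))

perf <- evaluate_pub(pub, profiles)
jsonlite::write_json(unclass(perf), "results/performance.json",
                     auto_unbox = TRUE, digits = NA)
print(perf)
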