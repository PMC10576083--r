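#!/usr/bin/env Rscript
# Stage 1: generate the study-mirror synthetic cohort.
#
# 56 tumors, 20 truly polyploid (stratified), 250 tumor nuclei per tumor over
# 6 high-magnification fields, 10% per-signal FFPE dropout, 5% whole-nucleus
# hybridization failure, marker categories allocated so the PUB=2 x class
# table is the study-mirror 15/5/3/33. Writes the four cohort tables under
# results/cohort/.

library(hccploidy)

seed <- 1L
cfg <- generator_config(seed = seed)
cohort <- generate_cohort(cfg)
paths <- write_cohort_tables(cohort, "results/cohort")

tr <- cohort$truths
message(sprintf("cohort: %d tumors (%d polyploid, %d near-diploid), seed %d",
                nrow(tr), sum(tr$true_class == "polyploid"),
                sum(tr$true_class == "near_diploid"), seed))
message(sprintf("nuclei table: %d rows (%d tumor nuclei, %d planted PGCCs)",
                nrow(cohort$nuclei), sum(cohort$nuclei$is_tumor),
                sum(cohort$nuclei$planted_pgcc)))
message("wrote: ", paste(paths, collapse = ", "))
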