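#!/usr/bin/env Rscript
# Stage 2: call tumor ploidy from the per-nucleus FISH spot counts.
#
# Per chromosome the predominant (modal non-zero) spot count over tumor
# nuclei; tumors with an average of the three predominant copies >= 2.5 are
# polyploid. Reads results/cohort/nuclei.csv, writes
# results/tumor_profiles.csv.

library(hccploidy)

nuclei <- validate_table("results/cohort/nuclei.csv", "nuclei")
profiles <- call_cohort(nuclei)
readr::write_csv(profiles, "results/tumor_profiles.csv")

s <- ploidy_call_summary(profiles)
message(sprintf("%d / %d tumors called polyploid (%.1f%%)",
                s$n_polyploid, s$n_tumors, s$pct_polyploid))
message(sprintf("mean average ploidy of the polyploid group: %.2f copies",
                s$mean_ploidy_polyploid))
message(sprintf("QC: %d tumors passed the >=200-nuclei / >=5-field minima",
                sum(profiles$qc_pass)))
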