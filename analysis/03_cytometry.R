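#!/usr/bin/env Rscript
# Stage 3: image-cytometric validation of the ploidy calls.
#
# Gates HNF4a+/Ki-67- tumor nuclei, normalizes integrated DAPI intensity to
# DNA content against each tumor's non-tumor (diploid) nuclei, and compares
# per-tumor median DNA content and nuclear area between the called groups
# (one-sided Mann-Whitney, polyploid > near-diploid). Writes
# results/cytometry.csv.

library(hccploidy)

nuclei <- validate_table("results/cohort/nuclei.csv", "nuclei")
profiles <- validate_table("results/tumor_profiles.csv", "tumor_profiles")

cyt <- cytometry_cohort(nuclei)
readr::write_csv(cyt, "results/cytometry.csv")

grp <- profiles$call[match(cyt$tumor_id, profiles$tumor_id)]
poly <- cyt[grp == "polyploid", ]
near <- cyt[grp == "near_diploid", ]
for (metric in c("median_c", "median_area")) {
  res <- compare_groups(poly, near, metric, "greater")
  message(sprintf(
    "%s: polyploid median %.2f vs near-diploid %.2f (one-sided MWU p = %.2e)",
    metric, median(res$a), median(res$b), res$p_value))
}
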