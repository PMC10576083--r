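#!/usr/bin/env Rscript
# Stage 5: cohort statistics and survival stratification.
#
# Serum AFP comparison (one-sided Mann-Whitney, polyploid > near-diploid),
# Fisher's exact test on the PUB=2 x ploidy-call table, and Kaplan-Meier /
# log-rank overall survival stratified by ploidy call and by PUB score.
# Writes results/stats_report.json and results/km_curves.csv.

library(hccploidy)

tabs <- read_cohort_tables("results/cohort")
profiles <- validate_table("results/tumor_profiles.csv", "tumor_profiles")
cyt <- readr::read_csv("results/cytometry.csv", show_col_types = FALSE)
pub <- readr::read_csv("results/pub.csv", show_col_types = FALSE)

rep <- cohort_stats_report(tabs$clinical, tabs$survival, profiles, cyt, pub)

jsonlite::write_json(list(
  afp = rep$afp,
  median_c = rep$median_c[c("metric", "statistic", "p_value", "alternative")],
  median_area = rep$median_area[c("metric", "statistic", "p_value",
                                  "alternative")],
  pub_vs_call_fisher = rep$pub_vs_call,
  km_ploidy = rep$km_ploidy[c("chisq", "df", "p_value")],
  km_pub = rep$km_pub[c("chisq", "df", "p_value")]
), "results/stats_report.json", auto_unbox = TRUE, digits = NA)

km <- dplyr::bind_rows(
  dplyr::mutate(rep$km_ploidy$curves, stratification = "ploidy"),
  dplyr::mutate(rep$km_pub$curves, stratification = "pub"))
readr::write_csv(km, "results/km_curves.csv")

message(sprintf("AFP polyploid > near-diploid: one-sided MWU p = %.3g",
                rep$afp$p_value))
message(sprintf("log-rank, polyploid vs near-diploid: chisq = %.2f, p = %.3g",
                rep$km_ploidy$chisq, rep$km_ploidy$p_value))
message(sprintf("log-rank, PUB=2 vs PUB<2: chisq = %.2f, p = %.3g",
                rep$km_pub$chisq, rep$km_pub$p_value))
message(sprintf("Fisher exact on the PUB=2 x call table: p = %.3g",
                rep$pub_vs_call$p_value))
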