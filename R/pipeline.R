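#' Cohort-level statistics report
#'
#' The statistical layer over the pipeline outputs: one-sided Mann-Whitney
#' comparisons of serum AFP and of the cytometric medians (polyploid >
#' near-diploid), Fisher's exact test on the PUB=2 x ploidy-call table, and
#' Kaplan-Meier / log-rank survival stratified by ploidy call and by PUB
#' score (2 vs below 2).
#'
#' @param clinical Clinical tibble (`tumor_id`, `afp_ng_ml`, `true_class`).
#' @param survival_records Survival tibble (`tumor_id`, `time_years`, `event`).
#' @param profiles Tumor profiles ([call_cohort()]).
#' @param cytometry Cytometry tibble ([cytometry_cohort()]).
#' @param pub PUB results ([pub_table()]).
#' @return List with components `afp`, `median_c`, `median_area`
#'   (Mann-Whitney results), `pub_vs_call` (Fisher), `km_ploidy`, `km_pub`
#'   (curves + log-rank), and `performance` ([evaluate_pub()]).
#' @export
cohort_stats_report <- function(clinical, survival_records, profiles,
                                cytometry, pub) {
  call_of <- setNames(profiles$call, profiles$tumor_id)
  grp <- call_of[clinical$tumor_id]
  afp <- mann_whitney_one_sided(
    clinical$afp_ng_ml[grp == "polyploid"],
    clinical$afp_ng_ml[grp == "near_diploid"], alternative = "greater")

  cyt_grp <- call_of[cytometry$tumor_id]
  cyt_poly <- cytometry[cyt_grp == "polyploid", , drop = FALSE]
  cyt_near <- cytometry[cyt_grp == "near_diploid", , drop = FALSE]
  cmp_c <- compare_groups(cyt_poly, cyt_near, "median_c", "greater")
  cmp_area <- compare_groups(cyt_poly, cyt_near, "median_area", "greater")

  perf <- evaluate_pub(pub, profiles)
  fisher <- fisher_exact_2x2(matrix(c(perf$tp, perf$fn, perf$fp, perf$tn), 2))

  surv <- survival_records
  surv$group <- unname(call_of[surv$tumor_id])
  km_ploidy <- km_logrank(surv, "polyploid", "near_diploid")

  surv_pub <- survival_records
  pub_of <- setNames(pub$pub_score, pub$tumor_id)
  surv_pub$group <- ifelse(pub_of[surv_pub$tumor_id] == 2, "PUB2", "PUB<2")
  km_pub <- km_logrank(surv_pub, "PUB2", "PUB<2")

  list(afp = afp, median_c = cmp_c, median_area = cmp_area,
       pub_vs_call = fisher, km_ploidy = km_ploidy, km_pub = km_pub,
       performance = perf)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> call-ploidy -> cytometry -> pub -> stats, writing every stage
#' table plus a run manifest (`manifest.json` with the config snapshot, seed,
#' package version and an MD5 hash of each output, so identical configs can
#' be verified to reproduce identical outputs).
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list: `paths` (named file paths), `summary` (ploidy call
#'   summary), `performance`, `stats` (full [cohort_stats_report()]).
#' @export
run_pipeline <- function(config = generator_config(), out_dir) {
  config <- validate_generator_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- run_stage("simulate", generate_cohort(config))
  paths <- run_stage("simulate", write_cohort_tables(cohort, out_dir))

  profiles <- run_stage("call-ploidy", call_cohort(cohort))
  paths[["tumor_profiles"]] <- file.path(out_dir, "tumor_profiles.csv")
  readr::write_csv(profiles, paths[["tumor_profiles"]], progress = FALSE)

  cyt <- run_stage("cytometry", cytometry_cohort(cohort))
  paths[["cytometry"]] <- file.path(out_dir, "cytometry.csv")
  readr::write_csv(cyt, paths[["cytometry"]], progress = FALSE)

  pub <- run_stage("pub", pub_table(pgcc_cohort(cohort), cohort$ihc))
  paths[["pub"]] <- file.path(out_dir, "pub.csv")
  readr::write_csv(pub, paths[["pub"]], progress = FALSE)
  perf <- run_stage("pub", evaluate_pub(pub, profiles))
  paths[["performance"]] <- file.path(out_dir, "performance.json")
  jsonlite::write_json(unclass(perf), paths[["performance"]],
                       auto_unbox = TRUE, digits = NA)

  stats_rep <- run_stage("stats", cohort_stats_report(
    cohort$clinical, cohort$survival, profiles, cyt, pub))
  paths[["stats_report"]] <- file.path(out_dir, "stats_report.json")
  jsonlite::write_json(list(
    afp = stats_rep$afp,
    median_c = stats_rep$median_c[c("metric", "statistic", "p_value",
                                    "alternative")],
    median_area = stats_rep$median_area[c("metric", "statistic", "p_value",
                                          "alternative")],
    pub_vs_call_fisher = stats_rep$pub_vs_call,
    km_ploidy = stats_rep$km_ploidy[c("chisq", "df", "p_value")],
    km_pub = stats_rep$km_pub[c("chisq", "df", "p_value")]
  ), paths[["stats_report"]], auto_unbox = TRUE, digits = NA)
  paths[["km_curves"]] <- file.path(out_dir, "km_curves.csv")
  readr::write_csv(dplyr::bind_rows(
    dplyr::mutate(stats_rep$km_ploidy$curves, stratification = "ploidy"),
    dplyr::mutate(stats_rep$km_pub$curves, stratification = "pub")),
    paths[["km_curves"]], progress = FALSE)

  manifest <- list(
    package = "hccploidy",
    version = as.character(utils::packageVersion("hccploidy")),
    seed = as.integer(config$seed),
    config = config[setdiff(names(config), "marker_conditionals")],
    marker_conditionals = lapply(config$marker_conditionals, as.list),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(tools::md5sum(unlist(paths)))
  )
  paths[["manifest"]] <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)

  invisible(list(paths = paths, summary = ploidy_call_summary(profiles),
                 performance = perf, stats = stats_rep))
}
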