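#' Flag polyploid giant cancer cells (PGCCs) in one tumor
#'
#' A PGCC is a tumor cell whose nucleus is at least `ratio` (default 3) times
#' larger in area than a regular cancer cell's nucleus; the "regular" baseline
#' is the median area over all tumor nuclei, which is robust as long as PGCCs
#' remain a minority. Density is PGCCs per examined 40x field (distinct
#' `field_id` values among tumor nuclei) and a tumor is PGCC-abundant when
#' one or more PGCC is seen per field on average
#' (`density >= density_threshold`).
#'
#' @param nuclei Nucleus tibble for a single tumor.
#' @param ratio Area ratio defining a PGCC (boundary inclusive).
#' @param density_threshold PGCCs per field at or above which the tumor is
#'   abundant.
#' @return One-row tibble: `tumor_id`, `baseline_area_um2`, `n_pgcc`,
#'   `n_fields`, `pgcc_density`, `pgcc_abundant`.
#' @examples
#' nuc <- tibble::tibble(tumor_id = "T1", field_id = 1,
#'                       area_um2 = c(rep(40, 9), 120), is_tumor = TRUE)
#' flag_pgccs(nuc)
#' @export
flag_pgccs <- function(nuclei, ratio = 3, density_threshold = 1) {
  tum <- nuclei[nuclei$is_tumor, , drop = FALSE]
  if (nrow(tum) == 0) {
    stop(structure(
      class = c("hccploidy_empty_tumor", "error", "condition"),
      list(message = sprintf("no tumor nuclei for tumor %s",
                             paste(unique(nuclei$tumor_id), collapse = ",")),
           call = NULL)))
  }
  baseline <- median(tum$area_um2)
  is_pgcc <- tum$area_um2 >= ratio * baseline
  n_fields <- length(unique(tum$field_id))
  density <- sum(is_pgcc) / n_fields
  tibble::tibble(
    tumor_id = unique(tum$tumor_id),
    baseline_area_um2 = baseline,
    n_pgcc = sum(is_pgcc),
    n_fields = n_fields,
    pgcc_density = density,
    pgcc_abundant = density >= density_threshold
  )
}

#' Per-tumor PGCC summaries over a cohort
#'
#' @param x An `hcc_cohort` or a nucleus tibble.
#' @inheritParams flag_pgccs
#' @return Tibble with one [flag_pgccs()] row per tumor.
#' @export
pgcc_cohort <- function(x, ratio = 3, density_threshold = 1) {
  nuclei <- if (inherits(x, "hcc_cohort")) x$nuclei else x
  parts <- split(nuclei, nuclei$tumor_id)
  dplyr::bind_rows(lapply(parts, flag_pgccs, ratio = ratio,
                          density_threshold = density_threshold))
}

#' Normalize a UBE2C immunostaining grade
#'
#' Grades enter as data (the staining-intensity rubric is a reading of the
#' slide, not a computation); this validates and canonicalizes them to
#' `negative`, `weak`, `moderate`, `strong` (case-insensitive, whitespace
#' trimmed).
#'
#' @param grade Character vector of grades.
#' @return Character vector of canonical grades.
#' @export
grade_ube2c <- function(grade) {
  g <- tolower(trimws(as.character(grade)))
  bad <- !(g %in% UBE2C_GRADES) | is.na(grade)
  if (any(bad)) {
    stop(structure(
      class = c("hccploidy_validation_error", "error", "condition"),
      list(message = sprintf(
        "unrecognized UBE2C grade(s): %s; allowed values are %s",
        paste(unique(grade[bad]), collapse = ", "),
        paste(UBE2C_GRADES, collapse = ", ")), call = NULL)))
  }
  g
}

#' PUB score: composite of PGCC abundance and UBE2C expression
#'
#' One point for PGCC abundance (one or more PGCC per 40x field) and one
#' point for moderate/strong UBE2C staining: score 0 means neither, 1 means
#' either, 2 means both.
#'
#' @param pgcc_abundant Logical vector.
#' @param ube2c_grade Grade vector (normalized via [grade_ube2c()]).
#' @return Integer vector of scores in {0, 1, 2}.
#' @examples
#' pub_score(TRUE, "moderate")   # 2
#' pub_score(FALSE, "weak")      # 0
#' @export
pub_score <- function(pgcc_abundant, ube2c_grade) {
  stopifnot(is.logical(pgcc_abundant), !any(is.na(pgcc_abundant)))
  g <- grade_ube2c(ube2c_grade)
  as.integer(pgcc_abundant) + as.integer(g %in% c("moderate", "strong"))
}

#' Per-tumor PUB results
#'
#' Joins PGCC summaries with the IHC grade table and scores each tumor.
#'
#' @param pgcc PGCC summary tibble ([pgcc_cohort()]).
#' @param ihc IHC tibble with `tumor_id` and `ube2c_grade`.
#' @return Tibble: `tumor_id`, `baseline_area_um2`, `pgcc_density`,
#'   `pgcc_abundant`, `ube2c_grade`, `pub_score`.
#' @export
pub_table <- function(pgcc, ihc) {
  check_same_tumors(pgcc$tumor_id, ihc$tumor_id, "pgcc", "ihc")
  out <- dplyr::inner_join(
    pgcc[, c("tumor_id", "baseline_area_um2", "pgcc_density", "pgcc_abundant")],
    ihc[, c("tumor_id", "ube2c_grade")], by = "tumor_id")
  out$ube2c_grade <- grade_ube2c(out$ube2c_grade)
  out$pub_score <- pub_score(out$pgcc_abundant, out$ube2c_grade)
  out
}

check_same_tumors <- function(a, b, name_a, name_b) {
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  if (length(only_a) || length(only_b)) {
    stop(structure(
      class = c("hccploidy_join_error", "error", "condition"),
      list(message = sprintf(
        "tumor_id sets differ: only in %s: {%s}; only in %s: {%s}",
        name_a, paste(only_a, collapse = ", "),
        name_b, paste(only_b, collapse = ", ")), call = NULL)))
  }
  invisible(TRUE)
}

#' Diagnostic performance of the PUB score against the ploidy call
#'
#' Cross-tabulates the positive rule (by default PUB score == 2) against the
#' FISH ploidy call and reports the contingency counts with sensitivity and
#' specificity, both exact and rounded to integer percent.
#'
#' @param pub PUB result tibble ([pub_table()]).
#' @param profiles Tumor profile tibble ([call_cohort()]).
#' @param positive_score Score at or above which the test is positive
#'   (default 2, i.e. score == 2 since 2 is the maximum).
#' @return List of class `diagnostic_performance`: `tp`, `fn`, `fp`, `tn`,
#'   `sensitivity`, `specificity` (percent), and rounded variants.
#' @export
evaluate_pub <- function(pub, profiles, positive_score = 2) {
  check_same_tumors(pub$tumor_id, profiles$tumor_id, "pub", "profiles")
  m <- dplyr::inner_join(pub[, c("tumor_id", "pub_score")],
                         profiles[, c("tumor_id", "call")], by = "tumor_id")
  test_pos <- m$pub_score >= positive_score
  truth_pos <- m$call == "polyploid"
  tp <- sum(test_pos & truth_pos)
  fn <- sum(!test_pos & truth_pos)
  fp <- sum(test_pos & !truth_pos)
  tn <- sum(!test_pos & !truth_pos)
  structure(list(
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    sensitivity_rounded = round(100 * tp / (tp + fn)),
    specificity_rounded = round(100 * tn / (tn + fp))
  ), class = "diagnostic_performance")
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  cat(sprintf(
    "<diagnostic_performance> tp=%d fn=%d fp=%d tn=%d | sensitivity %.1f%% specificity %.1f%% (rounded %d%%/%d%%)\n",
    x$tp, x$fn, x$fp, x$tn, x$sensitivity, x$specificity,
    x$sensitivity_rounded, x$specificity_rounded))
  invisible(x)
}
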