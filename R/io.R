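#' Table schemas used by the pipeline
#'
#' Column names, types and value domains for the delimited tables the
#' pipeline reads and writes: `nuclei`, `ihc`, `clinical`, `survival`,
#' `tumor_profiles`. All tables are comma-separated UTF-8 with a header row;
#' booleans are serialized as `true`/`false`; missing values are not allowed
#' in required columns.
#'
#' @return Named list of schema definitions.
#' @export
table_schemas <- function() {
  list(
    nuclei = list(
      required = c("tumor_id", "field_id", "nucleus_id",
                   "spots_chr7", "spots_chr11", "spots_chr16",
                   "area_um2", "dapi_integrated",
                   "hnf4a_pos", "ki67_pos", "is_tumor"),
      key = c("tumor_id", "nucleus_id"),
      checks = list(
        spots_chr7 = "count", spots_chr11 = "count", spots_chr16 = "count",
        area_um2 = "positive", dapi_integrated = "positive",
        hnf4a_pos = "logical", ki67_pos = "logical", is_tumor = "logical")
    ),
    ihc = list(
      required = c("tumor_id", "ube2c_grade", "aurka_grade", "top2a_grade",
                   "pgcc_per_field"),
      key = "tumor_id",
      checks = list(ube2c_grade = "grade", aurka_grade = "grade",
                    top2a_grade = "grade", pgcc_per_field = "nonnegative")
    ),
    clinical = list(
      required = c("tumor_id", "afp_ng_ml", "true_class"),
      key = "tumor_id",
      checks = list(afp_ng_ml = "positive", true_class = "class_label")
    ),
    survival = list(
      required = c("tumor_id", "time_years", "event"),
      key = "tumor_id",
      checks = list(time_years = "positive", event = "logical")
    ),
    tumor_profiles = list(
      required = c("tumor_id", "c7", "c11", "c16", "average_ploidy", "call",
                   "n_nuclei_used", "n_fields", "qc_pass"),
      key = "tumor_id",
      checks = list(c7 = "count_pos", c11 = "count_pos", c16 = "count_pos",
                    average_ploidy = "positive", call = "class_label",
                    n_nuclei_used = "count", n_fields = "count",
                    qc_pass = "logical")
    )
  )
}

check_domain <- function(x, kind) {
  switch(kind,
    count = is.na(x) | x < 0 | x != round(x),
    count_pos = is.na(x) | x < 1 | x != round(x),
    nonnegative = is.na(x) | x < 0,
    positive = is.na(x) | x <= 0,
    logical = is.na(x) | !(is.logical(x) | x %in% c(0, 1, TRUE, FALSE)),
    grade = is.na(x) | !(tolower(trimws(x)) %in% UBE2C_GRADES),
    class_label = is.na(x) | !(x %in% c("near_diploid", "polyploid")),
    stop("unknown domain kind: ", kind)
  )
}

domain_description <- function(kind) {
  switch(kind,
    count = "a non-negative integer",
    count_pos = "a positive integer",
    nonnegative = "a non-negative number",
    positive = "a positive number",
    logical = "a logical (true/false)",
    grade = paste0("one of ", paste(UBE2C_GRADES, collapse = ", ")),
    class_label = "one of near_diploid, polyploid"
  )
}

#' Validate a delimited table against a pipeline schema
#'
#' Enforces column presence, value domains (grades, flags, non-negative
#' integers, positive reals) and key uniqueness, collecting every violation
#' with its row number before failing.
#'
#' @param x A file path or a data frame.
#' @param schema Schema name (see [table_schemas()]).
#' @return The validated tibble (invisibly unchanged apart from reading).
#' @export
validate_table <- function(x, schema) {
  schemas <- table_schemas()
  if (!schema %in% names(schemas))
    stop("unknown schema '", schema, "'; available: ",
         paste(names(schemas), collapse = ", "))
  sc <- schemas[[schema]]
  df <- if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x)
    readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  } else tibble::as_tibble(x)

  errors <- character(0)
  missing_cols <- setdiff(sc$required, names(df))
  if (length(missing_cols))
    errors <- c(errors, sprintf("missing column(s): %s",
                                paste(missing_cols, collapse = ", ")))

  if (!length(missing_cols)) {
    for (col in names(sc$checks)) {
      bad <- which(check_domain(df[[col]], sc$checks[[col]]))
      for (r in utils::head(bad, 20))
        errors <- c(errors, sprintf("row %d: %s = %s is not %s", r, col,
                                    format(df[[col]][r]),
                                    domain_description(sc$checks[[col]])))
      if (length(bad) > 20)
        errors <- c(errors, sprintf("... and %d more %s violations",
                                    length(bad) - 20, col))
    }
    dup <- duplicated(df[, sc$key, drop = FALSE])
    for (r in utils::head(which(dup), 20))
      errors <- c(errors, sprintf("row %d: duplicate key (%s)", r,
                                  paste(unlist(df[r, sc$key]), collapse = ", ")))
  }

  if (length(errors)) {
    stop(structure(
      class = c("hccploidy_validation_error", "error", "condition"),
      list(message = sprintf("table '%s' failed validation:\n%s", schema,
                             paste("  -", errors, collapse = "\n")),
           call = NULL, errors = errors)))
  }
  df
}

#' Write the four cohort tables of a synthetic dataset
#'
#' Writes `nuclei.csv`, `ihc.csv`, `clinical.csv` and `survival.csv` under
#' `dir` (created if needed). The nuclei table keeps the generator-truth
#' `planted_pgcc` column; readers that only need the measurement schema can
#' ignore it.
#'
#' @param cohort An `hcc_cohort`.
#' @param dir Output directory.
#' @return Invisible named vector of file paths.
#' @export
write_cohort_tables <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(nuclei = file.path(dir, "nuclei.csv"),
             ihc = file.path(dir, "ihc.csv"),
             clinical = file.path(dir, "clinical.csv"),
             survival = file.path(dir, "survival.csv"))
  readr::write_csv(cohort$nuclei, paths[["nuclei"]], progress = FALSE)
  readr::write_csv(cohort$ihc, paths[["ihc"]], progress = FALSE)
  readr::write_csv(cohort$clinical, paths[["clinical"]], progress = FALSE)
  surv <- cohort$survival
  readr::write_csv(surv[, c("tumor_id", "time_years", "event")],
                   paths[["survival"]], progress = FALSE)
  invisible(paths)
}

#' Read and validate the cohort tables from a directory
#'
#' @param dir Directory holding `nuclei.csv`, `ihc.csv`, `clinical.csv`,
#'   `survival.csv`.
#' @return List of validated tibbles `nuclei`, `ihc`, `clinical`, `survival`.
#' @export
read_cohort_tables <- function(dir) {
  list(
    nuclei = validate_table(file.path(dir, "nuclei.csv"), "nuclei"),
    ihc = validate_table(file.path(dir, "ihc.csv"), "ihc"),
    clinical = validate_table(file.path(dir, "clinical.csv"), "clinical"),
    survival = validate_table(file.path(dir, "survival.csv"), "survival")
  )
}
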