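#' Predominant copy number for one chromosome probe
#'
#' The predominant copy number of a tumor for one probe is the modal non-zero
#' spot count over its tumor nuclei. Zero counts are excluded as
#' hybridization failures (whole-chromosome nullisomy is not a plausible
#' predominant state), and a tie between equally frequent counts is broken
#' toward the larger count: FFPE section truncation only removes signals, so
#' observed counts are biased downward and the larger tied value is the more
#' likely true copy number.
#'
#' @param nuclei Nucleus tibble (columns `spots_chr7/chr11/chr16`,
#'   `is_tumor`).
#' @param probe One of `"chr7"`, `"chr11"`, `"chr16"`.
#' @return Integer predominant copy number (>= 1).
#' @examples
#' nuc <- tibble::tibble(spots_chr7 = c(2, 2, 2, 2, 4), spots_chr11 = 2,
#'                       spots_chr16 = 2, is_tumor = TRUE)
#' predominant_copy_number(nuc, "chr7")
#' @export
predominant_copy_number <- function(nuclei, probe = c("chr7", "chr11", "chr16")) {
  probe <- match.arg(probe)
  counts <- nuclei[[paste0("spots_", probe)]][nuclei$is_tumor]
  counts <- counts[!is.na(counts) & counts > 0]
  if (length(counts) == 0) {
    stop(structure(
      class = c("hccploidy_uncallable_probe", "error", "condition"),
      list(message = sprintf(
        "probe %s has no non-zero spot counts in tumor nuclei; cannot call a predominant copy number",
        probe), call = NULL)))
  }
  tab <- table(counts)
  modal <- as.integer(names(tab)[tab == max(tab)])
  max(modal)  # tie -> larger count (undercount-bias rule)
}

#' Call the ploidy of one tumor from its nucleus table
#'
#' Computes the predominant copy-number triple over chromosomes 7, 11 and 16,
#' their average, and the ploidy call: polyploid when the average is at or
#' above `threshold` (2.5 copies by default, boundary inclusive). Tumors with
#' fewer informative nuclei than `min_nuclei` or fewer fields than
#' `min_fields` are still called but flagged `qc_pass = FALSE` with a
#' warning; the defaults mirror the study's evaluation minima (more than 200
#' tumor nuclei over 5 or more high-magnification fields).
#'
#' @param nuclei Nucleus tibble for a single tumor.
#' @param min_nuclei QC minimum number of tumor nuclei with at least one
#'   non-zero probe signal.
#' @param min_fields QC minimum number of distinct fields.
#' @param threshold Average-copy cutoff for the polyploid call.
#' @return One-row tibble: `tumor_id`, `c7`, `c11`, `c16`, `average_ploidy`,
#'   `call`, `n_nuclei_used`, `n_fields`, `qc_pass`.
#' @export
call_tumor <- function(nuclei, min_nuclei = 200, min_fields = 5,
                       threshold = 2.5) {
  if (nrow(nuclei) == 0) {
    stop(structure(
      class = c("hccploidy_uncallable_tumor", "error", "condition"),
      list(message = "empty nucleus table: nothing to call", call = NULL)))
  }
  ids <- unique(nuclei$tumor_id)
  if (length(ids) != 1)
    stop("call_tumor() expects nuclei from a single tumor; got: ",
         paste(ids, collapse = ", "))
  tum <- nuclei[nuclei$is_tumor, , drop = FALSE]

  triple <- tryCatch(
    vapply(PROBES, function(p) predominant_copy_number(nuclei, p), integer(1)),
    hccploidy_uncallable_probe = function(e) {
      stop(structure(
        class = c("hccploidy_uncallable_tumor", "error", "condition"),
        list(message = sprintf("tumor %s uncallable: %s", ids, conditionMessage(e)),
             call = NULL)))
    })

  spot_cols <- paste0("spots_", PROBES)
  informative <- rowSums(as.matrix(tum[, spot_cols]) > 0) > 0
  n_used <- sum(informative)
  n_fields <- length(unique(tum$field_id))
  qc <- n_used >= min_nuclei && n_fields >= min_fields
  if (!qc)
    warning(sprintf(
      "tumor %s below QC minima (%d informative nuclei, %d fields; need >= %d and >= %d)",
      ids, n_used, n_fields, min_nuclei, min_fields), call. = FALSE)

  avg <- mean(triple)
  tibble::tibble(
    tumor_id = ids,
    c7 = triple[["chr7"]], c11 = triple[["chr11"]], c16 = triple[["chr16"]],
    average_ploidy = avg,
    call = if (avg >= threshold) "polyploid" else "near_diploid",
    n_nuclei_used = n_used,
    n_fields = n_fields,
    qc_pass = qc
  )
}

#' Call ploidy for every tumor of a cohort
#'
#' @param x An `hcc_cohort` or a nucleus tibble covering several tumors.
#' @inheritParams call_tumor
#' @return Tibble of per-tumor profiles (one row per tumor, see
#'   [call_tumor()]), ordered by `tumor_id`.
#' @export
call_cohort <- function(x, min_nuclei = 200, min_fields = 5, threshold = 2.5) {
  nuclei <- if (inherits(x, "hcc_cohort")) x$nuclei else x
  parts <- split(nuclei, nuclei$tumor_id)
  dplyr::bind_rows(lapply(names(parts), function(id) {
    tryCatch(
      call_tumor(parts[[id]], min_nuclei = min_nuclei,
                 min_fields = min_fields, threshold = threshold),
      hccploidy_uncallable_tumor = function(e) {
        stop(structure(
          class = c("hccploidy_uncallable_tumor", "error", "condition"),
          list(message = sprintf("tumor %s: %s", id, conditionMessage(e)),
               call = NULL)))
      })
  }))
}

#' Summarize cohort-level ploidy calls
#'
#' @param profiles Output of [call_cohort()].
#' @return List: `n_tumors`, `n_polyploid`, `pct_polyploid` and
#'   `mean_ploidy_polyploid` (mean of `average_ploidy` over polyploid-called
#'   tumors).
#' @export
ploidy_call_summary <- function(profiles) {
  poly <- profiles$call == "polyploid"
  list(
    n_tumors = nrow(profiles),
    n_polyploid = sum(poly),
    pct_polyploid = 100 * mean(poly),
    mean_ploidy_polyploid = if (any(poly))
      mean(profiles$average_ploidy[poly]) else NA_real_
  )
}
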