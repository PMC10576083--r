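#' Gate nuclei for DNA-content cytometry
#'
#' Keeps HNF4a-positive / Ki-67-negative tumor nuclei, the image-cytometry
#' gate: HNF4a selects hepatocyte-lineage nuclei and Ki-67 excludes cycling
#' cells, whose S/G2/M DNA exceeds 2C and would be mistaken for polyploidy.
#' Row order is preserved.
#'
#' @param nuclei Nucleus tibble.
#' @return The gated subset.
#' @export
gate_nuclei <- function(nuclei) {
  out <- nuclei[nuclei$is_tumor & nuclei$hnf4a_pos & !nuclei$ki67_pos, ,
                drop = FALSE]
  if (nrow(out) == 0) {
    ids <- paste(unique(nuclei$tumor_id), collapse = ", ")
    stop(structure(
      class = c("hccploidy_empty_gate", "error", "condition"),
      list(message = sprintf(
        "no HNF4a+/Ki-67- tumor nuclei after gating (tumor %s)",
        if (nzchar(ids)) ids else "<none>"), call = NULL)))
  }
  out
}

# histogram mode of a numeric vector over fixed-width bins (log2 units).
# Bins are anchored at the sample median, not at zero, so a multiplicative
# gain (an additive shift in log space) moves the bin grid with the data and
# the estimated mode shifts by exactly that amount: c_value stays strictly
# gain-invariant. Ties go to the lowest bin.
histogram_mode <- function(x, bin_width = 0.05) {
  anchor <- median(x)
  b <- floor((x - anchor) / bin_width)
  tab <- table(b)
  b_mode <- as.numeric(names(tab)[which.max(tab)])
  anchor + (b_mode + 0.5) * bin_width
}

#' Normalize integrated DAPI intensity to DNA content (C-value)
#'
#' Integrated DAPI fluorescence is proportional to DNA content but carries an
#' arbitrary per-slide staining gain. The gain is estimated from a diploid
#' reference population (by default the non-tumor stromal/lymphocyte nuclei
#' of the same section) as the histogram mode of log2 intensity (bin width
#' 0.05 log2 units); each gated nucleus then gets
#' `c_value = 2 * dapi / mode(reference dapi)`, so the reference mode sits at
#' 2C. Nuclei are binned into ploidy classes at half-integer log2(C) edges:
#' below 1.5 -> ~2C, [1.5, 2.5) -> ~4C, [2.5, 3.5) -> ~8C, >= 3.5 -> >=8C.
#'
#' @param gated Gated tumor nuclei (see [gate_nuclei()]).
#' @param reference Diploid reference nuclei; at least 20 required.
#' @return An object of class `dna_index_profile`: list with `tumor_id`,
#'   `c_value` (per gated nucleus), `class_fractions` (named, sums to 1),
#'   `median_c`, `median_area`, `n_gated`, `n_reference`.
#' @export
normalize_dna_content <- function(gated, reference) {
  if (nrow(reference) < 20) {
    stop(structure(
      class = c("hccploidy_insufficient_reference", "error", "condition"),
      list(message = sprintf(
        "diploid reference has %d nuclei; at least 20 required for a stable intensity mode",
        nrow(reference)), call = NULL)))
  }
  ref_mode <- 2^histogram_mode(log2(reference$dapi_integrated))
  c_value <- 2 * gated$dapi_integrated / ref_mode

  lc <- log2(c_value)
  bins <- cut(lc, breaks = c(-Inf, 1.5, 2.5, 3.5, Inf),
              labels = c("2C", "4C", "8C", "ge8C"), right = FALSE)
  fr <- as.numeric(table(bins)) / length(lc)
  names(fr) <- c("2C", "4C", "8C", "ge8C")

  structure(list(
    tumor_id = unique(gated$tumor_id),
    c_value = c_value,
    class_fractions = fr,
    median_c = median(c_value),
    median_area = median(gated$area_um2),
    n_gated = nrow(gated),
    n_reference = nrow(reference)
  ), class = "dna_index_profile")
}

#' @export
print.dna_index_profile <- function(x, ...) {
  cat(sprintf(
    "<dna_index_profile> tumor %s: %d gated nuclei, median %.2fC, fractions 2C/4C/8C/>=8C = %s\n",
    paste(x$tumor_id, collapse = ","), x$n_gated, x$median_c,
    paste(sprintf("%.2f", x$class_fractions), collapse = "/")))
  invisible(x)
}

#' Per-tumor image cytometry over a cohort
#'
#' Gates each tumor's nuclei, normalizes DNA content against that tumor's
#' non-tumor nuclei, and tabulates medians and ploidy-class fractions.
#'
#' @param x An `hcc_cohort` or a nucleus tibble.
#' @return Tibble with one row per tumor: `tumor_id`, `n_gated`, `median_c`,
#'   `median_area_um2`, `frac_2c`, `frac_4c`, `frac_8c`, `frac_ge8c`.
#' @export
cytometry_cohort <- function(x) {
  nuclei <- if (inherits(x, "hcc_cohort")) x$nuclei else x
  parts <- split(nuclei, nuclei$tumor_id)
  dplyr::bind_rows(lapply(parts, function(nuc) {
    prof <- normalize_dna_content(gate_nuclei(nuc),
                                  nuc[!nuc$is_tumor, , drop = FALSE])
    tibble::tibble(
      tumor_id = prof$tumor_id,
      n_gated = prof$n_gated,
      median_c = prof$median_c,
      median_area_um2 = prof$median_area,
      frac_2c = prof$class_fractions[["2C"]],
      frac_4c = prof$class_fractions[["4C"]],
      frac_8c = prof$class_fractions[["8C"]],
      frac_ge8c = prof$class_fractions[["ge8C"]]
    )
  }))
}

#' Compare a cytometric metric between two tumor groups
#'
#' One-sided Mann-Whitney comparison of a per-tumor metric (median DNA
#' content or median nuclear area) between two groups of tumors, with the
#' alternative that group A exceeds group B (e.g. polyploid > near-diploid).
#'
#' @param profiles_a,profiles_b Cytometry tibbles ([cytometry_cohort()] rows)
#'   for the two groups.
#' @param metric `"median_c"` or `"median_area"`.
#' @param alternative Direction of the alternative for group A vs group B.
#' @return List: `metric`, per-group value vectors `a` and `b`, `statistic`
#'   (Mann-Whitney U for group A), `p_value`, `alternative`.
#' @export
compare_groups <- function(profiles_a, profiles_b,
                           metric = c("median_c", "median_area"),
                           alternative = c("greater", "less")) {
  metric <- match.arg(metric)
  alternative <- match.arg(alternative)
  col <- if (metric == "median_area") "median_area_um2" else metric
  if (nrow(profiles_a) == 0 || nrow(profiles_b) == 0) {
    stop(structure(
      class = c("hccploidy_empty_group", "error", "condition"),
      list(message = "both comparison groups must be non-empty", call = NULL)))
  }
  a <- profiles_a[[col]]
  b <- profiles_b[[col]]
  res <- mann_whitney_one_sided(a, b, alternative = alternative)
  list(metric = metric, a = a, b = b, statistic = res$statistic,
       p_value = res$p_value, alternative = alternative)
}
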