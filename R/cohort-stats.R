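#' One-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with an explicit direction. The exact
#' null distribution is used when the combined sample size is 20 or less and
#' there are no ties; otherwise the normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param x,y Numeric vectors.
#' @param alternative `"greater"` (x tends larger than y) or `"less"`.
#' @return List: `statistic` (Mann-Whitney U for `x`), `p_value`,
#'   `alternative`, `exact` (whether the exact distribution was used),
#'   `n_x`, `n_y`.
#' @examples
#' mann_whitney_one_sided(c(1, 2, 3), c(4, 5, 6), "less")$p_value  # 0.05
#' @export
mann_whitney_one_sided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0)
    stop(structure(
      class = c("hccploidy_input_error", "error", "condition"),
      list(message = "both samples must be non-empty", call = NULL)))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       alternative = alternative, exact = exact,
       n_x = length(x), n_y = length(y))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing the hypergeometric probabilities of all
#' tables (fixed margins) no more probable than the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List: `p_value`, `odds_ratio` (conditional MLE).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop(structure(
      class = c("hccploidy_input_error", "error", "condition"),
      list(message = "expected a 2x2 table of non-negative integer counts",
           call = NULL)))
  ht <- fisher.test(tab)
  list(p_value = ht$p.value, odds_ratio = unname(ht$estimate))
}

#' Pearson chi-square test for an r x k contingency table
#'
#' No continuity correction by default. A zero expected cell is an error (the
#' asymptotic distribution breaks down); Fisher's exact test is suggested
#' instead.
#'
#' @param tab Contingency table (matrix of non-negative counts).
#' @param correct Apply Yates continuity correction (2x2 only).
#' @return List: `statistic`, `df`, `p_value`.
#' @export
chi_square_2xk <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0))
    stop(structure(
      class = c("hccploidy_input_error", "error", "condition"),
      list(message = "counts must be non-negative", call = NULL)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop(structure(
      class = c("hccploidy_input_error", "error", "condition"),
      list(message = "zero expected count; use fisher_exact_2x2() for sparse tables",
           call = NULL)))
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival estimates with right censoring for each group and
#' the two-sided log-rank test between them.
#'
#' @param records Tibble with columns `time_years`, `event` (logical) and
#'   `group`.
#' @param group_a,group_b The two group labels to compare.
#' @return List: `curves` (tibble `group`, `time`, `survival`, `at_risk`,
#'   including the `time = 0, survival = 1` anchor per group), `chisq`, `df`,
#'   `p_value`.
#' @export
km_logrank <- function(records, group_a, group_b) {
  for (g in c(group_a, group_b)) {
    if (!any(records$group == g))
      stop(structure(
        class = c("hccploidy_empty_group", "error", "condition"),
        list(message = sprintf("group '%s' has no records", g), call = NULL)))
  }
  rec <- records[records$group %in% c(group_a, group_b), , drop = FALSE]
  if (!any(rec$event))
    stop(structure(
      class = c("hccploidy_input_error", "error", "condition"),
      list(message = "no events observed; log-rank test undefined", call = NULL)))
  grp <- factor(rec$group, levels = c(group_a, group_b))
  fit <- survival::survfit(survival::Surv(rec$time_years, rec$event) ~ grp)
  sm <- summary(fit, censored = FALSE)
  strata <- if (is.null(sm$strata)) rep(group_a, length(sm$time)) else
    sub("^grp=", "", as.character(sm$strata))
  curves <- dplyr::bind_rows(
    tibble::tibble(group = c(group_a, group_b), time = 0, survival = 1,
                   at_risk = as.numeric(table(grp)[c(group_a, group_b)])),
    tibble::tibble(group = strata, time = sm$time, survival = sm$surv,
                   at_risk = sm$n.risk))
  curves <- dplyr::arrange(curves, .data$group, .data$time)
  sd <- survival::survdiff(survival::Surv(rec$time_years, rec$event) ~ grp)
  chisq <- unname(sd$chisq)
  list(curves = curves, chisq = chisq, df = 1,
       p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Hypergeometric gene-list overlap test
#'
#' Upper-tail probability that two gene lists of sizes `n_a` and `n_b` drawn
#' from a universe of `n_universe` genes share `k` or more members,
#' `P(X >= k)` with `X ~ Hypergeometric`. Computed in log space so extreme
#' overlaps (p below 1e-300) keep a finite log10 p-value.
#'
#' @param k Observed overlap.
#' @param n_a,n_b Sizes of the two lists.
#' @param n_universe Size of the gene universe (default 20000).
#' @return List: `p_value` (may underflow to 0 for astronomical overlaps),
#'   `log10_p` (always finite), `k`, `n_a`, `n_b`, `n_universe`, `expected`
#'   (expected overlap under the null).
#' @examples
#' hypergeom_overlap(5, 5, 5, 10)$p_value  # 1/choose(10, 5)
#' @export
hypergeom_overlap <- function(k, n_a, n_b, n_universe = 20000) {
  ok <- all(c(k, n_a, n_b, n_universe) >= 0) && n_a <= n_universe &&
    n_b <= n_universe && k <= min(n_a, n_b)
  if (!ok)
    stop(structure(
      class = c("hccploidy_input_error", "error", "condition"),
      list(message = "require 0 <= k <= min(n_a, n_b) <= n_universe",
           call = NULL)))
  log_p <- phyper(k - 1, m = n_a, n = n_universe - n_a, k = n_b,
                  lower.tail = FALSE, log.p = TRUE)
  list(p_value = exp(log_p), log10_p = log_p / log(10),
       k = k, n_a = n_a, n_b = n_b, n_universe = n_universe,
       expected = n_a * n_b / n_universe)
}
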