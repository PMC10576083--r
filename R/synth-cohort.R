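#' @importFrom stats rbinom rpois rexp runif rlnorm rnorm median chisq.test
#'   fisher.test wilcox.test pchisq phyper setNames
#' @importFrom rlang .data
NULL

# lognormal noise with mean 1 and the requested coefficient of variation
rlnorm_cv <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# deterministic 31-bit sub-stream seed keyed by (cohort seed, tumor_id), so
# nuclei tables are reproducible even if tumors are generated in another order
tumor_substream_seed <- function(seed, tumor_id) {
  h <- 0
  for (ch in utf8ToInt(as.character(tumor_id)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483647 + 1)
}

PROBES <- c("chr7", "chr11", "chr16")
UBE2C_GRADES <- c("negative", "weak", "moderate", "strong")
MARKER_CATEGORIES <- c("both", "abundant_only", "ube2c_only", "neither")

#' Generate a synthetic HCC cohort
#'
#' Draws tumor-level ground truth (ploidy class, predominant copy-number
#' triple for chromosomes 7/11/16, PGCC rate, UBE2C grade, serum AFP, death
#' hazard), then per-nucleus FISH spot counts with FFPE noise, nuclear
#' morphometry proportional to DNA content, IHC grades, and right-censored
#' survival. Everything is derived from `config$seed`; per-tumor nucleus
#' tables use sub-streams keyed by tumor id.
#'
#' @param config A [generator_config()].
#' @return An object of class `hcc_cohort`: a list with tibbles `truths`,
#'   `nuclei`, `ihc`, `clinical`, `survival`, plus the `config`.
#' @examples
#' cohort <- generate_cohort(generator_config(n_tumors = 6, seed = 7,
#'                                            nuclei_per_tumor = 60))
#' table(cohort$truths$true_class)
#' @export
generate_cohort <- function(config = generator_config()) {
  config <- validate_generator_config(config)
  set.seed(config$seed)

  truths <- generate_tumor_truths(config)
  truths <- assign_marker_profiles(truths, config)

  n <- nrow(truths)
  poly <- truths$true_class == "polyploid"
  truths$afp <- rlnorm(
    n,
    meanlog = log(ifelse(poly, config$afp_median_polyploid,
                         config$afp_median_neardiploid)),
    sdlog = config$afp_sigma_log
  )
  truths$hazard <- config$hazard_neardiploid *
    ifelse(poly, config$hazard_ratio_polyploid, 1)

  surv <- generate_survival(truths, config)

  nuclei <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    generate_tumor_nuclei(truths[i, ], config,
                          seed = tumor_substream_seed(config$seed,
                                                      truths$tumor_id[i]))
  }))

  ihc <- tibble::tibble(
    tumor_id = truths$tumor_id,
    ube2c_grade = truths$ube2c_grade_true,
    aurka_grade = truths$aurka_grade_true,
    top2a_grade = truths$top2a_grade_true,
    pgcc_per_field = truths$pgcc_rate
  )
  clinical <- tibble::tibble(
    tumor_id = truths$tumor_id,
    afp_ng_ml = truths$afp,
    true_class = truths$true_class
  )

  structure(list(truths = truths, nuclei = nuclei, ihc = ihc,
                 clinical = clinical, survival = surv, config = config),
            class = "hcc_cohort")
}

#' @export
print.hcc_cohort <- function(x, ...) {
  cat(sprintf("<hcc_cohort> %d tumors (%d polyploid), %d nuclei, seed %d\n",
              nrow(x$truths),
              sum(x$truths$true_class == "polyploid"),
              nrow(x$nuclei), as.integer(x$config$seed)))
  invisible(x)
}

# tumor ids, ploidy classes and true copy-number triples
generate_tumor_truths <- function(config) {
  n <- config$n_tumors
  tumor_id <- sprintf("T%03d", seq_len(n))

  if (config$truth_mode == "stratified") {
    n_poly <- round(n * config$prevalence_polyploid)
    cls <- rep("near_diploid", n)
    if (n > 0 && n_poly > 0) cls[sample.int(n, n_poly)] <- "polyploid"
  } else {
    cls <- ifelse(runif(n) < config$prevalence_polyploid,
                  "polyploid", "near_diploid")
  }

  copies <- matrix(2L, nrow = n, ncol = 3,
                   dimnames = list(NULL, paste0("copies_", PROBES)))
  for (i in seq_len(n)) {
    if (cls[i] == "polyploid") {
      copies[i, ] <- 3L + rbinom(3, 1, config$p_tetrasomy_polyploid)
    } else if (runif(1) < config$p_trisomy_neardiploid) {
      copies[i, sample.int(3, 1)] <- 3L
    }
  }

  tibble::tibble(
    tumor_id = tumor_id,
    true_class = cls,
    copies_chr7 = copies[, 1],
    copies_chr11 = copies[, 2],
    copies_chr16 = copies[, 3],
    true_ploidy = rowMeans(copies)
  )
}

# largest-remainder rounding of n * p to integer category counts summing to n
stratified_counts <- function(n, p) {
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

#' Assign per-tumor marker profiles (UBE2C/AURKA/TOP2A grades, PGCC category)
#'
#' In `stratified` mode the four marker categories (`both`, `abundant_only`,
#' `ube2c_only`, `neither`) are allocated within each ploidy class in exact
#' largest-remainder proportion to `config$marker_conditionals`, then shuffled
#' across tumors of the class; at the default class sizes this reproduces the
#' study-mirror PUB=2 contingency table 15/5/3/33 exactly. In `stochastic`
#' mode each tumor samples its category independently.
#'
#' @param truths Tumor truth tibble from the generator.
#' @param config A [generator_config()].
#' @return `truths` with columns `marker_category`, `pgcc_abundant_true`,
#'   `pgcc_rate`, `ube2c_grade_true`, `aurka_grade_true`, `top2a_grade_true`.
#' @export
assign_marker_profiles <- function(truths, config) {
  n <- nrow(truths)
  category <- character(n)
  for (cls in c("polyploid", "near_diploid")) {
    idx <- which(truths$true_class == cls)
    if (length(idx) == 0) next
    p <- config$marker_conditionals[[cls]][MARKER_CATEGORIES]
    if (config$truth_mode == "stratified") {
      counts <- stratified_counts(length(idx), p)
      cats <- rep(MARKER_CATEGORIES, counts)
      category[idx] <- cats[sample.int(length(idx))]
    } else {
      category[idx] <- sample(MARKER_CATEGORIES, length(idx),
                              replace = TRUE, prob = p)
    }
  }
  abundant <- category %in% c("both", "abundant_only")
  ube2c_high <- category %in% c("both", "ube2c_only")

  truths$marker_category <- category
  truths$pgcc_abundant_true <- abundant
  truths$pgcc_rate <- ifelse(abundant, config$pgcc_rate_polyploid,
                             config$pgcc_rate_neardiploid)
  truths$ube2c_grade_true <- ifelse(ube2c_high,
                                    sample(c("moderate", "strong"), n, TRUE),
                                    sample(c("negative", "weak"), n, TRUE))
  poly <- truths$true_class == "polyploid"
  truths$aurka_grade_true <- ifelse(
    poly,
    sample(UBE2C_GRADES, n, TRUE, prob = c(0.05, 0.15, 0.45, 0.35)),
    sample(UBE2C_GRADES, n, TRUE, prob = c(0.35, 0.40, 0.20, 0.05)))
  truths$top2a_grade_true <- sample(UBE2C_GRADES, n, TRUE,
                                    prob = c(0.25, 0.35, 0.30, 0.10))
  truths
}

#' Generate the per-nucleus table for one tumor
#'
#' Produces regular tumor nuclei, planted PGCC nuclei and diploid non-tumor
#' nuclei. Observed spot counts thin the true copy number by the FFPE
#' per-signal dropout (`Binomial(copy, 1 - signal_dropout)`) and whole-nucleus
#' hybridization failures zero all three probes. DNA content `C` (in C-value
#' units; a diploid (2,2,2) nucleus is 2C) drives integrated DAPI intensity
#' (`gain * C` with lognormal CV `dapi_cv` and a per-tumor staining gain) and
#' nuclear area (`40 um^2 * (C/2)^(2/3)` with lognormal CV `area_cv`). Ki-67
#' positive (cycling) nuclei carry 1-2x extra DNA. PGCC nuclei are planted per
#' field: deterministically (`ceiling(pgcc_rate)`, all 32C, so the assigned
#' abundance category is noise-proof) when the cohort is stratified, else
#' `Poisson(pgcc_rate)` with C drawn from {8, 16, 32}.
#'
#' @param truth One row of the truth tibble.
#' @param config A [generator_config()].
#' @param seed Optional sub-stream seed; `NULL` continues the current stream.
#' @return Tibble of nuclei (one row each) with a generator-truth
#'   `planted_pgcc` column.
#' @export
generate_tumor_nuclei <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  copies <- c(truth$copies_chr7, truth$copies_chr11, truth$copies_chr16)
  c_base <- mean(copies)
  n_fields <- config$fields_per_tumor
  gain <- 50 * rlnorm_cv(1, config$gain_cv)

  n_t <- config$nuclei_per_tumor
  n_nt <- round(config$nontumor_fraction / (1 - config$nontumor_fraction) * n_t)

  # planted PGCCs per field
  if (config$truth_mode == "stratified") {
    per_field <- rep(if (isTRUE(truth$pgcc_abundant_true))
      ceiling(truth$pgcc_rate) else 0L, n_fields)
    # 32C giants sit at >= 4x the baseline area even for tetraploid clones,
    # so the assigned abundance category survives morphometric noise
    pg_c <- rep(32, sum(per_field))
  } else {
    per_field <- rpois(n_fields, truth$pgcc_rate)
    pg_c <- sample(c(8, 16, 32), sum(per_field), replace = TRUE,
                   prob = c(0.2, 0.4, 0.4))
  }
  n_pg <- sum(per_field)

  n_all <- n_t + n_pg + n_nt
  is_tumor <- c(rep(TRUE, n_t + n_pg), rep(FALSE, n_nt))
  planted_pgcc <- c(rep(FALSE, n_t), rep(TRUE, n_pg), rep(FALSE, n_nt))

  field_id <- integer(n_all)
  field_id[seq_len(n_t)] <- sample(rep_len(seq_len(n_fields), n_t))
  if (n_pg > 0) field_id[n_t + seq_len(n_pg)] <- rep(seq_len(n_fields), per_field)
  if (n_nt > 0) field_id[n_t + n_pg + seq_len(n_nt)] <-
    sample(rep_len(seq_len(n_fields), n_nt))

  # true per-probe copy numbers per nucleus
  true_counts <- matrix(2L, nrow = n_all, ncol = 3)
  true_counts[seq_len(n_t), ] <- matrix(copies, n_t, 3, byrow = TRUE)
  if (n_pg > 0)
    true_counts[n_t + seq_len(n_pg), ] <-
      t(vapply(pg_c, function(cc) as.integer(round(copies * cc / c_base)),
               integer(3)))

  # marker flags
  hnf4a_pos <- logical(n_all)
  hnf4a_pos[seq_len(n_t + n_pg)] <-
    rbinom(n_t + n_pg, 1, config$hnf4a_rate_tumor) == 1
  ki67_pos <- logical(n_all)
  ki67_pos[seq_len(n_t)] <- rbinom(n_t, 1, config$ki67_rate_tumor) == 1
  if (n_nt > 0) ki67_pos[n_t + n_pg + seq_len(n_nt)] <-
    rbinom(n_nt, 1, config$ki67_rate_nontumor) == 1

  # DNA content in C units: regular tumor nuclei at the clone mean copy
  # number, PGCCs at their planted C, non-tumor nuclei diploid; cycling
  # (Ki-67+) nuclei carry 1-2x extra DNA
  c_value <- c(rep(c_base, n_t), pg_c, rep(2, n_nt))
  boost <- ifelse(ki67_pos & !planted_pgcc, runif(n_all, 1, 2), 1)
  c_value <- c_value * boost

  dapi <- gain * c_value * rlnorm_cv(n_all, config$dapi_cv)
  area <- 40 * (c_value / 2)^(2 / 3) * rlnorm_cv(n_all, config$area_cv)

  # FFPE noise on observed spots
  observed <- matrix(0L, n_all, 3)
  for (j in 1:3)
    observed[, j] <- rbinom(n_all, true_counts[, j], 1 - config$signal_dropout)
  failed <- runif(n_all) < config$hyb_failure
  observed[failed, ] <- 0L

  tibble::tibble(
    tumor_id = truth$tumor_id,
    field_id = field_id,
    nucleus_id = sprintf("%s_n%04d", truth$tumor_id, seq_len(n_all)),
    spots_chr7 = observed[, 1],
    spots_chr11 = observed[, 2],
    spots_chr16 = observed[, 3],
    area_um2 = area,
    dapi_integrated = dapi,
    hnf4a_pos = hnf4a_pos,
    ki67_pos = ki67_pos,
    is_tumor = is_tumor,
    planted_pgcc = planted_pgcc
  )
}

#' Generate right-censored survival records
#'
#' Event times are exponential with each tumor's hazard; censoring times are
#' uniform over `config$censor_window`; the observed time is the minimum with
#' the corresponding event flag.
#'
#' @param truths Truth tibble carrying a `hazard` column (events/year).
#' @param config A [generator_config()].
#' @param seed Optional seed; `NULL` continues the current stream.
#' @return Tibble with `tumor_id`, `time_years`, `event`, `group`.
#' @export
generate_survival <- function(truths, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truths)
  t_event <- rexp(n, rate = truths$hazard)
  t_cens <- runif(n, config$censor_window[1], config$censor_window[2])
  tibble::tibble(
    tumor_id = truths$tumor_id,
    time_years = pmin(t_event, t_cens),
    event = t_event <= t_cens,
    group = truths$true_class
  )
}
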