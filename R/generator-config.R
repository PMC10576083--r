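#' Configuration for the synthetic HCC cohort generator
#'
#' Bundles every parameter of the synthetic-cohort generator with validation.
#' The defaults reproduce the structure of the study cohort the package is
#' calibrated to: 56 surgically resected HCCs of which 20 are polyploid
#' (prevalence 20/56 = 35.7%), more than 200 tumor nuclei scored per tumor
#' over 6 high-magnification fields, FFPE FISH signal dropout of 10% per
#' signal, and marker conditionals whose stratified allocation yields the
#' study-mirror PUB-score contingency table (15/5/3/33).
#'
#' @param n_tumors Number of tumors in the cohort.
#' @param prevalence_polyploid Fraction of tumors that are truly polyploid.
#' @param truth_mode `"stratified"` fixes the polyploid count at
#'   `round(n_tumors * prevalence_polyploid)` and allocates marker categories
#'   deterministically; `"stochastic"` samples both per tumor.
#' @param nuclei_per_tumor Number of regular tumor nuclei scored per tumor.
#'   Non-tumor (stromal/lymphocyte) nuclei and planted PGCCs are added on top.
#' @param fields_per_tumor Number of 40x fields examined per tumor.
#' @param nontumor_fraction Fraction of the recorded nuclei that are
#'   non-tumor; these diploid nuclei serve as the DNA-index reference.
#' @param signal_dropout Per-signal loss probability from FFPE section
#'   truncation (a spot of a truly `c`-copy nucleus is observed
#'   `Binomial(c, 1 - signal_dropout)`).
#' @param hyb_failure Probability that a nucleus fails hybridization entirely
#'   (all three probes read 0).
#' @param p_tetrasomy_polyploid Probability that a polyploid tumor's
#'   chromosome has predominant copy number 4 rather than 3. The default
#'   0.14 gives an expected average ploidy of 3.14 among polyploid tumors.
#' @param p_trisomy_neardiploid Probability that a near-diploid tumor carries
#'   a single trisomic chromosome (average at most 7/3, below the 2.5 cutoff).
#' @param pgcc_rate_polyploid,pgcc_rate_neardiploid Expected PGCCs per 40x
#'   field for PGCC-abundant and non-abundant tumors respectively.
#' @param marker_conditionals Per-class joint probabilities of the four
#'   marker categories `both` (PGCC-abundant and UBE2C moderate/strong),
#'   `abundant_only`, `ube2c_only`, `neither`. Each class entry must sum
#'   to 1. The defaults make the stratified study-mirror allocation exact:
#'   15/20 polyploid and 3/36 near-diploid tumors are `both`.
#' @param afp_median_neardiploid,afp_median_polyploid Median serum AFP
#'   (ng/mL) per class.
#' @param afp_sigma_log Log-scale standard deviation of the lognormal AFP
#'   distribution.
#' @param hazard_neardiploid Baseline death hazard (events/year) for
#'   near-diploid tumors.
#' @param hazard_ratio_polyploid Hazard ratio of polyploid vs near-diploid.
#' @param censor_window Two-element range (years) of the uniform
#'   administrative censoring time.
#' @param hnf4a_rate_tumor Probability a tumor nucleus stains HNF4a-positive.
#' @param ki67_rate_tumor,ki67_rate_nontumor Probability of Ki-67 positivity
#'   (cycling cells, whose DNA content is inflated by up to 2x).
#' @param dapi_cv,area_cv Coefficients of variation of the lognormal
#'   measurement noise on integrated DAPI intensity and nuclear area.
#' @param gain_cv Coefficient of variation of the per-tumor DAPI staining
#'   gain (forces the DNA-index normalization to be nontrivial).
#' @param seed Integer seed; every draw of the generator is derived from it.
#'
#' @return An object of class `generator_config` (a validated named list).
#' @examples
#' cfg <- generator_config(n_tumors = 8, nuclei_per_tumor = 50, seed = 1)
#' cfg$prevalence_polyploid
#' @export
generator_config <- function(n_tumors = 56,
                             prevalence_polyploid = 20 / 56,
                             truth_mode = c("stratified", "stochastic"),
                             nuclei_per_tumor = 250,
                             fields_per_tumor = 6,
                             nontumor_fraction = 0.2,
                             signal_dropout = 0.10,
                             hyb_failure = 0.05,
                             p_tetrasomy_polyploid = 0.14,
                             p_trisomy_neardiploid = 0.3,
                             pgcc_rate_polyploid = 2.0,
                             pgcc_rate_neardiploid = 0.1,
                             marker_conditionals = default_marker_conditionals(),
                             afp_median_neardiploid = 9.8,
                             afp_median_polyploid = 193,
                             afp_sigma_log = 2.0,
                             hazard_neardiploid = 0.08,
                             hazard_ratio_polyploid = 3.5,
                             censor_window = c(0.5, 5.0),
                             hnf4a_rate_tumor = 0.95,
                             ki67_rate_tumor = 0.10,
                             ki67_rate_nontumor = 0.02,
                             dapi_cv = 0.10,
                             area_cv = 0.15,
                             gain_cv = 0.30,
                             seed = 1L) {
  truth_mode <- match.arg(truth_mode)
  cfg <- list(
    n_tumors = n_tumors,
    prevalence_polyploid = prevalence_polyploid,
    truth_mode = truth_mode,
    nuclei_per_tumor = nuclei_per_tumor,
    fields_per_tumor = fields_per_tumor,
    nontumor_fraction = nontumor_fraction,
    signal_dropout = signal_dropout,
    hyb_failure = hyb_failure,
    p_tetrasomy_polyploid = p_tetrasomy_polyploid,
    p_trisomy_neardiploid = p_trisomy_neardiploid,
    pgcc_rate_polyploid = pgcc_rate_polyploid,
    pgcc_rate_neardiploid = pgcc_rate_neardiploid,
    marker_conditionals = marker_conditionals,
    afp_median_neardiploid = afp_median_neardiploid,
    afp_median_polyploid = afp_median_polyploid,
    afp_sigma_log = afp_sigma_log,
    hazard_neardiploid = hazard_neardiploid,
    hazard_ratio_polyploid = hazard_ratio_polyploid,
    censor_window = censor_window,
    hnf4a_rate_tumor = hnf4a_rate_tumor,
    ki67_rate_tumor = ki67_rate_tumor,
    ki67_rate_nontumor = ki67_rate_nontumor,
    dapi_cv = dapi_cv,
    area_cv = area_cv,
    gain_cv = gain_cv,
    seed = seed
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

#' Default joint marker conditionals
#'
#' Probabilities of the four marker categories given true ploidy class.
#' Under stratified allocation at the default class sizes (20 polyploid,
#' 36 near-diploid) these fractions land on integers and reproduce the
#' study-mirror PUB=2 contingency table: 15 of 20 polyploid and 3 of 36
#' near-diploid tumors are both PGCC-abundant and UBE2C-moderate/strong
#' (sensitivity 75%, specificity 33/36 = 91.7%, printed as 92%).
#'
#' @return Named list with `polyploid` and `near_diploid` probability vectors
#'   over categories `both`, `abundant_only`, `ube2c_only`, `neither`.
#' @export
default_marker_conditionals <- function() {
  list(
    polyploid    = c(both = 15 / 20, abundant_only = 0, ube2c_only = 5 / 20,
                     neither = 0),
    near_diploid = c(both = 3 / 36, abundant_only = 0, ube2c_only = 6 / 36,
                     neither = 27 / 36)
  )
}

config_error <- function(field, msg) {
  stop(structure(
    class = c("hccploidy_config_error", "error", "condition"),
    list(message = sprintf("invalid generator_config field '%s': %s", field, msg),
         call = NULL, field = field)
  ))
}

check_fraction <- function(cfg, field) {
  x <- cfg[[field]]
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    config_error(field, "must be a single number in [0, 1]")
}

check_count <- function(cfg, field, min = 1) {
  x <- cfg[[field]]
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    config_error(field, sprintf("must be a single integer >= %d", min))
}

check_positive <- function(cfg, field) {
  x <- cfg[[field]]
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    config_error(field, "must be a single positive number")
}

#' @rdname generator_config
#' @param cfg A `generator_config` object to validate.
#' @export
validate_generator_config <- function(cfg) {
  if (!inherits(cfg, "generator_config"))
    stop("expected a 'generator_config' object")
  check_count(cfg, "n_tumors", min = 1)
  for (f in c("prevalence_polyploid", "nontumor_fraction", "signal_dropout",
              "hyb_failure", "p_tetrasomy_polyploid", "p_trisomy_neardiploid",
              "hnf4a_rate_tumor", "ki67_rate_tumor", "ki67_rate_nontumor"))
    check_fraction(cfg, f)
  check_count(cfg, "nuclei_per_tumor")
  check_count(cfg, "fields_per_tumor")
  for (f in c("afp_median_neardiploid", "afp_median_polyploid",
              "afp_sigma_log", "hazard_neardiploid", "hazard_ratio_polyploid",
              "dapi_cv", "area_cv", "gain_cv"))
    check_positive(cfg, f)
  if (cfg$pgcc_rate_polyploid < 0) config_error("pgcc_rate_polyploid", "must be >= 0")
  if (cfg$pgcc_rate_neardiploid < 0) config_error("pgcc_rate_neardiploid", "must be >= 0")
  cw <- cfg$censor_window
  if (!is.numeric(cw) || length(cw) != 2L || any(is.na(cw)) || cw[1] <= 0 ||
      cw[2] < cw[1])
    config_error("censor_window", "must be an increasing positive range c(lo, hi)")
  mc <- cfg$marker_conditionals
  cats <- c("both", "abundant_only", "ube2c_only", "neither")
  if (!is.list(mc) || !all(c("polyploid", "near_diploid") %in% names(mc)))
    config_error("marker_conditionals", "must list 'polyploid' and 'near_diploid'")
  for (cls in c("polyploid", "near_diploid")) {
    p <- mc[[cls]]
    if (!is.numeric(p) || !all(cats %in% names(p)))
      config_error("marker_conditionals",
                   sprintf("'%s' must name categories %s", cls,
                           paste(cats, collapse = ", ")))
    if (any(p < 0) || any(p > 1))
      config_error("marker_conditionals", "probabilities must lie in [0, 1]")
    if (abs(sum(p[cats]) - 1) > 1e-9)
      config_error("marker_conditionals",
                   sprintf("'%s' probabilities must sum to 1", cls))
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed) ||
      cfg$seed != round(cfg$seed))
    config_error("seed", "must be a single integer")
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  n_poly <- round(x$n_tumors * x$prevalence_polyploid)
  cat(sprintf(
    "<generator_config> %d tumors (%s; ~%d polyploid), %d nuclei/tumor, %d fields, seed %d\n",
    x$n_tumors, x$truth_mode, n_poly, x$nuclei_per_tumor,
    x$fields_per_tumor, as.integer(x$seed)))
  invisible(x)
}
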