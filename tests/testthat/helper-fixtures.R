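# Small nucleus-table builder for hand-made fixtures. Defaults give a
# well-formed diploid tumor nucleus; any field can be overridden with a
# vector, which is recycled to the longest input.
make_nuclei <- function(n = NULL, tumor_id = "T001", field_id = 1L,
                        spots_chr7 = 2L, spots_chr11 = 2L, spots_chr16 = 2L,
                        area_um2 = 40, dapi_integrated = 100,
                        hnf4a_pos = TRUE, ki67_pos = FALSE, is_tumor = TRUE) {
  args <- list(tumor_id = tumor_id, field_id = field_id,
               spots_chr7 = spots_chr7, spots_chr11 = spots_chr11,
               spots_chr16 = spots_chr16, area_um2 = area_um2,
               dapi_integrated = dapi_integrated, hnf4a_pos = hnf4a_pos,
               ki67_pos = ki67_pos, is_tumor = is_tumor)
  if (is.null(n)) n <- max(vapply(args, length, integer(1)))
  out <- tibble::as_tibble(lapply(args, rep_len, length.out = n))
  out$nucleus_id <- sprintf("%s_n%04d", out$tumor_id, seq_len(n))
  out[, c("tumor_id", "field_id", "nucleus_id", "spots_chr7", "spots_chr11",
          "spots_chr16", "area_um2", "dapi_integrated", "hnf4a_pos",
          "ki67_pos", "is_tumor")]
}

# tumor nuclei whose three spot-count columns are given directly as a matrix
make_nuclei_spots <- function(spots, tumor_id = "T001") {
  spots <- as.matrix(spots)
  make_nuclei(n = nrow(spots), tumor_id = tumor_id,
              spots_chr7 = as.integer(spots[, 1]),
              spots_chr11 = as.integer(spots[, 2]),
              spots_chr16 = as.integer(spots[, 3]))
}

# --- independent oracles ----------------------------------------------------

# brute-force modal non-zero count with larger-value tie-break
oracle_mode <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(NA_integer_)
  freq <- vapply(sort(unique(counts)), function(v) sum(counts == v), integer(1))
  vals <- sort(unique(counts))
  max(vals[freq == max(freq)])
}

# exact one-sided Mann-Whitney p-value by enumeration of all assignments of
# ranks to the x sample (no ties); alternative = "less" means x below y
oracle_mwu_p <- function(x, y, alternative) {
  nx <- length(x)
  all_idx <- utils::combn(length(x) + length(y), nx)
  pooled <- c(x, y)
  u_of <- function(xv, yv) sum(outer(xv, yv, ">")) # Mann-Whitney U for x
  u_obs <- u_of(x, y)
  us <- apply(all_idx, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  if (alternative == "less") mean(us <= u_obs) else mean(us >= u_obs)
}

# two-sided Fisher exact p by enumeration of all tables with the observed
# margins, summing probabilities <= that of the observed table
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  prob_a <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(0)
    exp(lchoose(r1, a) + lchoose(r2, cc) - lchoose(r1 + r2, c1))
  }
  p_obs <- prob_a(tab[1, 1])
  amax <- min(r1, c1)
  ps <- vapply(0:amax, prob_a, numeric(1))
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# upper-tail hypergeometric by direct summation
oracle_hyper_p <- function(k, n_a, n_b, N) {
  kk <- k:min(n_a, n_b)
  sum(exp(lchoose(n_a, kk) + lchoose(N - n_a, n_b - kk) - lchoose(N, n_b)))
}

# product-limit estimate at each event time, no ties in times assumed
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  n <- length(time)
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (i in seq_len(n)) {
    if (event[i]) {
      s <- s * (1 - 1 / (n - i + 1))
      out <- rbind(out, data.frame(time = time[i], surv = s))
    }
  }
  out
}

# default study-mirror cohorts are used by several test files; cache by seed
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(seed) {
  key <- as.character(seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(generator_config(seed = seed))
  .cohort_cache[[key]]
}
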