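test_that("predominant copy number is the modal non-zero count", {
  nuc <- make_nuclei(spots_chr7 = c(2L, 2L, 2L, 2L, 4L))
  expect_equal(predominant_copy_number(nuc, "chr7"), 2L)
  # dropout zeros are excluded, not treated as nullisomy
  nuc <- make_nuclei(spots_chr11 = c(4L, 4L, 3L, 4L, 0L, 4L))
  expect_equal(predominant_copy_number(nuc, "chr11"), 4L)
  # frequency tie broken toward the larger count (undercount-bias rule)
  nuc <- make_nuclei(spots_chr16 = c(3L, 3L, 4L, 4L))
  expect_equal(predominant_copy_number(nuc, "chr16"), 4L)
  # non-tumor nuclei never contribute
  nuc <- make_nuclei(spots_chr7 = c(2L, 2L, 4L, 4L, 4L),
                     is_tumor = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(predominant_copy_number(nuc, "chr7"), 2L)
  # all-zero probe is uncallable
  nuc <- make_nuclei(spots_chr7 = 0L)
  expect_error(predominant_copy_number(nuc, "chr7"),
               class = "hccploidy_uncallable_probe")
})

test_that("predominant copy number equals the brute-force mode on all small inputs", {
  # every multiset of <= 6 nuclei with per-probe counts in 0..5, enumerated
  # as frequency vectors (n0..n5); the package must agree with the oracle
  grid <- expand.grid(n0 = 0:6, n1 = 0:6, n2 = 0:6, n3 = 0:6, n4 = 0:6,
                      n5 = 0:6)
  grid <- grid[rowSums(grid) >= 1 & rowSums(grid) <= 6, ]
  for (i in seq_len(nrow(grid))) {
    counts <- rep(0:5, times = unlist(grid[i, ]))
    expected <- oracle_mode(counts)
    nuc <- make_nuclei(spots_chr7 = as.integer(counts))
    if (is.na(expected)) {
      expect_error(predominant_copy_number(nuc, "chr7"),
                   class = "hccploidy_uncallable_probe")
    } else {
      expect_identical(predominant_copy_number(nuc, "chr7"), expected)
    }
  }
})

test_that("tumor calls honor the 2.5-copy inclusive boundary", {
  # predominant (4,4,4): tetraploid
  nuc <- make_nuclei(n = 10, spots_chr7 = 4L, spots_chr11 = 4L,
                     spots_chr16 = 4L)
  prof <- suppressWarnings(call_tumor(nuc))
  expect_equal(prof$average_ploidy, 4)
  expect_equal(prof$call, "polyploid")
  # predominant (2,2,3): average 2.33, near-diploid
  nuc <- make_nuclei(n = 9, spots_chr16 = 3L)
  prof <- suppressWarnings(call_tumor(nuc))
  expect_equal(prof$average_ploidy, 7 / 3)
  expect_equal(prof$call, "near_diploid")
  # predominant (2,3,3): average 2.67, polyploid
  nuc <- make_nuclei(n = 9, spots_chr11 = 3L, spots_chr16 = 3L)
  expect_equal(suppressWarnings(call_tumor(nuc))$call, "polyploid")
  # the boundary is inclusive ("2.5 or more"): an average exactly equal to
  # the threshold is polyploid (tested at an attainable average, 8/3)
  nuc <- make_nuclei(n = 9, spots_chr11 = 3L, spots_chr16 = 3L)
  prof <- suppressWarnings(call_tumor(nuc, threshold = 8 / 3))
  expect_equal(prof$average_ploidy, 8 / 3)
  expect_equal(prof$call, "polyploid")
})

test_that("QC minima flag but do not block small tumors", {
  nuc <- make_nuclei(n = 20, field_id = rep(1:2, 10))
  expect_warning(prof <- call_tumor(nuc), "below QC minima")
  expect_false(prof$qc_pass)
  expect_equal(prof$n_nuclei_used, 20)
  expect_equal(prof$n_fields, 2)
  # and pass cleanly above the minima
  nuc <- make_nuclei(n = 250, field_id = rep(1:6, length.out = 250))
  expect_silent(prof <- call_tumor(nuc))
  expect_true(prof$qc_pass)
})

test_that("empty or uncallable tumors raise typed errors with context", {
  expect_error(call_tumor(make_nuclei(n = 0)),
               class = "hccploidy_uncallable_tumor")
  nuc <- make_nuclei(n = 5, spots_chr11 = 0L)
  expect_error(suppressWarnings(call_tumor(nuc)),
               class = "hccploidy_uncallable_tumor")
  expect_error(suppressWarnings(call_cohort(nuc)), "T001",
               class = "hccploidy_uncallable_tumor")
})

test_that("nucleus order never changes the call", {
  set.seed(31)
  nuc <- make_nuclei(n = 60, field_id = rep(1:6, 10),
                     spots_chr7 = sample(0:4, 60, TRUE),
                     spots_chr11 = sample(1:4, 60, TRUE),
                     spots_chr16 = sample(1:5, 60, TRUE))
  a <- suppressWarnings(call_tumor(nuc))
  b <- suppressWarnings(call_tumor(nuc[sample.int(60), ]))
  expect_equal(a, b)
})

test_that("raising the threshold never makes a near-diploid call polyploid", {
  set.seed(17)
  for (rep in 1:20) {
    nuc <- make_nuclei(n = 30, field_id = rep(1:5, 6),
                       spots_chr7 = sample(1:4, 30, TRUE),
                       spots_chr11 = sample(1:4, 30, TRUE),
                       spots_chr16 = sample(1:4, 30, TRUE))
    lo <- suppressWarnings(call_tumor(nuc, threshold = 2.5))
    hi <- suppressWarnings(call_tumor(nuc, threshold = 3.5))
    expect_false(lo$call == "near_diploid" && hi$call == "polyploid")
  }
})

test_that("the caller recovers the true copy triple under default FFPE noise", {
  # 1000 simulated tumors at default dropout 0.10 / hybridization failure
  # 0.05 with 250 nuclei; the true triple must be recovered in > 99%
  cfg <- generator_config(seed = 0)
  set.seed(1234)
  triples <- cbind(sample(2:4, 1000, TRUE), sample(2:4, 1000, TRUE),
                   sample(2:4, 1000, TRUE))
  hits <- vapply(seq_len(nrow(triples)), function(i) {
    truth <- tibble::tibble(tumor_id = "X", copies_chr7 = triples[i, 1],
                            copies_chr11 = triples[i, 2],
                            copies_chr16 = triples[i, 3],
                            pgcc_abundant_true = FALSE, pgcc_rate = 0)
    nuc <- generate_tumor_nuclei(truth, cfg)
    prof <- call_tumor(nuc)
    all(c(prof$c7, prof$c11, prof$c16) == triples[i, ])
  }, logical(1))
  expect_gt(mean(hits), 0.99)
})

test_that("noiseless cohorts round-trip to the truth labels", {
  cfg <- generator_config(n_tumors = 12, signal_dropout = 0, hyb_failure = 0,
                          nuclei_per_tumor = 250, seed = 6)
  co <- generate_cohort(cfg)
  prof <- call_cohort(co)
  tr <- co$truths[match(prof$tumor_id, co$truths$tumor_id), ]
  expect_equal(prof$call, tr$true_class)
  expect_equal(prof$c7, tr$copies_chr7)
  expect_equal(prof$c11, tr$copies_chr11)
  expect_equal(prof$c16, tr$copies_chr16)
})

test_that("single diploid tumor cohorts summarize to 0% polyploid", {
  cfg <- generator_config(n_tumors = 1, prevalence_polyploid = 0,
                          p_trisomy_neardiploid = 0, nuclei_per_tumor = 250,
                          seed = 9)
  prof <- call_cohort(generate_cohort(cfg))
  s <- ploidy_call_summary(prof)
  expect_equal(s$pct_polyploid, 0)
  expect_true(is.na(s$mean_ploidy_polyploid))
})
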