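test_that("one-sided Mann-Whitney matches exact enumeration on small samples", {
  # fully separated samples: U = 0, p = 1/C(6,3) = 0.05
  res <- mann_whitney_one_sided(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / choose(6, 3))
  expect_true(res$exact)
  # random no-tie samples with combined n <= 12 against the enumeration oracle
  set.seed(100)
  for (rep in 1:15) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(1:100, nx + ny)  # distinct values, no ties
    x <- v[1:nx]; y <- v[-(1:nx)]
    for (alt in c("greater", "less")) {
      expect_equal(mann_whitney_one_sided(x, y, alt)$p_value,
                   oracle_mwu_p(x, y, alt), tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney direction and null behave as expected", {
  x <- c(1.1, 2.2, 3.3, 4.4)
  expect_gte(mann_whitney_one_sided(x, x + 0.05 * c(1, -1, 1, -1),
                                    "greater")$p_value, 0.3)
  # the two one-sided exact tails overlap at the observed table
  y <- c(2.5, 3.1, 5.0)
  pg <- mann_whitney_one_sided(x, y, "greater")$p_value
  pl <- mann_whitney_one_sided(x, y, "less")$p_value
  expect_gte(pg + pl, 1)
  expect_error(mann_whitney_one_sided(numeric(0), y),
               class = "hccploidy_input_error")
})

test_that("Fisher exact matches hypergeometric enumeration", {
  # diagonal 5/5 table: only 2 of the C(10,5) arrangements are as extreme
  res <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  # zero margin: p = 1
  expect_equal(fisher_exact_2x2(matrix(c(3, 4, 0, 0), 2))$p_value, 1)
  # transpose symmetry
  tab <- matrix(c(7, 2, 1, 5), 2)
  expect_equal(fisher_exact_2x2(tab)$p_value, fisher_exact_2x2(t(tab))$p_value)
  # all tables with total <= 12 against the enumeration oracle
  tabs <- expand.grid(a = 0:12, b = 0:12, c = 0:12, d = 0:12)
  tabs <- tabs[rowSums(tabs) <= 12 & rowSums(tabs) >= 1, ]
  set.seed(8)
  tabs <- tabs[sample.int(nrow(tabs), 300), ]
  for (i in seq_len(nrow(tabs))) {
    tab <- matrix(unlist(tabs[i, ]), 2, byrow = TRUE)
    expect_equal(fisher_exact_2x2(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)),
               class = "hccploidy_input_error")
})

test_that("chi-square statistic follows the closed-form Pearson sum", {
  res <- chi_square_2xk(matrix(10, 2, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res <- chi_square_2xk(matrix(c(20, 0, 0, 20), 2))
  expect_equal(res$statistic, 40)
  expect_equal(res$df, 1)
  # doubling all counts doubles the statistic at fixed proportions
  tab <- matrix(c(12, 6, 8, 14, 5, 9), 2, byrow = TRUE)
  expect_equal(chi_square_2xk(2 * tab)$statistic,
               2 * chi_square_2xk(tab)$statistic)
  expect_equal(chi_square_2xk(tab)$df, 2)
  # zero expected cell points at Fisher
  expect_error(chi_square_2xk(matrix(c(5, 0, 3, 0), 2)), "fisher",
               class = "hccploidy_input_error")
})

test_that("Kaplan-Meier curves follow the product-limit closed form", {
  rec <- tibble::tibble(tumor_id = 1:6,
                        time_years = c(1, 2, 3, 1.5, 2.5, 3.5),
                        event = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
                        group = rep(c("A", "B"), each = 3))
  res <- km_logrank(rec, "A", "B")
  a <- res$curves[res$curves$group == "A", ]
  expect_equal(a$time, c(0, 1, 2, 3))
  expect_equal(a$survival, c(1, 2 / 3, 1 / 3, 0))
  # against the oracle on a censored single group
  set.seed(3)
  tt <- sort(runif(8, 0.1, 5)); ev <- c(TRUE, TRUE, FALSE, TRUE, FALSE,
                                        TRUE, TRUE, FALSE)
  rec2 <- tibble::tibble(tumor_id = 1:9,
                         time_years = c(tt, 1),
                         event = c(ev, TRUE),
                         group = c(rep("A", 8), "B"))
  res2 <- km_logrank(rec2, "A", "B")
  ka <- res2$curves[res2$curves$group == "A" & res2$curves$time > 0, ]
  ko <- oracle_km(tt, ev)
  expect_equal(ka$time, ko$time)
  expect_equal(ka$survival, ko$surv)
})

test_that("Kaplan-Meier estimates are valid survival functions", {
  set.seed(14)
  for (rep in 1:10) {
    n <- 30
    rec <- tibble::tibble(
      tumor_id = seq_len(n),
      time_years = rexp(n, 0.3) + 0.01,
      event = runif(n) < 0.7,
      group = sample(c("A", "B"), n, TRUE, prob = c(0.6, 0.4)))
    if (!any(rec$event)) next
    res <- tryCatch(km_logrank(rec, "A", "B"),
                    hccploidy_empty_group = function(e) NULL)
    if (is.null(res)) next
    for (g in c("A", "B")) {
      cv <- res$curves[res$curves$group == g, ]
      expect_equal(cv$survival[cv$time == 0], 1)
      expect_true(all(diff(cv$survival) <= 1e-12))
      expect_true(all(cv$survival >= 0 & cv$survival <= 1))
    }
    expect_gte(res$p_value, 0)
    expect_lte(res$p_value, 1)
  }
})

test_that("identical survival groups give a null log-rank statistic", {
  rec <- tibble::tibble(tumor_id = 1:6,
                        time_years = rep(c(1, 2, 3), 2),
                        event = TRUE,
                        group = rep(c("A", "B"), each = 3))
  res <- km_logrank(rec, "A", "B")
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
  expect_error(km_logrank(rec, "A", "C"), class = "hccploidy_empty_group")
})

test_that("high-PUB strata show worse survival in nearly all replicates", {
  # at hazard ratio 3.5 the PUB=2 stratum (mostly polyploid) must show worse
  # survival -- more deaths than the log-rank null expects, i.e. its curve
  # sits below the PUB<2 stratum -- in at least 95% of 100 seeded cohorts
  cfg0 <- generator_config()
  worse <- vapply(1:100, function(s) {
    set.seed(s + 5000)
    truths <- tibble::tibble(
      tumor_id = sprintf("T%03d", 1:56),
      true_class = c(rep("polyploid", 20), rep("near_diploid", 36)))
    truths <- assign_marker_profiles(truths, cfg0)
    truths$hazard <- cfg0$hazard_neardiploid *
      ifelse(truths$true_class == "polyploid", cfg0$hazard_ratio_polyploid, 1)
    surv <- generate_survival(truths, cfg0)
    pub2 <- truths$marker_category == "both"
    surv$group <- ifelse(pub2[match(surv$tumor_id, truths$tumor_id)],
                         "PUB2", "PUB<2")
    grp <- factor(surv$group, levels = c("PUB2", "PUB<2"))
    sd <- survival::survdiff(survival::Surv(surv$time_years, surv$event) ~ grp)
    sd$obs[1] > sd$exp[1]
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})

test_that("hypergeometric overlap tail is exact, monotone and underflow-safe", {
  expect_equal(hypergeom_overlap(0, 5, 5, 10)$p_value, 1)
  expect_equal(hypergeom_overlap(5, 5, 5, 10)$p_value, 1 / choose(10, 5),
               tolerance = 1e-12)
  # against direct summation
  set.seed(44)
  for (rep in 1:20) {
    N <- sample(10:60, 1)
    na <- sample(1:N, 1); nb <- sample(1:N, 1)
    k <- sample(0:min(na, nb), 1)
    expect_equal(hypergeom_overlap(k, na, nb, N)$p_value,
                 oracle_hyper_p(k, na, nb, N), tolerance = 1e-9)
  }
  # strictly decreasing in k
  ps <- vapply(0:20, function(k) hypergeom_overlap(k, 30, 40, 200)$p_value,
               numeric(1))
  expect_true(all(diff(ps) < 0))
  # complementary tails: P(X >= k) + P(X <= k - 1) = 1
  for (k in c(0, 3, 7)) {
    up <- hypergeom_overlap(k, 20, 30, 100)$p_value
    lo <- phyper(k - 1, 20, 80, 30)
    expect_equal(up + lo, 1, tolerance = 1e-12)
  }
  # an astronomical overlap keeps a finite log10 p
  res <- hypergeom_overlap(200, 200, 200, 20000)
  expect_equal(res$p_value, 0)  # underflows in linear space
  expect_true(is.finite(res$log10_p))
  expect_lt(res$log10_p, -300)
  expect_error(hypergeom_overlap(6, 5, 5, 10),
               class = "hccploidy_input_error")
})
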