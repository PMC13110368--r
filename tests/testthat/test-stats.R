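# brute-force two-tailed Mann-Whitney p by enumerating all labelings
enumerate_mw_p <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  n <- length(pool)
  u_obs <- sum(rank(pool)[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(idx) {
    sum(rank(pool)[idx]) - nx * (nx + 1) / 2
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

test_that("delta-delta-Ct recovers exact folds on noise-free plates", {
  pl <- simulate_qpcr_plate(true_fold = 1, ct_noise_sd = 0, seed = 1)
  expect_equal(delta_delta_ct(pl)$fold_change, 1)
  # a uniform +1 cycle on the mutant target halves expression
  pl2 <- simulate_qpcr_plate(true_fold = 0.5, ct_noise_sd = 0, seed = 1)
  expect_equal(delta_delta_ct(pl2)$fold_change, 0.5)
})

test_that("delta-delta-Ct recovers a 0.35 fold from noisy plates on average", {
  folds <- vapply(1:50, function(s) {
    pl <- simulate_qpcr_plate(0.35, ct_noise_sd = 0.15, n_biological = 6,
                              seed = s)
    delta_delta_ct(pl)$fold_change
  }, 0)
  expect_equal(mean(folds), 0.35, tolerance = 0.03 / 0.35)
})

test_that("fold changes are invariant to a constant Ct shift on the plate", {
  pl <- simulate_qpcr_plate(0.7, ct_noise_sd = 0.1, seed = 2)
  f1 <- delta_delta_ct(pl)$fold_change
  pl$ct <- pl$ct + 3.21
  expect_equal(delta_delta_ct(pl)$fold_change, f1)
})

test_that("a missing reference gene names the offending sample", {
  pl <- simulate_qpcr_plate(1, 0, seed = 1)
  bad <- dplyr::filter(pl, !(gene == "rpl13" & sample == "mutant_2"))
  expect_error(delta_delta_ct(bad), "mutant_2")
})

test_that("Mann-Whitney handles the textbook separable case", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic_U, 0)
  expect_equal(r$p_two_tailed, 0.1)
  expect_equal(r$method, "exact")
})

test_that("identical samples give p = 1", {
  r <- mann_whitney_u(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$p_two_tailed, 1)
})

test_that("exact p matches the enumeration oracle for all untied n <= 6", {
  set.seed(20)
  for (nx in 2:6) {
    for (ny in 2:6) {
      vals <- sample(1000, nx + ny)     # untied by construction
      x <- vals[seq_len(nx)]
      y <- vals[-seq_len(nx)]
      r <- mann_whitney_u(x, y)
      expect_equal(r$method, "exact")
      expect_equal(r$p_two_tailed, enumerate_mw_p(x, y),
                   info = sprintf("nx=%d ny=%d", nx, ny))
    }
  }
})

test_that("exact U and p agree with the reference implementation", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(7)
    y <- rnorm(9, 0.5)
    mine <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$statistic_U, unname(ref$statistic))
    expect_equal(mine$p_two_tailed, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the approximate path is sane under heavy ties", {
  x <- c(1, 1, 2, 2, 3, 3, 3, 4, 4, 5, 5, 5, 6, 6)
  y <- c(2, 3, 3, 4, 4, 4, 5, 5, 6, 6, 7, 7, 7, 8)
  mine <- mann_whitney_u(x, y)
  expect_equal(mine$method, "normal_approx_tie_corrected")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(mine$p_two_tailed, ref$p.value, tolerance = 1e-6)
})

test_that("rank-test p is invariant under strictly increasing transforms", {
  set.seed(22)
  x <- rnorm(5)
  y <- rnorm(6, 1)
  p1 <- mann_whitney_u(x, y)$p_two_tailed
  p2 <- mann_whitney_u(exp(x), exp(y))$p_two_tailed
  p3 <- mann_whitney_u(x^3 + 2 * x, y^3 + 2 * y)$p_two_tailed
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("significance labels honour the inclusive printed thresholds", {
  expect_equal(significance_label(0.2), "ns")
  expect_equal(significance_label(0.05), "*")
  expect_equal(significance_label(0.01), "**")
  expect_equal(significance_label(0.001), "***")
  expect_equal(significance_label(1e-6), "****")
  # monotone: smaller p never yields a weaker label
  ps <- sort(c(runif(30), 0.05, 0.01, 0.001, 1e-4))
  lv <- c(ns = 0, `*` = 1, `**` = 2, `***` = 3, `****` = 4)
  strength <- lv[significance_label(ps)]
  expect_true(all(diff(strength) <= 0))
})

test_that("percent change is the signed relative difference of means", {
  expect_equal(percent_change(120, 96), -20)
  expect_equal(percent_change(120, 120), 0)
  expect_equal(percent_change(120, 180), 50)
  expect_error(percent_change(0, 5), "zero")
})

test_that("group summaries match closed forms and duplication behaviour", {
  df <- tibble::tibble(g = "a", v = c(2, 4, 6))
  s <- summarize_groups(df, v, g)
  expect_equal(s$mean, 4)
  expect_equal(s$sd, 2)
  expect_equal(s$sem, 2 / sqrt(3))
  dup <- summarize_groups(dplyr::bind_rows(df, df), v, g)
  expect_equal(dup$n, 6L)
  expect_equal(dup$mean, 4)
  expect_equal(dup$sd, s$sd, tolerance = 0.12)   # pooled SD shrinks slightly
  expect_equal(dup$sem, s$sd / sqrt(6), tolerance = 0.12)
  expect_warning(summarize_groups(tibble::tibble(g = c("a", "b"), v = 1:2),
                                  v, g), "size 1")
})

test_that("Wilson intervals match the score-interval reference", {
  r <- proportion_with_ci(0, 20)
  expect_equal(r$estimate, 0)
  expect_equal(r$lower, 0)
  r2 <- proportion_with_ci(20, 20)
  expect_equal(r2$estimate, 1)
  expect_equal(r2$upper, 1)
  r3 <- proportion_with_ci(16, 100)
  ref <- stats::prop.test(16, 100, correct = FALSE)$conf.int
  expect_equal(r3$lower, ref[1], tolerance = 1e-9)
  expect_equal(r3$upper, ref[2], tolerance = 1e-9)
  expect_lt(r3$lower, 0.16)
  expect_gt(r3$upper, 0.16)
})

test_that("cohort tests report percent effects with star labels", {
  set.seed(23)
  df <- tibble::tibble(
    genotype = rep(c("wt", "mut"), each = 12),
    cell_count = c(rnorm(12, 120, 2), rnorm(12, 180, 3)))
  res <- cohort_tests(df, cell_count, genotype, ref_group = "wt")
  expect_equal(res$group, "mut")
  expect_gt(res$percent_change, 45)
  expect_lt(res$percent_change, 55)
  expect_lt(res$p.value, 0.001)
  expect_equal(res$method, "mann_whitney")
  welch <- cohort_tests(df, cell_count, genotype, ref_group = "wt",
                        method = "welch")
  expect_lt(welch$p.value, 0.001)
})

test_that("tidy and glance return one-row summaries", {
  r <- mann_whitney_u(1:5, 3:9)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_named(td, c("statistic", "p.value", "n_x", "n_y", "method", "label"))
  expect_identical(glance(r), td)
})
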