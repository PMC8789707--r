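test_that("rank correlations match hand arithmetic and the stats reference", {
  x <- 1:6; y <- c(2, 1, 4, 3, 6, 5)
  # no ties: rs = 1 - 6*sum(d^2)/(n(n^2-1)) = 1 - 36/210
  res <- fabnorms:::rank_correlation(x, y)
  expect_equal(res$coefficient, 1 - 36 / 210)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(res$coefficient, unname(ct$estimate))

  mono <- fabnorms:::rank_correlation(1:20, exp(1:20))
  expect_equal(mono$coefficient, 1)
  expect_equal(mono$p, 0)

  degen <- fabnorms:::rank_correlation(rep(1, 10), 1:10)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$coefficient))
})

test_that("the battery splits alpha over exactly k comparisons", {
  coh <- generate_cohort(default_generator_config(n = 200, seed = 15))
  bat <- correlation_battery(coh)
  expect_equal(nrow(bat), 28)
  expect_equal(unique(bat$alpha_adjusted), 0.05 / 28)
  expect_equal(unique(bat$alpha_adjusted) * attr(bat, "k"), 0.05)
  expect_equal(bonferroni_alpha(0.05, 28, digits = 4), 0.0017)
  # FAB total vs MoCA total: strong positive association by construction
  top <- bat[bat$var1 == "fab" & bat$var2 == "moca_total", ]
  expect_gt(top$coefficient, 0.3)
  expect_true(top$significant)
})

test_that("spearman batteries are invariant under monotone transforms", {
  coh <- generate_cohort(default_generator_config(n = 150, seed = 25))
  a <- fabnorms:::rank_correlation(coh$age, scale_scores(coh, "fab"))
  b <- fabnorms:::rank_correlation(coh$age^3, scale_scores(coh, "fab"))
  expect_equal(a$coefficient, b$coefficient)
  expect_equal(a$p, b$p)
})

test_that("sub-scale battery shows part-whole structure", {
  coh <- generate_cohort(default_generator_config(n = 475, seed = 33))
  sb <- subscale_battery(coh)
  expect_equal(nrow(sb), 6)
  with_total <- sb$coefficient[sb$var2 == "fab"]
  between <- sb$coefficient[sb$var2 != "fab"]
  expect_true(all(with_total > 0))
  expect_gt(min(with_total), max(between))  # 0.63-0.7 vs 0.21-0.24 pattern

  dup <- make_cohort(list(cohort_row("a", items = c(3, 3, 3, 3, 3, 3)),
                          cohort_row("b", items = c(0, 0, 0, 0, 0, 0)),
                          cohort_row("c", items = c(2, 1, 2, 1, 2, 1))))
  sbd <- subscale_battery(dup)
  expect_equal(sbd$coefficient[sbd$var1 == "fab1" & sbd$var2 == "fab2"], 1)
})

test_that("sex tests reproduce closed-form t statistics and policies", {
  coh <- make_cohort(list(
    cohort_row("m1", "M", items = c(1, 0, 0, 0, 0, 0)),
    cohort_row("m2", "M", items = c(2, 0, 0, 0, 0, 0)),
    cohort_row("m3", "M", items = c(3, 0, 0, 0, 0, 0)),
    cohort_row("f1", "F", items = c(2, 0, 0, 0, 0, 0)),
    cohort_row("f2", "F", items = c(3, 0, 0, 0, 0, 0)),
    cohort_row("f3", "F", items = c(3, 1, 0, 0, 0, 0))))
  res <- sex_tests(coh, scales = "fab1", variance_policy = "pooled")
  m <- c(1, 2, 3); f <- c(2, 3, 4)
  sp <- sqrt((var(m) + var(f)) / 2)
  expect_equal(res$t, (mean(m) - mean(f)) / (sp * sqrt(2 / 3)))
  expect_equal(res$df, 4)

  same <- make_cohort(list(
    cohort_row("m1", "M", items = c(1, 1, 1, 1, 1, 1)),
    cohort_row("m2", "M", items = c(2, 2, 2, 2, 2, 2)),
    cohort_row("f1", "F", items = c(1, 1, 1, 1, 1, 1)),
    cohort_row("f2", "F", items = c(2, 2, 2, 2, 2, 2))))
  expect_equal(sex_tests(same, scales = "fab")$t, 0)

  single <- make_cohort(list(cohort_row("a", "F"), cohort_row("b", "F")))
  expect_error(sex_tests(single), "both sexes")

  # generator has no sex effect: expect null results on the default cohort
  big <- generate_cohort(default_generator_config(seed = 3))
  res_big <- sex_tests(big)
  expect_true(all(res_big$p > 0.05))
  # welch df is strictly below the pooled df of n - 2
  welch <- sex_tests(big, scales = "fab", variance_policy = "welch")
  pooled <- sex_tests(big, scales = "fab", variance_policy = "pooled")
  expect_equal(pooled$df, nrow(big) - 2)
  expect_lt(welch$df, pooled$df)
})

test_that("minimum sample size search matches an independent grid scan and
           brackets the power target", {
  expect_equal(as.integer(min_sample_size(3, 0.05, 0.05, 0.9)), 287L)

  # oracle: vectorised noncentral-F power over a grid, same convention
  grid_oracle <- function(u, f2, alpha, power) {
    n <- (u + 2):2000
    v <- n - u
    pw <- pf(qf(1 - alpha, u, v), u, v, ncp = f2 * (u + v + 1),
             lower.tail = FALSE)
    n[min(which(pw >= power))]
  }
  got <- min_sample_size(3, 0.35, 0.05, 0.8)
  expect_equal(as.integer(got), grid_oracle(3, 0.35, 0.05, 0.8))

  # bracketing: power at n_min reaches the target, at n_min - 1 it does not
  n <- as.integer(min_sample_size(3, 0.05, 0.05, 0.9))
  expect_gte(regression_power(n, 3, 0.05), 0.9)
  expect_lt(regression_power(n - 1, 3, 0.05), 0.9)

  # monotone in effect size
  expect_lt(as.integer(min_sample_size(3, 0.10, 0.05, 0.9)), 287L)
  expect_error(min_sample_size(3, 1e-9, 0.05, 0.9, max_n = 500), "unreachable")

  # textbook intercept accounting shifts the answer by one
  expect_equal(as.integer(min_sample_size(3, 0.05, 0.05, 0.9,
                                          intercept_in_df = TRUE)), 288L)
})
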