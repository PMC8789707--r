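test_that("cohort CSV round-trips bit-exactly and rejects invalid rows", {
  coh <- generate_cohort(default_generator_config(n = 20, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  strip <- function(d) {
    d <- as.data.frame(d)
    attr(d, "provenance") <- NULL; attr(d, "latent") <- NULL
    d
  }
  expect_equal(strip(back), strip(coh))

  df <- as.data.frame(coh)
  df$education[3] <- 0
  bad1 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, bad1, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(bad1), "row 3.*education")

  df <- as.data.frame(coh)
  df$fab2[5] <- 4
  bad2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, bad2, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(bad2), "row 5.*fab2")

  df <- as.data.frame(coh)
  df$age <- NULL
  bad3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, bad3, row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(bad3), "missing required columns.*age")
})

test_that("read_cohort honours a column-name schema map", {
  coh <- generate_cohort(default_generator_config(n = 5, seed = 3))
  df <- as.data.frame(coh)
  names(df)[names(df) == "education"] <- "edu_years"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  back <- read_cohort(path, schema = c(education = "edu_years"))
  expect_equal(back$education, coh$education)
  expect_error(read_cohort(path, schema = c(education = "no_such_col")),
               "absent columns")
})

test_that("scale scores sum the right items and partition the total", {
  row <- cohort_row(items = c(2, 3, 1, 2, 0, 3))
  expect_identical(scale_scores(row, "fab1"), 5L)
  expect_identical(scale_scores(row, "fab2"), 3L)
  expect_identical(scale_scores(row, "fab3"), 3L)
  expect_identical(scale_scores(row, "fab"), 11L)

  maxed <- cohort_row(items = rep(3, 6))
  expect_identical(scale_scores(maxed, "fab"), 18L)
  for (s in c("fab1", "fab2", "fab3"))
    expect_identical(scale_scores(maxed, s), 6L)

  # partition identity over random item patterns
  set.seed(42)
  items <- matrix(sample(0:3, 6 * 50, replace = TRUE), ncol = 6)
  df <- as.data.frame(items)
  names(df) <- paste0("fab", 1:6)
  expect_identical(
    scale_scores(df, "fab1") + scale_scores(df, "fab2") + scale_scores(df, "fab3"),
    scale_scores(df, "fab"))
})

test_that("stratification table counts every participant exactly once", {
  empty <- generate_cohort(default_generator_config(n = 0, seed = 1))
  expect_true(all(stratification_table(empty) == 0))

  coh <- four_person_cohort()
  tab <- stratification_table(coh)
  expect_equal(sum(tab), 4)
  expect_equal(unname(tab["F", "<=35", "<=5"]), 1)       # A: 30y, 4y edu
  expect_equal(unname(tab["M", "<=35", "<=5"]), 1)       # B
  expect_equal(unname(tab["F", "66-75", "12-16"]), 1)    # C: 70y, 12y edu
  expect_equal(unname(tab["M", ">95", ">21"]), 1)        # D: 98y, 25y edu

  big <- generate_cohort(default_generator_config(n = 200, seed = 5))
  expect_equal(sum(stratification_table(big)), 200)
  expect_error(stratification_table(coh, age_breaks = c(0, 50, 40, Inf)),
               "strictly increasing")
})

test_that("generated default cohort reproduces the 306/169 sex split closely", {
  coh <- generate_cohort(default_generator_config(n = 475, seed = 20))
  tab <- stratification_table(coh)
  n_f <- sum(tab["F", , ])
  expect_equal(n_f + sum(tab["M", , ]), 475)
  # Bernoulli(306/475) marginal: allow ~3 sd around the expectation
  expect_lt(abs(n_f - 306), 3 * sqrt(475 * (306 / 475) * (169 / 475)))
})

test_that("descriptives report moments, ranges and degenerate columns", {
  rows <- lapply(1:5, function(i)
    cohort_row(id = paste0("P", i), age = c(41, 42, 43, 44, 45)[i],
               education = 10))
  coh <- make_cohort(rows)
  d <- descriptives(coh, c("age", "education"))
  expect_equal(d$mean[d$variable == "age"], 43)
  expect_equal(d$min[d$variable == "age"], 41)
  expect_equal(d$max[d$variable == "age"], 45)
  expect_equal(d$sd[d$variable == "education"], 0)
  expect_true(is.nan(d$skewness[d$variable == "education"]))
  expect_error(descriptives(make_cohort(list(cohort_row()))), "at least 2")
})

test_that("normality screen matches hand-computed moments and thresholds", {
  sym <- normality_screen(c(-2, -1, 0, 1, 2))
  expect_equal(sym$skewness, 0)
  expect_false(sym$abnormal)

  spike <- normality_screen(c(0, 0, 0, 0, 10))
  # by hand: m2 = 16, m3 = 96, g1 = 1.5, G1 = 1.5 * sqrt(20) / 3 = sqrt(5)
  expect_equal(spike$skewness, sqrt(5))
  expect_true(spike$abnormal)

  set.seed(7)
  gauss <- normality_screen(rnorm(10000))
  expect_false(gauss$abnormal)

  const <- normality_screen(rep(3, 10))
  expect_true(const$degenerate)
  expect_true(is.na(const$abnormal))
  expect_error(normality_screen(c(1, 2)), "at least 3")
})

test_that("normality flag is invariant under location-scale maps and the raw
           kurtosis convention equals excess plus three", {
  set.seed(13)
  for (i in 1:20) {
    x <- rgamma(50, shape = sample(c(0.5, 2, 10), 1))
    a <- runif(1, -5, 5); b <- runif(1, 0.1, 10)
    expect_identical(normality_screen(x)$abnormal,
                     normality_screen(a + b * x)$abnormal)
    expect_equal(normality_screen(x, kurtosis = "raw")$kurtosis,
                 normality_screen(x, kurtosis = "excess")$kurtosis + 3)
  }
})

test_that("skewness and kurtosis agree with the e1071 reference estimators", {
  set.seed(99)
  x <- rexp(200)
  scr <- normality_screen(x)
  expect_equal(scr$skewness, e1071::skewness(x, type = 2))
  expect_equal(scr$kurtosis, e1071::kurtosis(x, type = 1))
})
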