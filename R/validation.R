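# Validation statistics: correlation batteries with Bonferroni control,
# sex-difference tests, and the regression power analysis.

# Spearman rho on average ranks with the large-sample t approximation.
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(coefficient = NA_real_, n = n, p = NA_real_,
                degenerate = TRUE))
  r <- if (method == "spearman") stats::cor(rank(x), rank(y)) else stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(coefficient = r, n = n, p = p, degenerate = FALSE)
}

#' Correlation battery with Bonferroni control
#'
#' All pairwise correlations between a set of FAB measures and a set of MoCA
#' measures, with the familywise alpha split over the `k` pairs
#' (`alpha_adjusted = family_alpha / k`). Spearman's rho on average ranks is
#' the default; p-values use the t approximation on the rank correlation.
#' Pairs with a zero-variance member are flagged degenerate rather than
#' dropped.
#'
#' @param cohort A `fab_cohort`.
#' @param fab_measures,moca_measures Variable names (scale names `fab`,
#'   `fab1..3` are recognised).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param family_alpha Familywise significance level (default 0.05).
#' @return Data frame with one row per pair: `coefficient`, `n`, `p`,
#'   `alpha_adjusted`, `significant`, `degenerate`.
#' @export
correlation_battery <- function(cohort,
                                fab_measures = c("fab", "fab1", "fab2", "fab3"),
                                moca_measures = c("moca_total", "moca_ef",
                                                  "moca_a", "moca_l", "moca_m",
                                                  "moca_vs", "moca_o"),
                                method = "spearman", family_alpha = 0.05) {
  pairs <- expand.grid(fab = fab_measures, moca = moca_measures,
                       stringsAsFactors = FALSE)
  k <- nrow(pairs)
  alpha_adj <- family_alpha / k
  get_var <- function(v)
    if (v %in% names(fab_scales())) scale_scores(cohort, v) else cohort[[v]]
  rows <- lapply(seq_len(k), function(i) {
    res <- rank_correlation(get_var(pairs$fab[i]), get_var(pairs$moca[i]),
                            method)
    data.frame(var1 = pairs$fab[i], var2 = pairs$moca[i], method = method,
               coefficient = res$coefficient, n = res$n, p = res$p,
               alpha_adjusted = alpha_adj,
               significant = !res$degenerate & res$p < alpha_adj,
               degenerate = res$degenerate)
  })
  out <- do.call(rbind, rows)
  attr(out, "k") <- k
  attr(out, "family_alpha") <- family_alpha
  out
}

#' Sub-scale intercorrelation battery
#'
#' The three pairwise sub-scale correlations plus each sub-scale against the
#' total (part--whole correlations), Bonferroni-corrected over the six pairs.
#'
#' @inheritParams correlation_battery
#' @export
subscale_battery <- function(cohort, method = "spearman", family_alpha = 0.05) {
  pairs <- rbind(
    data.frame(var1 = c("fab1", "fab1", "fab2"), var2 = c("fab2", "fab3", "fab3")),
    data.frame(var1 = c("fab1", "fab2", "fab3"), var2 = "fab"))
  k <- nrow(pairs)
  alpha_adj <- family_alpha / k
  rows <- lapply(seq_len(k), function(i) {
    res <- rank_correlation(scale_scores(cohort, pairs$var1[i]),
                            scale_scores(cohort, pairs$var2[i]), method)
    data.frame(var1 = pairs$var1[i], var2 = pairs$var2[i], method = method,
               coefficient = res$coefficient, n = res$n, p = res$p,
               alpha_adjusted = alpha_adj,
               significant = !res$degenerate & res$p < alpha_adj,
               degenerate = res$degenerate)
  })
  do.call(rbind, rows)
}

#' Two-sample sex-difference tests per scale
#'
#' Independent-samples t test of each scale score between sexes. Under the
#' default `"pretest"` policy an F ratio test of variance homogeneity at
#' `pretest_alpha` decides per scale between the pooled-variance t (integer
#' df) and Welch's unequal-variance t (fractional df).
#'
#' @param cohort A `fab_cohort` with both sexes represented (n >= 2 each).
#' @param scales Scale names to test.
#' @param variance_policy `"pretest"`, `"pooled"` or `"welch"`.
#' @param pretest_alpha Level of the homogeneity pretest (default 0.05).
#' @return Data frame with `scale`, `t`, `df`, `p`, `policy_used`.
#' @export
sex_tests <- function(cohort, scales = c("fab", "fab1", "fab2", "fab3"),
                      variance_policy = c("pretest", "pooled", "welch"),
                      pretest_alpha = 0.05) {
  variance_policy <- match.arg(variance_policy)
  sex <- as.character(cohort$sex)
  if (length(unique(sex)) < 2 || min(table(sex)) < 2)
    stop("both sexes must be represented with at least 2 observations each")
  rows <- lapply(scales, function(s) {
    y <- as.numeric(scale_scores(cohort, s))
    m <- y[sex == "M"]; f <- y[sex == "F"]
    pooled <- switch(variance_policy,
      pooled = TRUE, welch = FALSE,
      pretest = stats::var.test(m, f)$p.value >= pretest_alpha)
    tt <- stats::t.test(m, f, var.equal = pooled)
    data.frame(scale = s, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               policy_used = if (pooled) "pooled" else "welch")
  })
  do.call(rbind, rows)
}

#' Power of the multiple-regression F test
#'
#' Power of the overall noncentral-F test of a multiple linear regression
#' with `u` numerator degrees of freedom at total sample size `n`, under
#' Cohen's effect size `f2` and the noncentrality convention
#' `lambda = f2 * (u + v + 1)` where `v` is the denominator df. By default
#' `v = n - u` (the convention under which published minimum-N figures in
#' the normative literature reproduce); set `intercept_in_df = TRUE` for the
#' textbook `v = n - u - 1`.
#'
#' @param n Total sample size.
#' @param u Numerator degrees of freedom (number of predictors).
#' @param f2 Cohen's effect size, `R^2 / (1 - R^2)`.
#' @param alpha Significance level.
#' @param intercept_in_df Whether the intercept is counted in the error df.
#' @return Power (vectorised over `n`).
#' @export
regression_power <- function(n, u, f2, alpha = 0.05, intercept_in_df = FALSE) {
  v <- n - u - as.integer(intercept_in_df)
  lambda <- f2 * (u + v + 1)
  ifelse(v < 1, NA_real_,
         stats::pf(stats::qf(1 - alpha, u, v), u, v, ncp = lambda,
                   lower.tail = FALSE))
}

#' Minimum sample size for a multiple-regression power target
#'
#' Smallest integer `n` whose [regression_power()] reaches the target.
#'
#' @inheritParams regression_power
#' @param power Target power (1 - beta).
#' @param max_n Search ceiling; an error is raised if the target is not
#'   reachable below it.
#' @return Integer minimum sample size, with the achieved power as attribute
#'   `power`.
#' @examples
#' min_sample_size(u = 3, f2 = 0.05, alpha = 0.05, power = 0.9)  # 287
#' @export
min_sample_size <- function(u, f2, alpha = 0.05, power = 0.9,
                            intercept_in_df = FALSE, max_n = 1e6) {
  stopifnot(f2 > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- u + 2L
  repeat {
    pw <- regression_power(n, u, f2, alpha, intercept_in_df)
    if (!is.na(pw) && pw >= power) break
    n <- n + 1L
    if (n > max_n) stop("target power unreachable below max_n")
  }
  structure(n, power = pw)
}

#' Bonferroni-adjusted alpha
#'
#' `family_alpha / k`, optionally truncated (floored) at a display precision
#' as correlation tables conventionally report it.
#'
#' @param family_alpha Familywise level.
#' @param k Number of comparisons.
#' @param digits If non-`NULL`, truncate to this many decimals.
#' @examples
#' bonferroni_alpha(0.05, 28, digits = 4)  # 0.0017
#' @export
bonferroni_alpha <- function(family_alpha, k, digits = NULL) {
  a <- family_alpha / k
  if (!is.null(digits)) a <- floor(a * 10^digits) / 10^digits
  a
}
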