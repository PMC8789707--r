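# Demographic transform machinery and regression-based score adjustment.

TRANSFORM_FAMILIES <- list(
  identity   = function(x) x,
  square     = function(x) x^2,
  cube       = function(x) x^3,
  log        = function(x) log(x),
  reciprocal = function(x) 1 / x
)

#' Demographic predictor transform
#'
#' A transform of age or education used as a regression predictor, together
#' with its centering constant (the sample mean of the transformed predictor,
#' so that the adjustment vanishes for an average participant).
#'
#' @param predictor `"age"` or `"education"`.
#' @param family One of `"identity"`, `"square"`, `"cube"`, `"log"`,
#'   `"reciprocal"`. Logarithmic and reciprocal transforms are restricted to
#'   education, which is recorded as completed school years and is at least 1.
#' @param centering_constant Finite numeric; mean of the transformed predictor.
#' @return Object of class `fab_transform`.
#' @examples
#' transform_spec("age", "cube", 269630.547368)
#' @export
transform_spec <- function(predictor = c("age", "education"), family,
                           centering_constant) {
  predictor <- match.arg(predictor)
  family <- match.arg(family, names(TRANSFORM_FAMILIES))
  if (predictor == "age" && family %in% c("log", "reciprocal"))
    stop("log/reciprocal transforms are reserved for education")
  stopifnot(is.finite(centering_constant))
  structure(list(predictor = predictor, family = family,
                 centering_constant = centering_constant),
            class = "fab_transform")
}

#' Evaluate a centered transform
#'
#' Applies the transform family and subtracts the centering constant.
#'
#' @param spec A `fab_transform`.
#' @param value Age or education in years (vectorised).
#' @return Centered transformed value(s).
#' @examples
#' eval_transform(transform_spec("age", "cube", 269630.547368), 35)
#' @export
eval_transform <- function(spec, value) {
  stopifnot(inherits(spec, "fab_transform"))
  if (spec$family %in% c("log", "reciprocal") && any(value < 1, na.rm = TRUE))
    stop(sprintf("%s transform requires %s >= 1", spec$family, spec$predictor))
  TRANSFORM_FAMILIES[[spec$family]](value) - spec$centering_constant
}

#' Demographic adjustment equation
#'
#' Encodes `adjusted = raw + age_coef * (T_a(age) - c_a) +
#' edu_coef * (T_e(edu) - c_e)`. Adjustment coefficients are the *negated*
#' fitted regression slopes, so the correction removes the estimated
#' demographic effect: with performance declining in age, the age adjustment
#' coefficient is positive and older participants receive a bonus.
#'
#' @param scale Scale name.
#' @param age_spec,edu_spec `fab_transform` objects.
#' @param age_coef,edu_coef Adjustment coefficients (score units per
#'   transformed-predictor unit).
#' @param fit Optional list of fit statistics (standardized betas, p-values,
#'   residual sd, R^2) attached by [fit_adjustment()].
#' @return Object of class `fab_equation`.
#' @export
adjustment_equation <- function(scale, age_spec, age_coef, edu_spec, edu_coef,
                                fit = NULL) {
  stopifnot(inherits(age_spec, "fab_transform"), inherits(edu_spec, "fab_transform"),
            is.finite(age_coef), is.finite(edu_coef))
  structure(list(scale = scale,
                 age = list(spec = age_spec, coef = age_coef),
                 education = list(spec = edu_spec, coef = edu_coef),
                 fit = fit),
            class = "fab_equation")
}

#' @export
print.fab_equation <- function(x, ...) {
  cat(sprintf(
    "<fab_equation> %s\n  AS = RS %+g * [%s(age) - %g] %+g * [%s(education) - %g]\n",
    x$scale, x$age$coef, x$age$spec$family, x$age$spec$centering_constant,
    x$education$coef, x$education$spec$family,
    x$education$spec$centering_constant))
  if (!is.null(x$fit))
    cat(sprintf("  fitted: beta_age = %.3f (p = %.2g), beta_edu = %.3f (p = %.2g), R^2 = %.3f\n",
                x$fit$beta_age, x$fit$p_age, x$fit$beta_edu, x$fit$p_edu, x$fit$r_squared))
  invisible(x)
}

#' Fit a demographic adjustment equation by ordinary least squares
#'
#' Regresses the raw scale score simultaneously on a centered age transform
#' and a centered education transform; centering constants are the cohort
#' means of the transformed predictors. The returned adjustment coefficients
#' are the negated slopes.
#'
#' @param cohort A `fab_cohort`.
#' @param scale A `fab_scale` or scale name; alternatively supply `response`.
#' @param age_family,edu_family Transform family names.
#' @param response Optional numeric response overriding the scale score
#'   (used when fitting continuous latent scores).
#' @return A `fab_equation` with `fit` statistics.
#' @export
fit_adjustment <- function(cohort, scale = "fab",
                           age_family = "cube", edu_family = "log",
                           response = NULL) {
  y <- if (is.null(response)) as.numeric(scale_scores(cohort, scale)) else response
  n <- length(y)
  if (n < 4) stop("need more observations than parameters to fit")
  age_fun <- TRANSFORM_FAMILIES[[match.arg(age_family, c("identity", "square", "cube"))]]
  edu_fun <- TRANSFORM_FAMILIES[[match.arg(edu_family, c("identity", "log", "reciprocal"))]]
  ta <- age_fun(cohort$age); te <- edu_fun(cohort$education)
  ca <- mean(ta); ce <- mean(te)
  xa <- ta - ca; xe <- te - ce
  qrX <- qr(cbind(1, xa, xe))
  if (qrX$rank < 3) stop("singular design: age/education transforms are collinear or degenerate")
  f <- stats::lm(y ~ xa + xe)
  sm <- summary(f)
  co <- sm$coefficients
  fit <- list(slope_age = co["xa", "Estimate"], slope_edu = co["xe", "Estimate"],
              se_age = co["xa", "Std. Error"], se_edu = co["xe", "Std. Error"],
              p_age = co["xa", "Pr(>|t|)"], p_edu = co["xe", "Pr(>|t|)"],
              beta_age = co["xa", "Estimate"] * stats::sd(xa) / stats::sd(y),
              beta_edu = co["xe", "Estimate"] * stats::sd(xe) / stats::sd(y),
              r_squared = sm$r.squared, sigma = sm$sigma, rss = sum(sm$residuals^2),
              n = n, df_residual = f$df.residual)
  scale_name <- if (is.character(scale)) scale else scale$name
  adjustment_equation(
    scale_name,
    transform_spec("age", match.arg(age_family, c("identity", "square", "cube")), ca),
    -fit$slope_age,
    transform_spec("education", match.arg(edu_family, c("identity", "log", "reciprocal")), ce),
    -fit$slope_edu,
    fit = fit)
}

#' Select the best demographic transform pair
#'
#' Fits every candidate (age family, education family) pair simultaneously
#' and returns the pair minimising the residual sum of squares (equivalently,
#' maximising R^2 -- the "most significant" joint model among equal-sized
#' competitors). The full per-pair report is retained for audit, including
#' per-term |t| statistics for tie inspection.
#'
#' @inheritParams fit_adjustment
#' @param age_candidates,edu_candidates Candidate family name vectors.
#' @return List with `age_family`, `edu_family`, `equation` (the refit winner)
#'   and `report` (one row per candidate pair).
#' @export
select_transforms <- function(cohort, scale = "fab",
                              age_candidates = c("identity", "square", "cube"),
                              edu_candidates = c("identity", "log", "reciprocal"),
                              response = NULL) {
  stopifnot(length(age_candidates) >= 1, length(edu_candidates) >= 1)
  rows <- list(); eqs <- list()
  for (fa in age_candidates) for (fe in edu_candidates) {
    eq <- tryCatch(
      fit_adjustment(cohort, scale, fa, fe, response = response),
      error = function(e) NULL)
    if (is.null(eq)) next
    key <- paste(fa, fe, sep = "+")
    eqs[[key]] <- eq
    rows[[key]] <- data.frame(
      age_family = fa, edu_family = fe, rss = eq$fit$rss,
      r_squared = eq$fit$r_squared,
      t_age = abs(eq$fit$slope_age / eq$fit$se_age),
      t_edu = abs(eq$fit$slope_edu / eq$fit$se_edu),
      p_age = eq$fit$p_age, p_edu = eq$fit$p_edu)
  }
  if (!length(rows)) stop("all candidate pairs produced singular fits")
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  best <- report[order(report$rss), ][1, ]
  list(age_family = best$age_family, edu_family = best$edu_family,
       equation = eqs[[paste(best$age_family, best$edu_family, sep = "+")]],
       report = report)
}

#' Demographically adjusted score
#'
#' `AS = RS + age term + education term`, unrounded; rounding happens only at
#' presentation. Affine in the raw score with unit slope.
#'
#' @param raw Raw score(s).
#' @param age,education Years (vectorised with `raw`).
#' @param eq A `fab_equation`.
#' @return Adjusted score(s), full precision.
#' @export
adjust_score <- function(raw, age, education, eq) {
  stopifnot(inherits(eq, "fab_equation"))
  raw +
    eq$age$coef * eval_transform(eq$age$spec, age) +
    eq$education$coef * eval_transform(eq$education$spec, education)
}

# Half-up (away from zero at .5) rounding used for grid display; a small
# epsilon absorbs binary-representation error in products like 0.275 * 100.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Age-by-education adjustment grid
#'
#' Tabulates the adjustment factor (the correction added to a raw score of 0)
#' over integer lattices of age and education, rounded half-up at the stated
#' precision. Grids are a display convenience: scoring uses the continuous
#' equation.
#'
#' @param eq A `fab_equation`.
#' @param ages,educations Lattice vectors; defaults are ages 35 to 95 in
#'   steps of 5 and education 5, 8, 11, 13, 16, 18, 21 years.
#' @param decimals Display precision (default 2).
#' @return Matrix of class `fab_grid` with educations as rows and ages as
#'   columns.
#' @export
generate_grid <- function(eq, ages = seq(35, 95, by = 5),
                          educations = c(5, 8, 11, 13, 16, 18, 21),
                          decimals = 2) {
  if (!length(ages) || !length(educations)) stop("empty lattice")
  adj <- outer(educations, ages,
               function(e, a) adjust_score(0, a, e, eq))
  g <- round_half_up(adj, decimals)
  dimnames(g) <- list(education = as.character(educations),
                      age = as.character(ages))
  structure(g, class = c("fab_grid", class(g)), scale = eq$scale,
            decimals = decimals)
}

#' Compare a generated grid with a reference grid
#'
#' Cell-by-cell comparison at a tolerance; mismatching cells are reported
#' with both values. Cells that are `NA` in the reference (unreadable or
#' known-anomalous print cells) are skipped.
#'
#' @param grid A `fab_grid`.
#' @param reference Matrix with identical dimnames.
#' @param tol Allowed absolute difference (default 0.01, one display unit).
#' @return List with `n_compared`, `n_matched`, `match_rate` and a
#'   `mismatches` data frame.
#' @export
compare_grid <- function(grid, reference, tol = 0.01) {
  stopifnot(identical(dim(grid), dim(reference)))
  keep <- !is.na(reference)
  diff <- abs(grid - reference)
  bad <- which(keep & diff > tol + 1e-9, arr.ind = TRUE)
  mism <- data.frame(
    education = rownames(grid)[bad[, 1]], age = colnames(grid)[bad[, 2]],
    generated = grid[bad], reference = reference[bad])
  list(n_compared = sum(keep), n_matched = sum(keep) - nrow(mism),
       match_rate = (sum(keep) - nrow(mism)) / sum(keep),
       mismatches = mism)
}
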