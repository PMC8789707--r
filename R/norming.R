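# Non-parametric tolerance limits and Equivalent Score construction.

ES_LABELS <- c("0" = "abnormal", "1" = "borderline", "2" = "low-end normal",
               "3" = "normal", "4" = "normal")

#' Equivalent Score labels
#'
#' Clinical labels of the five ES levels: 0 abnormal, 1 borderline,
#' 2 low-end normal, 3 and 4 normal (4 marking scores above the median).
#'
#' @return Named character vector over levels "0".."4".
#' @export
es_labels <- function() ES_LABELS

#' Tolerance-limit ranks for the population 5th centile
#'
#' Order-statistic ranks giving one-sided non-parametric confidence bounds on
#' a population centile. The outer rank `r` is the largest integer with
#' `P(Binomial(n, centile) >= r) >= confidence`: the r-th smallest adjusted
#' score is then a lower confidence bound on the population centile (an
#' observation at or below it is confidently below the centile, i.e.
#' abnormal). The inner rank `s` is the smallest integer with
#' `P(Binomial(n, centile) >= s) <= 1 - confidence` (an upper confidence
#' bound); scores between the two limits are of uncertain classification.
#'
#' @param n Sample size.
#' @param centile Population centile bounded (default 0.05).
#' @param confidence One-sided confidence level (default 0.95).
#' @return List with `outer` (NA when no rank achieves the confidence at this
#'   `n`), `inner`, `n`, `centile`, `confidence`.
#' @examples
#' tolerance_ranks(475)   # outer 16, inner 33
#' @export
tolerance_ranks <- function(n, centile = 0.05, confidence = 0.95) {
  stopifnot(n >= 1)
  if (centile <= 0 || centile >= 1 || confidence <= 0 || confidence >= 1)
    stop("centile and confidence must lie strictly in (0, 1)")
  r <- 1:n
  # P(Bin(n, p) >= r) for each candidate rank
  upper_tail <- stats::pbinom(r - 1L, n, centile, lower.tail = FALSE)
  outer_ok <- which(upper_tail >= confidence)
  inner_ok <- which(upper_tail <= 1 - confidence)
  list(outer = if (length(outer_ok)) max(outer_ok) else NA_integer_,
       inner = if (length(inner_ok)) min(inner_ok) else NA_integer_,
       n = n, centile = centile, confidence = confidence)
}

#' Norm table: tolerance limits and ES interval boundaries
#'
#' Builds the ES scaffold from a sample of adjusted scores: the outer and
#' inner tolerance limits (order statistics at the [tolerance_ranks()]
#' ranks), the sample median, and two inner thresholds `t1 < t2` splitting
#' the outer-limit-to-median region into ES 1/2/3.
#'
#' Two threshold schemes are available. `"z_thirds"` (default) places t1 and
#' t2 at the empirical centiles corresponding to equal thirds of the standard
#' normal interval `[z(centile), 0]` (for the 5th centile: the 13.64% and
#' 29.18% centiles). `"equal_frequency"` places them so the three ES bands
#' hold equal numbers of observations between the outer rank and the median
#' rank.
#'
#' @param adjusted_scores Numeric vector of adjusted scores.
#' @param scale Scale name recorded in the table.
#' @param scheme `"z_thirds"` or `"equal_frequency"`.
#' @param precision Display precision in decimals (default 2).
#' @param centile,confidence Passed to [tolerance_ranks()].
#' @return Object of class `fab_norm_table` with fields `scale`, `n`, `oTL`,
#'   `iTL`, `median`, `t1`, `t2`, `scheme`, `precision`, `degenerate`.
#' @export
compute_norm_table <- function(adjusted_scores, scale = "fab",
                               scheme = c("z_thirds", "equal_frequency"),
                               precision = 2,
                               centile = 0.05, confidence = 0.95) {
  scheme <- match.arg(scheme)
  x <- sort(adjusted_scores[!is.na(adjusted_scores)])
  n <- length(x)
  rk <- tolerance_ranks(n, centile, confidence)
  if (is.na(rk$outer))
    stop(sprintf("norms not derivable at n = %d: no outer tolerance rank reaches %.0f%% confidence",
                 n, 100 * confidence))
  oTL <- x[rk$outer]
  iTL <- x[rk$inner]
  med <- stats::median(x)
  if (scheme == "z_thirds") {
    zc <- stats::qnorm(centile)
    cents <- stats::pnorm(zc * c(2, 1) / 3)
    # type-1 (inverse ECDF) quantiles: thresholds are observed order statistics
    t1 <- stats::quantile(x, cents[1], type = 1, names = FALSE)
    t2 <- stats::quantile(x, cents[2], type = 1, names = FALSE)
  } else {
    med_rank <- ceiling(n / 2)
    ranks <- rk$outer + round((med_rank - rk$outer) * c(1, 2) / 3)
    t1 <- x[ranks[1]]; t2 <- x[ranks[2]]
  }
  # enforce ordering under heavy ties
  t1 <- max(oTL, t1); t2 <- max(t1, t2); med <- max(t2, med)
  structure(list(scale = scale, n = n, oTL = oTL, iTL = iTL, median = med,
                 t1 = t1, t2 = t2, scheme = scheme, precision = precision,
                 centile = centile, confidence = confidence,
                 degenerate = oTL == med),
            class = "fab_norm_table")
}

#' Construct a norm table from known boundaries
#'
#' Used for published tables whose boundaries are known at display precision.
#'
#' @param scale Scale name.
#' @param oTL,iTL,t1,t2,median Boundary values (right-closed interval tops
#'   for ES 0, 1, 2 and 3 respectively; `iTL` is informational).
#' @param precision Display precision.
#' @param n Sample size behind the table, if known.
#' @return A `fab_norm_table`.
#' @export
norm_table <- function(scale, oTL, iTL, t1, t2, median, precision = 2,
                       n = NA_integer_) {
  stopifnot(oTL <= t1, t1 <= t2, t2 <= median, oTL <= iTL)
  structure(list(scale = scale, n = n, oTL = oTL, iTL = iTL, median = median,
                 t1 = t1, t2 = t2, scheme = "published", precision = precision,
                 centile = 0.05, confidence = 0.95, degenerate = oTL == median),
            class = "fab_norm_table")
}

#' @export
print.fab_norm_table <- function(x, ...) {
  p <- x$precision
  f <- function(v) formatC(v, format = "f", digits = p)
  step <- 10^-p
  cat(sprintf("<fab_norm_table> %s (n = %s, scheme = %s)\n", x$scale,
              ifelse(is.na(x$n), "?", x$n), x$scheme))
  cat(sprintf("  oTL = %s, iTL = %s, median = %s\n", f(x$oTL), f(x$iTL), f(x$median)))
  cat(sprintf("  ES0 <= %s | ES1 %s-%s | ES2 %s-%s | ES3 %s-%s | ES4 >= %s\n",
              f(x$oTL), f(x$oTL + step), f(x$t1), f(x$t1 + step), f(x$t2),
              f(x$t2 + step), f(x$median), f(x$median + step)))
  invisible(x)
}

#' Classify an adjusted score into an Equivalent Score
#'
#' Total over the reals: ES 0 for `AS <= oTL`; ES 1, 2, 3 over the
#' right-closed bands up to `t1`, `t2` and the median; ES 4 strictly above
#' the median.
#'
#' @param AS Adjusted score(s).
#' @param table A `fab_norm_table`.
#' @return Integer vector of ES levels 0--4 with a `labels` attribute.
#' @examples
#' tab <- norm_table("fab", 12.02, 13.16, 13.71, 15.10, 16.24)
#' classify_es(c(12.02, 14.00, 16.24, 16.25), tab)
#' @export
classify_es <- function(AS, table) {
  stopifnot(inherits(table, "fab_norm_table"))
  lv <- ifelse(AS <= table$oTL, 0L,
        ifelse(AS <= table$t1, 1L,
        ifelse(AS <= table$t2, 2L,
        ifelse(AS <= table$median, 3L, 4L))))
  attr(lv, "labels") <- unname(ES_LABELS[as.character(lv)])
  lv
}
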