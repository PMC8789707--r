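#' @keywords internal
"_PACKAGE"

# Canonical cohort columns (CSV schema): one row per participant.
COHORT_COLUMNS <- c("id", "sex", "age", "education",
                    paste0("fab", 1:6),
                    "moca_total", "moca_ef", "moca_a", "moca_l",
                    "moca_m", "moca_vs", "moca_o")

MOCA_SUB_COLUMNS <- c("moca_ef", "moca_a", "moca_l", "moca_m", "moca_vs", "moca_o")

#' Default MoCA sub-domain maxima
#'
#' Maximum attainable points per MoCA sub-domain under the usual sectioning
#' (executive: trail-making, fluency, abstraction; attention; language:
#' naming, repetition; memory: delayed recall; visuospatial: cube and clock;
#' orientation). The six maxima sum to the MoCA total of 30. Override when a
#' different sectioning is in use.
#'
#' @return Named integer vector over `EF, A, L, M, VS, O`.
#' @export
moca_domain_maxima <- function() {
  c(EF = 4L, A = 6L, L = 5L, M = 5L, VS = 4L, O = 6L)
}

new_cohort <- function(df, provenance = "unspecified") {
  rownames(df) <- NULL
  structure(df, class = c("fab_cohort", "data.frame"), provenance = provenance)
}

#' Validate cohort rows against the domain invariants
#'
#' Checks demographics (18--110 years of age; at least one year of education,
#' required by the logarithmic and reciprocal education transforms), FAB item
#' ranges (0--3), MoCA total (0--30) and MoCA sub-domain maxima. MoCA fields
#' may be missing (`NA`): such records remain usable for FAB norming and are
#' only excluded pairwise from correlation analyses.
#'
#' @param df Data frame in the canonical cohort layout.
#' @param moca_max Named maxima per MoCA sub-domain, see [moca_domain_maxima()].
#' @return Data frame of diagnostics with columns `row`, `field`, `problem`;
#'   zero rows when the cohort is valid.
#' @export
validate_cohort <- function(df, moca_max = moca_domain_maxima()) {
  bad <- list()
  flag <- function(rows, field, problem) {
    if (any(rows)) bad[[length(bad) + 1L]] <<-
        data.frame(row = which(rows), field = field, problem = problem)
  }
  flag(is.na(df$id) | !nzchar(as.character(df$id)), "id", "missing id")
  flag(duplicated(df$id), "id", "duplicated id")
  flag(!(as.character(df$sex) %in% c("F", "M")), "sex", "sex must be F or M")
  flag(is.na(df$age) | df$age < 18 | df$age > 110, "age", "age outside [18, 110]")
  flag(is.na(df$education) | df$education < 1, "education",
       "education must be >= 1 year")
  for (i in 1:6) {
    v <- df[[paste0("fab", i)]]
    flag(is.na(v) | v < 0 | v > 3, paste0("fab", i), "item score outside [0, 3]")
  }
  flag(!is.na(df$moca_total) & (df$moca_total < 0 | df$moca_total > 30),
       "moca_total", "MoCA total outside [0, 30]")
  doms <- c(moca_ef = "EF", moca_a = "A", moca_l = "L",
            moca_m = "M", moca_vs = "VS", moca_o = "O")
  for (col in names(doms)) {
    v <- df[[col]]
    mx <- moca_max[[doms[[col]]]]
    flag(!is.na(v) & (v < 0 | v > mx), col,
         sprintf("sub-score outside [0, %d]", mx))
  }
  if (!length(bad))
    return(data.frame(row = integer(), field = character(), problem = character()))
  out <- do.call(rbind, bad)
  out[order(out$row), , drop = FALSE]
}

#' Read a cohort CSV
#'
#' Expects a comma-separated, UTF-8 file with header. Column names may be
#' remapped through `schema` (a named character vector from canonical name to
#' the name used in the file). Rows violating the domain invariants abort the
#' read with row-indexed diagnostics.
#'
#' @param path CSV file path.
#' @param schema Optional canonical-to-file column-name map.
#' @param moca_max MoCA sub-domain maxima, see [moca_domain_maxima()].
#' @return A `fab_cohort` data frame.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, schema = NULL, moca_max = moca_domain_maxima()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    pos <- match(unname(schema), names(df))
    if (anyNA(pos))
      stop("schema refers to absent columns: ",
           paste(unname(schema)[is.na(pos)], collapse = ", "))
    names(df)[pos] <- names(schema)
  }
  missing <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  df <- df[COHORT_COLUMNS]
  df$id <- as.character(df$id)
  df$sex <- factor(as.character(df$sex), levels = c("F", "M"))
  num_cols <- setdiff(COHORT_COLUMNS, c("id", "sex"))
  df[num_cols] <- lapply(df[num_cols], function(x) as.integer(x))
  diag <- validate_cohort(df, moca_max)
  if (nrow(diag)) {
    shown <- utils::head(diag, 10)
    stop("invalid cohort rows:\n",
         paste(sprintf("  row %d, %s: %s", shown$row, shown$field, shown$problem),
               collapse = "\n"),
         if (nrow(diag) > 10) sprintf("\n  ... and %d more", nrow(diag) - 10))
  }
  new_cohort(df, provenance = path)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: a written cohort reads back field-for-field
#' identical.
#'
#' @param cohort A `fab_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.fab_cohort <- function(x, ...) {
  cat(sprintf("<fab_cohort> %d participants (provenance: %s)\n",
              nrow(x), attr(x, "provenance")))
  NextMethod()
}

# --- stratification ---------------------------------------------------------

default_age_breaks <- function() c(-Inf, 35, 45, 55, 65, 75, 85, 95, Inf)
default_edu_breaks <- function() c(-Inf, 5, 11, 16, 21, Inf)

bin_labels <- function(breaks) {
  n <- length(breaks) - 1L
  lab <- character(n)
  for (i in seq_len(n)) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    lab[i] <- if (is.infinite(lo)) sprintf("<=%g", hi)
      else if (is.infinite(hi)) sprintf(">%g", lo)
      else sprintf("%g-%g", lo + 1, hi)
  }
  lab
}

#' Sex-by-demographics stratification table
#'
#' Counts males and females in each age-by-education cell. Default bins
#' follow the usual normative presentation (age up to 35 then decades to 95
#' and beyond; education bands up to 5, 6--11, 12--16, 17--21, beyond 21
#' completed years).
#'
#' @param cohort A `fab_cohort`.
#' @param age_breaks,edu_breaks Strictly increasing numeric break vectors
#'   (right-closed intervals; use `-Inf`/`Inf` for open ends).
#' @return A 3-way contingency table `sex x age x education` of class
#'   `fab_stratification`; cell counts sum to `nrow(cohort)`.
#' @export
stratification_table <- function(cohort,
                                 age_breaks = default_age_breaks(),
                                 edu_breaks = default_edu_breaks()) {
  for (b in list(age_breaks, edu_breaks))
    if (is.unsorted(b, strictly = TRUE))
      stop("breaks must be strictly increasing (overlapping bins are not allowed)")
  age_bin <- cut(cohort$age, age_breaks, labels = bin_labels(age_breaks),
                 right = TRUE)
  edu_bin <- cut(cohort$education, edu_breaks, labels = bin_labels(edu_breaks),
                 right = TRUE)
  sex <- factor(as.character(cohort$sex), levels = c("M", "F"))
  tab <- table(sex = sex, age = age_bin, education = edu_bin)
  class(tab) <- c("fab_stratification", class(tab))
  tab
}

#' @export
print.fab_stratification <- function(x, ...) {
  m <- x["M", , ]; f <- x["F", , ]
  cells <- matrix(sprintf("%d/%d", t(m), t(f)), nrow = dim(x)[3],
                  dimnames = list(education = dimnames(x)$education,
                                  age = dimnames(x)$age))
  cat("M/F counts per education (rows) x age (columns) cell\n")
  print(cells, quote = FALSE)
  invisible(x)
}

# --- descriptives and the normality screen ----------------------------------

# Central sample moments about the mean.
central_moment <- function(x, k) mean((x - mean(x))^k)

# Adjusted Fisher-Pearson skewness (the SPSS/Excel G1 statistic).
sample_skewness <- function(x) {
  n <- length(x)
  m2 <- central_moment(x, 2)
  if (m2 == 0) return(NaN)
  g1 <- central_moment(x, 3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# Moment kurtosis b2 = m4/m2^2 ("raw"); the normal reference value is 3.
sample_kurtosis <- function(x, convention = c("excess", "raw")) {
  convention <- match.arg(convention)
  m2 <- central_moment(x, 2)
  if (m2 == 0) return(NaN)
  b2 <- central_moment(x, 4) / m2^2
  if (convention == "excess") b2 - 3 else b2
}

#' Screen a variable for distributional abnormality
#'
#' Flags a sample as distributionally abnormal when `|skewness| >=
#' skew_threshold` or `|kurtosis statistic| >= kurt_threshold` (defaults 1
#' and 3). Skewness is the adjusted Fisher--Pearson statistic. Two kurtosis
#' conventions are supported: `"excess"` (moment kurtosis minus 3, the value
#' statistical packages print, default) and `"raw"` (moment kurtosis itself,
#' for screens stated in raw terms). A zero-variance input yields a
#' degenerate result with `NaN` statistics rather than an error.
#'
#' @param values Numeric vector, `length >= 3`.
#' @param skew_threshold,kurt_threshold Abnormality thresholds.
#' @param kurtosis Kurtosis convention, `"excess"` or `"raw"`.
#' @return List with `skewness`, `kurtosis`, `kurtosis_convention`,
#'   `abnormal`, `degenerate`.
#' @examples
#' normality_screen(c(-2, -1, 0, 1, 2))   # symmetric, not abnormal
#' normality_screen(c(0, 0, 0, 0, 10))    # skewness sqrt(5), abnormal
#' @export
normality_screen <- function(values, skew_threshold = 1, kurt_threshold = 3,
                             kurtosis = c("excess", "raw")) {
  kurtosis <- match.arg(kurtosis)
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("normality screen needs at least 3 observations")
  sk <- sample_skewness(values)
  ku <- sample_kurtosis(values, kurtosis)
  degenerate <- is.nan(sk)
  list(skewness = sk, kurtosis = ku, kurtosis_convention = kurtosis,
       abnormal = if (degenerate) NA else
         (abs(sk) >= skew_threshold) || (abs(ku) >= kurt_threshold),
       degenerate = degenerate)
}

#' Descriptive summary of cohort variables
#'
#' Per-variable n, mean, standard deviation, range, skewness and kurtosis
#' (excess convention; see [normality_screen()]). Derived scale scores
#' (`fab`, `fab1`, `fab2`, `fab3`) are recognised alongside raw columns.
#'
#' @param cohort A `fab_cohort`.
#' @param variables Character vector of variable names; defaults to the
#'   background and cognitive variables usually tabulated.
#' @return Data frame with one row per variable.
#' @export
descriptives <- function(cohort,
                         variables = c("age", "education", "moca_total",
                                       "fab", "fab1", "fab2", "fab3")) {
  if (nrow(cohort) < 2) stop("descriptives need at least 2 rows (sd undefined)")
  scales <- fab_scales()
  one <- function(v) {
    x <- if (v %in% names(scales)) scale_scores(cohort, scales[[v]])
         else if (v %in% names(cohort)) cohort[[v]]
         else stop("unknown variable: ", v)
    x <- x[!is.na(x)]
    data.frame(variable = v, n = length(x), mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x),
               skewness = sample_skewness(x),
               kurtosis = sample_kurtosis(x, "excess"))
  }
  out <- do.call(rbind, lapply(variables, one))
  rownames(out) <- NULL
  out
}
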