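# Published Italian adult norms for the FAB and its sub-scales, shipped as
# versioned data: four adjustment equations and four ES tables.

published_norms_path <- function()
  system.file("extdata", "published_norms.json", package = "fabnorms",
              mustWork = TRUE)

# md5 of the checked-in norms file; guards against accidental edits.
PUBLISHED_NORMS_MD5 <- "bd36ed7f51e53dc03cfc4948eeb77d54"

#' Load the published norm set
#'
#' Reads the checked-in norms file (adjustment-equation coefficients and
#' centering constants; ES interval boundaries per scale) and verifies its
#' checksum before constructing the equation and table objects.
#'
#' @param path Norms JSON path; defaults to the file shipped with the package.
#' @param verify Set to `FALSE` to skip the integrity check (e.g. for a
#'   user-supplied norm file).
#' @return List with `equations` (named `fab_equation` list), `tables`
#'   (named `fab_norm_table` list) and `provenance`.
#' @examples
#' norms <- load_published_norms()
#' norms$tables$fab$oTL   # 12.02
#' @export
load_published_norms <- function(path = published_norms_path(), verify = missing(path)) {
  if (verify) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, PUBLISHED_NORMS_MD5))
      stop("published norms file failed its integrity check (md5 ", md5, ")")
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  eqs <- lapply(raw$equations, function(e)
    adjustment_equation(e$scale,
      transform_spec("age", e$age$family, e$age$center), e$age$coef,
      transform_spec("education", e$education$family, e$education$center),
      e$education$coef))
  tabs <- lapply(raw$tables, function(t)
    norm_table(t$scale, t$oTL, t$iTL, t$t1, t$t2, t$median,
               precision = t$precision, n = t$n))
  names(eqs) <- vapply(eqs, `[[`, "", "scale")
  names(tabs) <- vapply(tabs, `[[`, "", "scale")
  list(equations = eqs, tables = tabs, provenance = raw$provenance)
}

#' Published adjustment grids as printed
#'
#' The age-by-education adjustment grids accompanying the published
#' equations, transcribed at display precision for verification. Cells that
#' are unreadable or known typesetting anomalies are `NA`; the anomaly log
#' lists them with the printed value where one exists.
#'
#' @return List with `grids` (named list of education-by-age matrices) and
#'   `anomalies` (data frame `scale, education, age, printed, note`).
#' @export
published_grids <- function() {
  dir <- system.file("extdata", package = "fabnorms", mustWork = TRUE)
  read_grid <- function(scale) {
    df <- utils::read.csv(file.path(dir, paste0("grid_", scale, ".csv")),
                          check.names = FALSE)
    m <- as.matrix(df[-1])
    dimnames(m) <- list(education = as.character(df$education),
                        age = colnames(df)[-1])
    m
  }
  grids <- sapply(c("fab", "fab1", "fab2", "fab3"), read_grid,
                  simplify = FALSE)
  anomalies <- utils::read.csv(file.path(dir, "grid_anomalies.csv"))
  list(grids = grids, anomalies = anomalies)
}

#' Score one subject against a norm set
#'
#' Computes raw, adjusted and Equivalent Scores for the FAB total and the
#' three sub-scales. Demographics outside the grid extent (ages 35--95,
#' education 5--21) are scored through the continuous equations with a
#' warning recorded in the report.
#'
#' @param age,education Years.
#' @param fab_items Length-6 integer vector of item scores (0--3), or `NULL`
#'   when `raw` is given.
#' @param raw Named numeric vector of per-scale raw scores (`fab`, `fab1`,
#'   `fab2`, `fab3`), used when item scores are unavailable; missing scales
#'   are skipped.
#' @param norms A norm set from [load_published_norms()].
#' @return Data frame of class `fab_subject_report`, one row per scale, with
#'   `raw`, `adjusted`, `es`, `label`; demographics and warnings as
#'   attributes.
#' @examples
#' score_subject(age = 75, education = 5, raw = c(fab = 14))
#' @export
score_subject <- function(age, education, fab_items = NULL, raw = NULL,
                          norms = load_published_norms()) {
  stopifnot(length(age) == 1, length(education) == 1)
  if (age < 18 || age > 110) stop("age outside supported domain [18, 110]")
  if (education < 1) stop("education must be >= 1 year")
  if (is.null(fab_items) && is.null(raw))
    stop("provide fab_items or per-scale raw scores")
  if (!is.null(fab_items)) {
    if (length(fab_items) != 6 || any(is.na(fab_items)) ||
        any(fab_items < 0 | fab_items > 3))
      stop("fab_items must be 6 scores in [0, 3]")
    row <- as.data.frame(as.list(stats::setNames(fab_items, paste0("fab", 1:6))))
    raw <- vapply(fab_scales(), function(s) scale_scores(row, s)[1], 0L)
  }
  warnings <- character()
  if (age < 35 || age > 95)
    warnings <- c(warnings, "age outside the 35-95 grid extent; continuous equation used")
  if (education < 5 || education > 21)
    warnings <- c(warnings, "education outside the 5-21 grid extent; continuous equation used")
  scales <- intersect(names(norms$equations), names(raw))
  rows <- lapply(scales, function(s) {
    rng <- fab_scales()[[s]]
    if (raw[[s]] < rng$min_score || raw[[s]] > rng$max_score)
      stop(sprintf("raw %s score %g outside [%d, %d]", s, raw[[s]],
                   rng$min_score, rng$max_score))
    AS <- adjust_score(raw[[s]], age, education, norms$equations[[s]])
    es <- classify_es(AS, norms$tables[[s]])
    data.frame(scale = s, raw = raw[[s]], adjusted = AS,
               es = as.integer(es), label = attr(es, "labels"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("fab_subject_report", "data.frame"),
            age = age, education = education, warnings = warnings)
}

#' @export
print.fab_subject_report <- function(x, ...) {
  cat(sprintf("FAB report: age %g, education %g\n",
              attr(x, "age"), attr(x, "education")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-5s raw %2g -> adjusted %5.2f -> ES %d (%s)\n",
                x$scale[i], x$raw[i], x$adjusted[i], x$es[i], x$label[i]))
  for (w in attr(x, "warnings")) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Score a whole cohort
#'
#' One report row per subject; rows failing validation are reported in the
#' `failures` attribute and the run continues.
#'
#' @param cohort A `fab_cohort`, a data frame in the cohort layout, or a CSV
#'   path.
#' @param norms A norm set from [load_published_norms()].
#' @param out Optional CSV path for the report.
#' @return Data frame with demographics and, per scale, raw/adjusted/ES
#'   columns; attribute `failures` holds row-indexed diagnostics.
#' @export
batch_score <- function(cohort, norms = load_published_norms(), out = NULL) {
  if (is.character(cohort))
    cohort <- utils::read.csv(cohort, stringsAsFactors = FALSE)
  df <- as.data.frame(cohort)
  need <- c("id", "sex", "age", "education", paste0("fab", 1:6))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  diag <- if (nrow(df)) {
    probe <- df
    for (col in setdiff(COHORT_COLUMNS, names(probe))) probe[[col]] <- NA_integer_
    validate_cohort(probe[COHORT_COLUMNS])
  } else data.frame(row = integer(), field = character(), problem = character())
  ok <- setdiff(seq_len(nrow(df)), unique(diag$row))
  base <- df[ok, c("id", "sex", "age", "education")]
  scales <- fab_scales()
  for (s in names(scales)) {
    raw <- if (length(ok)) scale_scores(df[ok, , drop = FALSE], scales[[s]]) else integer()
    AS <- if (length(ok))
      adjust_score(raw, df$age[ok], df$education[ok], norms$equations[[s]])
      else numeric()
    es <- if (length(ok)) as.integer(classify_es(AS, norms$tables[[s]])) else integer()
    base[[paste0("raw_", s)]] <- raw
    base[[paste0("as_", s)]] <- round(AS, 2)
    base[[paste0("es_", s)]] <- es
  }
  rownames(base) <- NULL
  if (!is.null(out))
    utils::write.csv(base, out, row.names = FALSE, quote = FALSE)
  structure(base, failures = diag)
}
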