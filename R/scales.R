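#' Scale definitions for the FAB and its sub-scales
#'
#' The Frontal Assessment Battery has six items, each scored 0--3. The total
#' scale sums all six (range 0--18); three two-item sub-scales cover
#' linguistically mediated executive functioning (items 1--2, similarities and
#' phonemic fluency), planning (items 3--4, Luria motor sequences and
#' conflicting instructions) and inhibition (items 5--6, go--no-go and
#' prehension behaviour), each with range 0--6.
#'
#' @param name Scale name, one of `"fab"`, `"fab1"`, `"fab2"`, `"fab3"`.
#' @param item_indices Integer vector of item positions (subset of 1..6).
#' @param min_score,max_score Attainable raw-score range.
#' @return An object of class `fab_scale`.
#' @examples
#' scale_definition("fab1", 1:2)
#' @export
scale_definition <- function(name, item_indices,
                             min_score = 0L,
                             max_score = 3L * length(item_indices)) {
  item_indices <- as.integer(item_indices)
  stopifnot(length(item_indices) >= 1, all(item_indices %in% 1:6),
            !anyDuplicated(item_indices), min_score <= max_score)
  structure(list(name = name, item_indices = sort(item_indices),
                 min_score = as.integer(min_score),
                 max_score = as.integer(max_score)),
            class = "fab_scale")
}

#' @rdname scale_definition
#' @return `fab_scales()` returns a named list of the four standard scales.
#' @export
fab_scales <- function() {
  list(fab  = scale_definition("fab",  1:6),
       fab1 = scale_definition("fab1", 1:2),
       fab2 = scale_definition("fab2", 3:4),
       fab3 = scale_definition("fab3", 5:6))
}

#' @export
print.fab_scale <- function(x, ...) {
  cat(sprintf("<fab_scale> %s: items %s, range %d-%d\n", x$name,
              paste(x$item_indices, collapse = ","), x$min_score, x$max_score))
  invisible(x)
}

#' Raw scale scores
#'
#' Sums the item scores belonging to a scale. The three sub-scale scores
#' always partition the total: `fab1 + fab2 + fab3 == fab`.
#'
#' @param cohort A `fab_cohort` (or any data frame with columns `fab1..fab6`).
#' @param scale A `fab_scale`, or a name understood by [fab_scales()].
#' @return Integer vector of raw scores, one per row.
#' @examples
#' coh <- generate_cohort(default_generator_config(n = 5, seed = 1))
#' scale_scores(coh, "fab")
#' @export
scale_scores <- function(cohort, scale) {
  if (is.character(scale)) scale <- fab_scales()[[match.arg(scale, names(fab_scales()))]]
  stopifnot(inherits(scale, "fab_scale"))
  cols <- paste0("fab", scale$item_indices)
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    stop("cohort lacks item columns: ", paste(missing, collapse = ", "))
  items <- as.matrix(cohort[cols])
  as.integer(rowSums(items))
}
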