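# Hand-buildable cohort rows for unit tests.

cohort_row <- function(id = "P1", sex = "F", age = 60, education = 10,
                       items = c(3, 3, 3, 3, 3, 3), moca_total = 25,
                       moca = c(moca_ef = 3, moca_a = 5, moca_l = 4,
                                moca_m = 4, moca_vs = 3, moca_o = 6)) {
  row <- data.frame(id = id, sex = sex, age = age, education = education)
  for (i in 1:6) row[[paste0("fab", i)]] <- items[i]
  row$moca_total <- moca_total
  for (nm in names(moca)) row[[nm]] <- moca[[nm]]
  row
}

make_cohort <- function(rows) {
  df <- do.call(rbind, rows)
  df$sex <- factor(df$sex, levels = c("F", "M"))
  structure(df, class = c("fab_cohort", "data.frame"), provenance = "test")
}

# A tiny deterministic 4-person cohort spanning bins.
four_person_cohort <- function() {
  make_cohort(list(
    cohort_row("A", "F", 30, 4,  c(2, 3, 1, 2, 0, 3)),
    cohort_row("B", "M", 30, 4,  c(1, 1, 1, 1, 1, 1)),
    cohort_row("C", "F", 70, 12, c(3, 3, 3, 3, 3, 3)),
    cohort_row("D", "M", 98, 25, c(0, 0, 0, 0, 0, 0))))
}
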