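#' Two-proportion chi-squared test on library-normalized counts
#'
#' Compares the number of small RNA reads mapping to a locus between two
#' conditions, each normalized to its library size, via the 2x2 table
#' `[mapped, library - mapped] x [A, B]` with 1 degree of freedom. Yates
#' continuity correction (|O - E| reduced by 0.5, floored at 0) is applied
#' by default.
#'
#' @param mapped_a,library_a Mapped and total library counts, condition A.
#' @param mapped_b,library_b Same for condition B.
#' @param continuity_correction Apply Yates correction (default `TRUE`).
#' @param locus_id Optional locus label carried into the result.
#' @return List of class `count_test`: `locus_id`, the four input counts,
#'   `statistic`, `df` (always 1), `p_value`, `percent_a`, `percent_b`
#'   (mapped / library x 100).
#' @export
#' @examples
#' proportion_chisq(36, 19193551, 160, 19167336)
proportion_chisq <- function(mapped_a, library_a, mapped_b, library_b,
                             continuity_correction = TRUE,
                             locus_id = NA_character_) {
  counts <- c(mapped_a, library_a, mapped_b, library_b)
  assert_that(all(counts >= 0) && all(is.finite(counts)),
              "counts must be non-negative finite numbers")
  assert_that(library_a > 0 && library_b > 0,
              "library sizes must be positive")
  assert_that(mapped_a <= library_a && mapped_b <= library_b,
              "mapped reads cannot exceed the library size")
  tab <- matrix(c(mapped_a, library_a - mapped_a,
                  mapped_b, library_b - mapped_b), nrow = 2)
  if (mapped_a + mapped_b == 0) {
    warning("no mapped reads in either condition; statistic is 0")
    stat <- 0
  } else {
    stat <- unname(suppressWarnings(
      stats::chisq.test(tab, correct = continuity_correction)$statistic))
  }
  structure(list(locus_id = locus_id,
                 mapped_a = mapped_a, library_a = library_a,
                 mapped_b = mapped_b, library_b = library_b,
                 statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 percent_a = normalized_percent(mapped_a, library_a),
                 percent_b = normalized_percent(mapped_b, library_b)),
            class = "count_test")
}

#' @export
print.count_test <- function(x, ...) {
  cat(sprintf(
    "<count_test%s>\n  A: %g / %g (%.4g%%)   B: %g / %g (%.4g%%)\n",
    ifelse(is.na(x$locus_id), "", paste0(" ", x$locus_id)),
    x$mapped_a, x$library_a, x$percent_a,
    x$mapped_b, x$library_b, x$percent_b))
  cat(sprintf("  Chi-squared = %.4g, df = %d, p-value %s\n", x$statistic,
              x$df, format.pval(x$p_value, digits = 4)))
  invisible(x)
}

#' Percentage of library-normalized reads
#'
#' @param mapped Reads mapping to the locus.
#' @param library Total library size (> 0).
#' @return `mapped / library * 100`.
#' @export
normalized_percent <- function(mapped, library) {
  assert_that(all(library > 0), "library size must be positive")
  mapped / library * 100
}

#' Run the count test over a locus table
#'
#' @param loci data.frame with `locus_id`, `mapped_a`, `library_a`,
#'   `mapped_b`, `library_b`.
#' @inheritParams proportion_chisq
#' @return data.frame with `statistic`, `df`, `p_value`, `percent_a`,
#'   `percent_b` appended.
#' @export
proportion_chisq_table <- function(loci, continuity_correction = TRUE) {
  res <- lapply(seq_len(nrow(loci)), function(i) {
    ct <- proportion_chisq(loci$mapped_a[i], loci$library_a[i],
                           loci$mapped_b[i], loci$library_b[i],
                           continuity_correction = continuity_correction,
                           locus_id = loci$locus_id[i])
    data.frame(locus_id = ct$locus_id, statistic = ct$statistic, df = ct$df,
               p_value = ct$p_value, percent_a = ct$percent_a,
               percent_b = ct$percent_b, stringsAsFactors = FALSE)
  })
  cbind(loci, do.call(rbind, res)[, -1, drop = FALSE])
}
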