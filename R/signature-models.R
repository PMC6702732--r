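#' Construct a small RNA signature model
#'
#' A signature model describes the small RNA read population a contig class
#' emits: a probability mass function over read lengths (15-35 nt), the
#' fraction of reads originating from the positive strand, and how many
#' reads each contig of the class receives.
#'
#' @param name Character label for the class (e.g. `"sirna"`, `"pirna"`,
#'   `"degradation"`, `"mixed"`).
#' @param size_pmf Named numeric vector mapping read length (nt, names
#'   coercible to integers in 15..35) to probability. Must sum to 1 within
#'   `1e-9`.
#' @param positive_strand_fraction Probability in \[0, 1\] that a read maps
#'   to the positive strand.
#' @param reads_per_contig Positive integer; reads simulated per contig.
#'
#' @return An object of class `signature_model`.
#' @export
#' @examples
#' signature_model("sirna", c(`21` = 1), 0.5, 100)
signature_model <- function(name, size_pmf, positive_strand_fraction,
                            reads_per_contig) {
  assert_that(is.character(name) && length(name) == 1L && nzchar(name),
              "name must be a non-empty string")
  assert_that(is.numeric(size_pmf) && length(size_pmf) >= 1L &&
                !is.null(names(size_pmf)),
              "size_pmf must be a named numeric vector")
  sizes <- suppressWarnings(as.integer(names(size_pmf)))
  assert_that(!anyNA(sizes) && all(sizes >= 15L & sizes <= 35L),
              "size_pmf keys must be read lengths within [15, 35]")
  assert_that(!anyDuplicated(sizes), "size_pmf keys must be unique")
  assert_that(all(size_pmf >= 0), "size_pmf probabilities must be >= 0")
  assert_that(abs(sum(size_pmf) - 1) <= 1e-9,
              "size_pmf must sum to 1 (got %.12g)", sum(size_pmf))
  assert_that(is.numeric(positive_strand_fraction) &&
                length(positive_strand_fraction) == 1L &&
                positive_strand_fraction >= 0 &&
                positive_strand_fraction <= 1,
              "positive_strand_fraction must be in [0, 1]")
  assert_that(is.numeric(reads_per_contig) && length(reads_per_contig) == 1L &&
                reads_per_contig >= 1 &&
                reads_per_contig == as.integer(reads_per_contig),
              "reads_per_contig must be a positive integer count")
  structure(
    list(name = name,
         size_pmf = setNames(as.numeric(size_pmf), as.character(sizes)),
         positive_strand_fraction = positive_strand_fraction,
         reads_per_contig = as.integer(reads_per_contig)),
    class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model '%s'>\n", x$name))
  cat(sprintf("  sizes: %s nt\n",
              paste(range(as.integer(names(x$size_pmf))), collapse = "-")))
  cat(sprintf("  positive strand fraction: %.2f\n",
              x$positive_strand_fraction))
  cat(sprintf("  reads per contig: %d\n", x$reads_per_contig))
  invisible(x)
}

#' Default signature models for the three canonical small RNA classes
#'
#' The defaults encode the field's canonical signatures: `sirna` is sharply
#' enriched at 21 nt and unbiased in strand (Dicer-2 processing of dsRNA
#' replication intermediates hits both strands); `pirna` spans 23-29 nt with
#' a 27-28 nt peak and a strong negative-strand bias (the Cluster-4-like
#' pattern); `pirna_positive` is its positive-biased mirror (Cluster-1-like);
#' `degradation` is a broad, featureless 15-35 nt population with a strand
#' bias, as expected for breakdown products of an abundant transcript.
#' The exact probabilities are package calibration choices, not measured
#' values; override any model by passing your own [signature_model()].
#'
#' @param reads_per_contig Reads simulated per contig, default 1000.
#' @return Named list of `signature_model` objects
#'   (`sirna`, `pirna`, `pirna_positive`, `degradation`).
#' @export
#' @examples
#' models <- default_signature_models()
#' models$sirna
default_signature_models <- function(reads_per_contig = 1000) {
  pirna_pmf <- c(`23` = 0.05, `24` = 0.07, `25` = 0.10, `26` = 0.15,
                 `27` = 0.25, `28` = 0.25, `29` = 0.13)
  unif <- setNames(rep(1 / 21, 21), as.character(15:35))
  list(
    sirna = signature_model(
      "sirna", c(`20` = 0.10, `21` = 0.80, `22` = 0.10),
      positive_strand_fraction = 0.5, reads_per_contig = reads_per_contig),
    pirna = signature_model(
      "pirna", pirna_pmf,
      positive_strand_fraction = 0.10, reads_per_contig = reads_per_contig),
    pirna_positive = signature_model(
      "pirna_positive", pirna_pmf,
      positive_strand_fraction = 0.90, reads_per_contig = reads_per_contig),
    degradation = signature_model(
      "degradation", unif,
      positive_strand_fraction = 0.20, reads_per_contig = reads_per_contig))
}
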