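#' log2-RPKM abundance matrix
#'
#' RPKM = count x 1e9 / (contig length in nt x library size); the reported
#' value is `log2(RPKM + pseudocount)`. The default pseudocount of 1 maps
#' zero counts to 0; with `pseudocount = 0`, zero counts would be `-Inf`
#' and are clamped to `na_sentinel` for plotting.
#'
#' @param read_counts Numeric matrix, contigs x pools.
#' @param contig_lengths Named or positionally matched lengths (nt) > 0.
#' @param library_sizes Per-pool total read counts > 0.
#' @param pseudocount Added inside the log (default 1).
#' @param na_sentinel Replacement for `-Inf` when `pseudocount = 0`
#'   (default `NA`).
#' @return Matrix of log2 abundances, same dimnames as `read_counts`.
#' @export
#' @examples
#' m <- matrix(c(100, 0), 1, 2,
#'             dimnames = list("c1", c("pool1", "pool2")))
#' rpkm_matrix(m, contig_lengths = 1000, library_sizes = c(1e6, 1e6))
rpkm_matrix <- function(read_counts, contig_lengths, library_sizes,
                        pseudocount = 1, na_sentinel = NA_real_) {
  read_counts <- as.matrix(read_counts)
  assert_that(all(contig_lengths > 0), "contig lengths must be positive")
  assert_that(all(library_sizes > 0), "library sizes must be positive")
  assert_that(length(contig_lengths) == nrow(read_counts),
              "need one length per contig row")
  assert_that(length(library_sizes) == ncol(read_counts),
              "need one library size per pool column")
  rpkm <- sweep(read_counts * 1e9 / contig_lengths, 2, library_sizes, "/")
  v <- log2(rpkm + pseudocount)
  v[is.infinite(v)] <- na_sentinel
  v
}

#' Species composition with read-count and frequency filters
#'
#' Per pool, a species passes when it has at least `min_reads` reads and at
#' least `min_freq` frequency of the pool total (both inclusive). Species
#' failing either filter are pooled into a per-pool `other_fraction`, so
#' passing frequencies plus the other fraction sum to 1.
#'
#' @param species_counts data.frame with `pool_id`, `species`,
#'   `read_count` (OTU-level rows may be pre-collapsed with
#'   [collapse_otu_counts()]).
#' @param min_reads Minimum reads (default 100, inclusive).
#' @param min_freq Minimum frequency (default 0.01, inclusive).
#' @return List with `rows` (data.frame `pool_id`, `species`,
#'   `read_count`, `frequency`, `passes_filter`) and `other_fraction`
#'   (data.frame `pool_id`, `other_fraction`).
#' @export
species_composition <- function(species_counts, min_reads = 100,
                                min_freq = 0.01) {
  assert_that(all(species_counts$read_count >= 0),
              "read counts must be non-negative")
  totals <- tapply(species_counts$read_count, species_counts$pool_id, sum)
  zero <- names(totals)[totals == 0]
  assert_that(length(zero) == 0L, "pool(s) with zero total reads: %s",
              paste(zero, collapse = ", "))
  rows <- species_counts
  rows$frequency <- rows$read_count / as.numeric(totals[rows$pool_id])
  rows$passes_filter <- rows$read_count >= min_reads &
    rows$frequency >= min_freq
  other <- tapply(rows$frequency * !rows$passes_filter, rows$pool_id, sum)
  list(rows = rows,
       other_fraction = data.frame(pool_id = names(other),
                                   other_fraction = as.numeric(other),
                                   stringsAsFactors = FALSE))
}

#' Collapse OTU-level rows to species-level counts
#'
#' @param otu_counts data.frame with `pool_id`, `species`, `read_count`
#'   (one row per OTU).
#' @return data.frame summed per (pool, species).
#' @export
collapse_otu_counts <- function(otu_counts) {
  agg <- stats::aggregate(read_count ~ pool_id + species, data = otu_counts,
                          FUN = sum)
  agg[order(agg$pool_id, agg$species), , drop = FALSE]
}

#' Per-contig, per-pool read counts from alignments
#'
#' Counts each alignment once toward its contig in the pool the contig
#' belongs to; the helper that feeds [rpkm_matrix()].
#'
#' @param alignments Alignment data.frame.
#' @param contigs Contig data.frame with `pool_id`.
#' @return Integer matrix contigs x pools.
#' @export
count_matrix <- function(alignments, contigs) {
  pools <- sort(unique(contigs$pool_id))
  pool_of <- setNames(contigs$pool_id, contigs$id)
  tab <- table(factor(alignments$contig_id, levels = contigs$id),
               factor(pool_of[alignments$contig_id], levels = pools))
  matrix(as.integer(tab), nrow = nrow(contigs),
         dimnames = list(contigs$id, pools))
}
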