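#' Compute strand-specific small RNA size profiles
#'
#' For each contig, counts aligned reads into 42 cells: read length 15-35 nt
#' by strand (+/-). Each alignment increments exactly one cell; reads
#' outside 15-35 nt are excluded from both the cells and the total.
#'
#' @param alignments Alignment data.frame (TSV dialect columns).
#' @param contigs Contig data.frame; every contig gets a row (possibly all
#'   zero) and contributes its `pool_id`.
#' @return data.frame with `contig_id`, `pool_id`, `total_reads` and the 42
#'   count columns `p15..p35`, `m15..m35`.
#' @export
#' @examples
#' ctg <- data.frame(id = "c1", sequence = strrep("A", 600), length = 600,
#'                   origin_label = "virus", pool_id = "pool1")
#' aln <- data.frame(read_id = c("r1", "r2", "r3", "r4"), contig_id = "c1",
#'                   strand = c("+", "+", "-", "-"), start0 = 0L,
#'                   read_length = c(21L, 21L, 21L, 25L), mismatches = 0L)
#' compute_profiles(aln, ctg)[, c("p21", "m21", "m25", "total_reads")]
compute_profiles <- function(alignments, contigs) {
  unknown <- setdiff(unique(alignments$contig_id), contigs$id)
  assert_that(length(unknown) == 0L,
              "alignment(s) reference unknown contig(s): %s",
              paste(unknown, collapse = ", "))
  cells <- profile_cell_names()
  mat <- matrix(0L, nrow = nrow(contigs), ncol = length(cells),
                dimnames = list(contigs$id, cells))
  keep <- alignments$read_length >= min(PROFILE_SIZES) &
    alignments$read_length <= max(PROFILE_SIZES)
  a <- alignments[keep, , drop = FALSE]
  if (nrow(a)) {
    cell <- paste0(ifelse(a$strand == "+", "p", "m"), a$read_length)
    tab <- table(factor(a$contig_id, levels = contigs$id),
                 factor(cell, levels = cells))
    mat <- matrix(as.integer(tab), nrow = nrow(contigs),
                  dimnames = dimnames(mat))
  }
  out <- data.frame(contig_id = contigs$id,
                    pool_id = contigs$pool_id %||% NA_character_,
                    total_reads = as.integer(rowSums(mat)),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mat, optional = TRUE))
}

#' @rdname compute_profiles
#' @param contig A single-row contig data.frame (or one row of one).
#' @export
compute_profile <- function(alignments, contig) {
  compute_profiles(alignments[alignments$contig_id %in% contig$id, ,
                              drop = FALSE],
                   contig)
}

#' Retain profiles with enough mapped reads
#'
#' Keeps profiles with `total_reads >= min_reads` — the "at least 100
#' small RNA reads" gate (inclusive, so 100 passes and 99 fails).
#'
#' @param profiles Profile data.frame from [compute_profiles()].
#' @param min_reads Inclusive threshold (default 100).
#' @return The retained subset; a message reports how many were dropped.
#' @export
filter_profiles <- function(profiles, min_reads = 100) {
  keep <- profiles$total_reads >= min_reads
  if (any(!keep)) {
    message(sum(!keep), " profile(s) below ", min_reads, " reads removed")
  }
  out <- profiles[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' z-score normalize size profiles
#'
#' Converts each profile's 42 counts to frequencies (cell / total over the
#' in-range 15-35 nt reads) and standardizes the 42-cell vector jointly
#' across both strands to mean 0, sd 1 (population sd, divisor 42). A
#' profile whose 42 frequencies are all equal has sd 0 and is flagged
#' `degenerate` with all z-values 0.
#'
#' @param profiles Profile data.frame; every row must have
#'   `total_reads > 0` (apply [filter_profiles()] first).
#' @return data.frame with `contig_id`, `pool_id`, `degenerate` and 42
#'   z-score columns named as in the input.
#' @export
zscore_profiles <- function(profiles) {
  assert_that(nrow(profiles) == 0L || all(profiles$total_reads > 0),
              "profiles with zero mapped reads cannot be z-scored; filter first")
  cells <- profile_cell_names()
  m <- as.matrix(profiles[, cells, drop = FALSE])
  freq <- m / profiles$total_reads
  mu <- rowMeans(freq)
  # population sd over the 42 cells
  sdev <- sqrt(rowMeans((freq - mu)^2))
  degenerate <- sdev == 0
  z <- (freq - mu) / ifelse(degenerate, 1, sdev)
  z[degenerate, ] <- 0
  out <- data.frame(contig_id = profiles$contig_id,
                    pool_id = profiles$pool_id,
                    degenerate = degenerate,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  cbind(out, as.data.frame(z, optional = TRUE))
}

#' @rdname zscore_profiles
#' @param profile A single profile row.
#' @export
zscore_profile <- function(profile) {
  assert_that(nrow(profile) == 1L, "zscore_profile expects a single row")
  zscore_profiles(profile)
}

#' Positive-strand fraction of a profile
#'
#' The quantity behind "predominantly negative strand": the fraction of
#' in-range reads mapping to the positive strand.
#'
#' @param profiles Profile data.frame with `total_reads > 0`.
#' @return Numeric vector, one fraction per profile row.
#' @export
strand_fraction <- function(profiles) {
  assert_that(nrow(profiles) == 0L || all(profiles$total_reads > 0),
              "strand fraction undefined for zero-read profiles")
  pos <- rowSums(as.matrix(
    profiles[, paste0("p", PROFILE_SIZES), drop = FALSE]))
  unname(pos / profiles$total_reads)
}

# extract the n x 42 numeric matrix (rownames = contig ids) from a profile
# or z-profile data.frame
profile_matrix <- function(df) {
  m <- as.matrix(df[, profile_cell_names(), drop = FALSE])
  rownames(m) <- df$contig_id
  m
}

#' Write / read a profile matrix as TSV
#'
#' @param profiles Profile or z-profile data.frame.
#' @param path Output path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  write.table(profiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @export
read_profiles_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
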