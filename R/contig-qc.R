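#' Filter contigs by length
#'
#' Retains contigs strictly longer than `min_len_exclusive` nt — the "longer
#' than 500 nucleotides" gate, so a 500 nt contig is removed and a 501 nt
#' contig kept.
#'
#' @param contigs Contig data.frame.
#' @param min_len_exclusive Exclusive lower bound in nt (default 500).
#' @return The retained subset, rows in input order.
#' @export
filter_by_length <- function(contigs, min_len_exclusive = 500) {
  out <- contigs[contigs$length > min_len_exclusive, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise identity and coverage between two sequences
#'
#' Aligns the shorter sequence globally against the best-scoring local
#' window of the longer (match +1, mismatch -1, gap -2), in both
#' orientations, and reports the better one. Identity is matches over
#' aligned columns; coverage is aligned columns over the shorter sequence
#' length. This is the transparent desk-scale substitute for a k-mer
#' accelerated clusterer's similarity engine.
#'
#' @param a,b Nucleotide strings.
#' @return List with `identity`, `coverage`, `strand` (`+` or `-` for the
#'   reverse-complement orientation).
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) return(pairwise_identity(b, a))
  score_one <- function(shorter) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(shorter), Biostrings::DNAString(b),
      type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 0, gapExtension = 2)
    cols <- Biostrings::nchar(pa)
    list(identity = if (cols > 0) Biostrings::nmatch(pa) / cols else 0,
         coverage = cols / nchar(shorter))
  }
  fwd <- score_one(a)
  rev <- score_one(revcomp(a))
  if (rev$identity * rev$coverage > fwd$identity * fwd$coverage) {
    c(rev, strand = "-")
  } else {
    c(fwd, strand = "+")
  }
}

#' Collapse redundant contigs into clusters (greedy, longest first)
#'
#' Contigs are visited in decreasing length order (ties broken by id).
#' Each contig joins the first existing representative it matches at
#' `identity >= identity_threshold` over `coverage >= coverage_threshold`
#' of the shorter sequence (both orientations tried), else founds a new
#' cluster. The output clusters partition the input.
#'
#' @param contigs Contig data.frame (normally already length-filtered).
#' @param identity_threshold Minimum nucleotide identity (default 0.95).
#' @param coverage_threshold Minimum fraction of the shorter sequence
#'   aligned (default 0.90).
#' @return data.frame with one row per contig: `contig_id`,
#'   `representative`, `identity`, `coverage` (1 for representatives
#'   themselves).
#' @export
collapse_redundancy <- function(contigs, identity_threshold = 0.95,
                                coverage_threshold = 0.90) {
  assert_that(identity_threshold > 0 && identity_threshold <= 1 &&
                coverage_threshold > 0 && coverage_threshold <= 1,
              "thresholds must be fractions in (0, 1]")
  ord <- order(-contigs$length, contigs$id)
  cs <- contigs[ord, , drop = FALSE]
  reps <- character(0)
  rows <- vector("list", nrow(cs))
  for (i in seq_len(nrow(cs))) {
    assigned <- FALSE
    for (r in reps) {
      pm <- pairwise_identity(cs$sequence[i],
                              cs$sequence[match(r, cs$id)])
      if (pm$identity >= identity_threshold &&
          pm$coverage >= coverage_threshold) {
        rows[[i]] <- data.frame(contig_id = cs$id[i], representative = r,
                                identity = pm$identity,
                                coverage = pm$coverage,
                                stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, cs$id[i])
      rows[[i]] <- data.frame(contig_id = cs$id[i],
                              representative = cs$id[i],
                              identity = 1, coverage = 1,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(data.frame(
    contig_id = character(), representative = character(),
    identity = numeric(), coverage = numeric(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

# valid functional-status categories of an annotated ORF
ORF_STATUSES <- c("complete", "partial_technical", "fragmented_frameshifted",
                  "short_orf")

#' Summarize ORF functional status over a contig set
#'
#' Computes the mean ORF count per contig (reported to one decimal) and
#' splits contigs into functional and non-functional: a contig is
#' non-functional if any of its ORFs is fragmented/frameshifted, or if all
#' of its ORFs are short-ORF calls; all other contigs (including those with
#' no annotated ORF) count as functional.
#'
#' @param orf_records data.frame with `contig_id`, `orf_id`, `status`
#'   (one of `complete`, `partial_technical`, `fragmented_frameshifted`,
#'   `short_orf`).
#' @param contigs Contig data.frame (every ORF must belong to one).
#' @return List with `n_contigs`, `n_orfs`, `orfs_per_contig_mean` (one
#'   decimal), `functional_contigs`, `nonfunctional_contigs`, and `empty`
#'   flag for the degenerate zero-contig case.
#' @export
summarize_orf_status <- function(orf_records, contigs) {
  assert_that(all(orf_records$status %in% ORF_STATUSES),
              "unknown ORF status value(s): %s",
              paste(setdiff(unique(orf_records$status), ORF_STATUSES),
                    collapse = ", "))
  orphans <- setdiff(unique(orf_records$contig_id), contigs$id)
  assert_that(length(orphans) == 0L,
              "ORF record(s) reference unknown contig(s): %s",
              paste(orphans, collapse = ", "))
  n_contigs <- nrow(contigs)
  n_orfs <- nrow(orf_records)
  if (n_contigs == 0L) {
    return(list(n_contigs = 0L, n_orfs = n_orfs,
                orfs_per_contig_mean = NA_real_,
                functional_contigs = 0L, nonfunctional_contigs = 0L,
                empty = TRUE))
  }
  frag <- unique(orf_records$contig_id[
    orf_records$status == "fragmented_frameshifted"])
  has_orf <- split(orf_records$status, orf_records$contig_id)
  short_only <- names(has_orf)[vapply(has_orf,
                                      function(s) all(s == "short_orf"),
                                      logical(1))]
  nonfunc <- union(frag, short_only)
  list(n_contigs = n_contigs, n_orfs = n_orfs,
       orfs_per_contig_mean = round(n_orfs / n_contigs, 1),
       functional_contigs = n_contigs - length(nonfunc),
       nonfunctional_contigs = length(nonfunc),
       empty = FALSE)
}
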