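# Small in-code fixture builders shared across test files.

# a profile data.frame row from a named cell -> count mapping,
# e.g. make_profile(c(p21 = 2, m21 = 1, m25 = 1))
make_profile <- function(cells, contig_id = "c1", pool_id = "pool1") {
  all_cells <- c(paste0("p", 15:35), paste0("m", 15:35))
  counts <- setNames(rep(0L, 42L), all_cells)
  counts[names(cells)] <- as.integer(cells)
  df <- data.frame(contig_id = contig_id, pool_id = pool_id,
                   total_reads = sum(counts), stringsAsFactors = FALSE)
  cbind(df, as.data.frame(as.list(counts)))
}

# n random non-degenerate profiles with totals in [50, 500]
random_profiles <- function(n, seed) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      counts <- rpois(42, lambda = runif(1, 1, 12))
      if (sum(counts) == 0 || length(unique(counts)) == 1) counts[1] <- counts[1] + 7L
      make_profile(setNames(counts, c(paste0("p", 15:35), paste0("m", 15:35))),
                   contig_id = sprintf("rc%04d", i),
                   pool_id = "pool1")
    })
    do.call(rbind, rows)
  })
}

# a contig data.frame from sequences
make_contigs <- function(sequences, ids = sprintf("c%d", seq_along(sequences)),
                         origin = "virus", pool = "pool1") {
  data.frame(id = ids, sequence = sequences, length = nchar(sequences),
             origin_label = rep_len(origin, length(ids)),
             pool_id = rep_len(pool, length(ids)),
             stringsAsFactors = FALSE)
}

make_alignments <- function(contig_id, strand, read_length,
                            start0 = 0L, mismatches = 0L) {
  n <- max(length(contig_id), length(strand), length(read_length))
  data.frame(read_id = sprintf("r%03d", seq_len(n)),
             contig_id = rep_len(contig_id, n),
             strand = rep_len(strand, n),
             start0 = rep_len(as.integer(start0), n),
             read_length = rep_len(as.integer(read_length), n),
             mismatches = rep_len(as.integer(mismatches), n),
             stringsAsFactors = FALSE)
}

# symmetric random distance matrix with zero diagonal and labels
random_distance_matrix <- function(n) {
  m <- matrix(runif(n * n, 0.05, 2), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  m
}
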