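test_that("FASTA reading: lengths, case, duplicates, metadata join", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 some description", "ACGTacgt", ">c2", "GGGCCC"), fa)
  md <- data.frame(contig_id = "c1", origin_label = "virus",
                   pool_id = "pool9")
  ctg <- read_contigs_fasta(fa, md)
  expect_equal(ctg$id, c("c1", "c2"))
  expect_equal(ctg$length, c(8L, 6L))
  expect_equal(ctg$sequence[1], "ACGTACGT")
  expect_equal(ctg$origin_label, c("virus", "unknown"))
  expect_equal(ctg$pool_id, c("pool9", NA))

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1", "AAAA", ">c1", "CCCC"), dup)
  expect_error(read_contigs_fasta(dup), "duplicate contig id.*c1")
})

test_that("fixture write/read round-trips record counts", {
  sim <- simulate_dataset(n_per_class = 2, reads_per_contig = 40, seed = 31,
                          length_range = c(600, 900))
  d <- withr::local_tempdir()
  paths <- write_fixture(sim, d)
  ctg <- read_contigs_fasta(paths[["contigs"]], paths[["truth"]])
  expect_equal(nrow(ctg), nrow(sim$contigs))
  expect_equal(ctg$sequence, sim$contigs$sequence)
  expect_equal(ctg$pool_id, sim$contigs$pool_id)
  rd <- read_reads_fastq(paths[["reads"]])
  expect_equal(nrow(rd), nrow(sim$reads))
  a <- read_alignments(paths[["alignments_tsv"]], contigs = ctg)
  expect_equal(nrow(a), nrow(sim$alignments))
})

test_that("SAM output is consistent with the truth strand and round-trips", {
  sim <- simulate_dataset(n_per_class = 2, reads_per_contig = 30, seed = 33,
                          length_range = c(600, 900))
  d <- withr::local_tempdir()
  paths <- write_fixture(sim, d)
  sam <- readLines(paths[["alignments_sam"]])
  body <- sam[!startsWith(sam, "@")]
  flags <- as.integer(vapply(strsplit(body, "\t"), `[`, character(1), 2))
  qn <- vapply(strsplit(body, "\t"), `[`, character(1), 1)
  truth_strand <- sim$alignments$strand[match(qn, sim$alignments$read_id)]
  expect_identical(ifelse(bitwAnd(flags, 16L) > 0L, "-", "+"), truth_strand)

  # SAM and TSV dialects of the same fixture parse identically
  ctg <- read_contigs_fasta(paths[["contigs"]])
  o <- function(x) {
    x <- x[order(x$read_id, x$contig_id, x$start0), ]
    rownames(x) <- NULL
    x
  }
  a_tsv <- o(read_alignments(paths[["alignments_tsv"]], contigs = ctg))
  a_sam <- o(read_alignments(paths[["alignments_sam"]], contigs = ctg))
  expect_equal(a_sam[names(a_tsv)], a_tsv)
})

test_that("empty simulation writes valid, re-loadable files", {
  sim <- simulate_contigs(c(sirna = 0), seed = 1)
  sim$reads <- data.frame(read_id = character(), sequence = character())
  sim$alignments <- make_alignments(character(), character(), integer())[0, ]
  d <- withr::local_tempdir()
  paths <- write_fixture(sim, d)
  expect_true(all(file.exists(paths)))
  expect_equal(nrow(read_contigs_fasta(paths[["contigs"]])), 0)
  expect_equal(nrow(read_reads_fastq(paths[["reads"]])), 0)
  expect_equal(nrow(read_alignments(paths[["alignments_tsv"]])), 0)
})

test_that("SAM flag and coordinate conventions", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:c1\tLN:100",
    # POS 1 (1-based) must become start0 = 0
    "r1\t0\tc1\t1\t255\t21M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAA\t*",
    # FLAG 16 -> negative strand
    "r2\t16\tc1\t5\t255\t21M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAA\t*",
    # FLAG 4 (unmapped) and 256 (secondary) are skipped
    "r3\t4\tc1\t1\t255\t*\t*\t0\t0\tAAAA\t*",
    "r4\t256\tc1\t9\t255\t21M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAA\t*"), sam)
  a <- read_alignments(sam, format = "sam")
  expect_equal(nrow(a), 2)
  expect_equal(a$start0[a$read_id == "r1"], 0L)
  expect_equal(a$strand[a$read_id == "r2"], "-")
  expect_equal(a$start0[a$read_id == "r2"], 4L)
  expect_equal(a$read_length, c(21L, 21L))
})

test_that("indel CIGARs are skipped with a message", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:c1\tLN:100",
    "r1\t0\tc1\t1\t255\t21M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAA\t*",
    "r2\t0\tc1\t1\t255\t10M1D11M\t*\t0\t0\tAAAAAAAAAAAAAAAAAAAAA\t*"), sam)
  expect_message(a <- read_alignments(sam, format = "sam"), "skipped")
  expect_equal(a$read_id, "r1")
})

test_that("alignments referencing unknown contigs are rejected", {
  ctg <- make_contigs(strrep("A", 600))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_alignments_tsv(make_alignments("ghost", "+", 21L), tsv)
  expect_error(read_alignments(tsv, contigs = ctg), "unknown contig.*ghost")
})

test_that("naive_map finds exact, reverse-complement and bounded-mismatch hits", {
  withr::with_seed(41, {
    ctg <- make_contigs(random_dna(200), ids = "c1")
    fwd <- substring(ctg$sequence, 11, 31)          # contig[10:31), 0-based 10
    rcv <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substring(ctg$sequence, 6, 26))))
    reads <- data.frame(read_id = c("f", "r"), sequence = c(fwd, rcv))
    aln <- naive_map(reads, ctg, max_mismatch = 0)
    f <- aln[aln$read_id == "f", ]
    expect_true(any(f$strand == "+" & f$start0 == 10 & f$mismatches == 0))
    r <- aln[aln$read_id == "r", ]
    expect_true(any(r$strand == "-" & r$start0 == 5 & r$mismatches == 0))

    # two substitutions -> invisible at max_mismatch = 1, found at 2
    mut <- substitute_bases(fwd, 2)
    reads2 <- data.frame(read_id = "m", sequence = mut)
    expect_equal(nrow(naive_map(reads2, ctg, max_mismatch = 1)), 0)
    hit2 <- naive_map(reads2, ctg, max_mismatch = 2)
    expect_true(any(hit2$start0 == 10 & hit2$mismatches == 2))
  })
})

test_that("naive_map recovers every simulated true alignment", {
  sim <- simulate_dataset(n_per_class = 2, reads_per_contig = 15, seed = 47,
                          length_range = c(600, 800),
                          classes = c("sirna", "pirna"))
  aln <- naive_map(sim$reads, sim$contigs, max_mismatch = 1)
  truth_key <- with(sim$alignments,
                    paste(read_id, contig_id, strand, start0))
  found_key <- with(aln, paste(read_id, contig_id, strand, start0))
  expect_true(all(truth_key %in% found_key))
})

test_that("dedupe collapses identical (sequence, contig, start, strand) hits", {
  ctg <- make_contigs(strrep("ACGT", 200), ids = "c1")
  sq <- substring(ctg$sequence, 1, 21)
  reads <- data.frame(read_id = c("a", "b"), sequence = c(sq, sq))
  full <- naive_map(reads, ctg, max_mismatch = 0)
  dd <- naive_map(reads, ctg, max_mismatch = 0, dedupe = TRUE)
  expect_equal(nrow(dd), nrow(full) / 2)
})
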