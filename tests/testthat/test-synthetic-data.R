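test_that("signature_model validates its invariants", {
  m <- signature_model("sirna", c(`21` = 1), 0.5, 100)
  expect_s3_class(m, "signature_model")
  expect_equal(sum(m$size_pmf), 1)

  expect_error(signature_model("x", c(`21` = 0.5), 0.5, 10), "sum to 1")
  expect_error(signature_model("x", c(`40` = 1), 0.5, 10), "within \\[15, 35\\]")
  expect_error(signature_model("x", c(`21` = 1), 1.2, 10),
               "positive_strand_fraction")
  expect_error(signature_model("x", c(`21` = 1), 0.5, 0), "positive integer")
})

test_that("simulate_contigs counts, pools and empty case", {
  sim <- simulate_contigs(c(sirna = 20, pirna = 20, degradation = 20),
                          seed = 11)
  expect_equal(nrow(sim$contigs), 60)
  expect_equal(unname(table(sim$truth$true_class)[c("sirna", "pirna",
                                                    "degradation")]),
               rep(20L, 3), ignore_attr = TRUE)
  # every contig has exactly one truth record
  expect_setequal(sim$truth$contig_id, sim$contigs$id)
  expect_false(anyDuplicated(sim$truth$contig_id) > 0)
  # origin mapping: degradation contigs are host, the rest virus
  expect_true(all(sim$truth$origin_label[
    sim$truth$true_class == "degradation"] == "host"))

  empty <- simulate_contigs(c(sirna = 0, pirna = 0), seed = 1)
  expect_equal(nrow(empty$contigs), 0)
  expect_equal(nrow(empty$truth), 0)
})

test_that("simulate_contigs rejects invalid parameters", {
  expect_error(simulate_contigs(c(sirna = 1), gc = 0, seed = 1),
               "gc must be")
  expect_error(simulate_contigs(c(sirna = 1), length_range = c(100, 400),
                                seed = 1), "length_range")
  expect_error(simulate_contigs(c(sirna = 1), length_range = c(900, 600),
                                seed = 1), "length_range")
})

test_that("same seed gives byte-identical fixtures, different seed differs", {
  sim1 <- simulate_dataset(n_per_class = 3, reads_per_contig = 50, seed = 5,
                           length_range = c(600, 900))
  sim2 <- simulate_dataset(n_per_class = 3, reads_per_contig = 50, seed = 5,
                           length_range = c(600, 900))
  expect_identical(sim1, sim2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixture(sim1, d1)
  p2 <- write_fixture(sim2, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  sim3 <- simulate_dataset(n_per_class = 3, reads_per_contig = 50, seed = 6,
                           length_range = c(600, 900))
  expect_false(identical(sim1$contigs$sequence, sim3$contigs$sequence))
})

test_that("degenerate pmf and strand boundary are honoured", {
  models <- list(sirna = signature_model("sirna", c(`21` = 1), 1.0, 500))
  sim <- simulate_contigs(c(sirna = 2), seed = 3)
  rd <- simulate_reads(sim$contigs, sim$truth, models, seed = 4)
  expect_true(all(rd$alignments$read_length == 21))
  expect_true(all(rd$alignments$strand == "+"))
  expect_true(all(nchar(rd$reads$sequence) == 21))
  # read sequences are contig substrings on the + strand
  i <- 1
  a <- rd$alignments[i, ]
  ctg <- sim$contigs$sequence[sim$contigs$id == a$contig_id]
  expect_identical(rd$reads$sequence[i],
                   substring(ctg, a$start0 + 1, a$start0 + a$read_length))
})

test_that("negative-strand reads are reverse complements of the contig", {
  models <- list(pirna = signature_model("pirna", c(`27` = 1), 0.0, 200))
  sim <- simulate_contigs(c(pirna = 1), seed = 8)
  rd <- simulate_reads(sim$contigs, sim$truth, models, seed = 9)
  expect_true(all(rd$alignments$strand == "-"))
  a <- rd$alignments[5, ]
  ctg <- sim$contigs$sequence[1]
  fwd <- substring(ctg, a$start0 + 1, a$start0 + a$read_length)
  expect_identical(rd$reads$sequence[5],
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(fwd))))
})

test_that("simulate_reads rejects missing models and short contigs", {
  sim <- simulate_contigs(c(sirna = 1), seed = 2)
  expect_error(simulate_reads(sim$contigs, sim$truth, list(), seed = 1),
               "no signature model")
  short <- make_contigs(strrep("A", 20), ids = "tiny")
  truth <- data.frame(contig_id = "tiny", true_class = "sirna",
                      pool_id = "pool1", origin_label = "virus")
  models <- list(sirna = signature_model("sirna", c(`35` = 1), 0.5, 10))
  expect_error(simulate_reads(short, truth, models, seed = 1),
               "shorter than the maximum read length")
})

test_that("sampler matches its pmf and strand fraction (fixed seeds)", {
  models <- default_signature_models(reads_per_contig = 1000)
  sim <- simulate_contigs(c(pirna = 10), seed = 21)
  rd <- simulate_reads(sim$contigs, sim$truth, models, seed = 22)
  # n = 10000 draws: chi-square goodness of fit at alpha = 0.01
  pmf <- models$pirna$size_pmf
  obs <- table(factor(rd$alignments$read_length,
                      levels = as.integer(names(pmf))))
  gof <- chisq.test(as.integer(obs), p = pmf)
  expect_gt(gof$p.value, 0.01)
  # empirical strand fraction within 3 binomial sds
  p <- models$pirna$positive_strand_fraction
  n <- nrow(rd$alignments)
  emp <- mean(rd$alignments$strand == "+")
  expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("error_rate introduces counted mismatches", {
  models <- list(sirna = signature_model("sirna", c(`21` = 1), 0.5, 300))
  sim <- simulate_contigs(c(sirna = 1), seed = 13)
  rd <- simulate_reads(sim$contigs, sim$truth, models, seed = 14,
                       error_rate = 0.02)
  expect_gt(sum(rd$alignments$mismatches), 0)
  # recorded mismatch counts agree with a direct sequence comparison
  ctg <- sim$contigs$sequence[1]
  for (i in which(rd$alignments$mismatches > 0)[1:3]) {
    a <- rd$alignments[i, ]
    ref <- substring(ctg, a$start0 + 1, a$start0 + a$read_length)
    if (a$strand == "-") {
      ref <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ref)))
    }
    got <- rd$reads$sequence[i]
    expect_equal(sum(strsplit(ref, "")[[1]] != strsplit(got, "")[[1]]),
                 a$mismatches)
  }
})
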