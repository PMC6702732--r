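#' Simulate random contigs with a ground-truth table
#'
#' Generates `n_per_class` random nucleotide sequences per signature class,
#' with lengths uniform in `length_range` and i.i.d. bases at the requested
#' GC content. Contigs are assigned round-robin to `pools` and carry an
#' origin label derived from their class (`origin_by_class`), emulating a
#' study design in which siRNA/piRNA-processed contigs are of viral origin
#' and degradation-profile contigs derive from the host.
#'
#' @param n_per_class Named integer vector: contigs per class. Names are
#'   class labels; values of 0 are allowed (and an all-zero vector yields an
#'   empty set).
#' @param length_range Integer vector of length 2, contig length bounds in
#'   nt, within \[501, 50000\].
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param pools Character vector of pool identifiers (default 4 pools).
#' @param origin_by_class Named character vector mapping class to an origin
#'   label in `{virus, unclassified, host}`. Classes absent from the map
#'   default to `"virus"`.
#'
#' @return A list with `contigs` (data.frame: `id`, `sequence`, `length`,
#'   `origin_label`, `pool_id`) and `truth` (data.frame: `contig_id`,
#'   `true_class`, `pool_id`, `origin_label`).
#' @export
#' @examples
#' sim <- simulate_contigs(c(sirna = 2, degradation = 2),
#'                         length_range = c(600, 900), seed = 1)
#' sim$truth
simulate_contigs <- function(n_per_class,
                             length_range = c(1000L, 3000L),
                             gc = 0.5,
                             seed,
                             pools = paste0("pool", 1:4),
                             origin_by_class = c(sirna = "virus",
                                                 pirna = "virus",
                                                 pirna_positive = "virus",
                                                 mixed = "virus",
                                                 degradation = "host")) {
  assert_that(is.numeric(n_per_class) && !is.null(names(n_per_class)) &&
                all(nzchar(names(n_per_class))) && all(n_per_class >= 0),
              "n_per_class must be a named vector of non-negative counts")
  assert_that(length(length_range) == 2L && all(is.finite(length_range)) &&
                length_range[1] <= length_range[2] &&
                length_range[1] >= 501 && length_range[2] <= 50000,
              "length_range must lie within [501, 50000] (contigs must pass the >500 nt gate)")
  assert_that(is.numeric(gc) && length(gc) == 1L && gc > 0 && gc < 1,
              "gc must be a fraction strictly between 0 and 1")
  assert_that(length(pools) >= 1L, "at least one pool id is required")

  n_per_class <- setNames(as.integer(n_per_class), names(n_per_class))
  classes <- rep(names(n_per_class), times = n_per_class)
  n <- length(classes)
  empty_contigs <- data.frame(id = character(), sequence = character(),
                              length = integer(), origin_label = character(),
                              pool_id = character(),
                              stringsAsFactors = FALSE)
  empty_truth <- data.frame(contig_id = character(), true_class = character(),
                            pool_id = character(), origin_label = character(),
                            stringsAsFactors = FALSE)
  if (n == 0L) return(list(contigs = empty_contigs, truth = empty_truth))

  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    lens <- sample(seq.int(length_range[1], length_range[2]), n,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(names(base_p), L, replace = TRUE, prob = base_p),
            collapse = "")
    }, character(1))
    ids <- sprintf("%s_c%03d", classes, stats::ave(seq_len(n), classes,
                                                   FUN = seq_along))
    pool_id <- rep_len(pools, n)
    origin <- unname(origin_by_class[classes])
    origin[is.na(origin)] <- "virus"
    contigs <- data.frame(id = ids, sequence = seqs, length = lens,
                          origin_label = origin, pool_id = pool_id,
                          stringsAsFactors = FALSE)
    truth <- data.frame(contig_id = ids, true_class = classes,
                        pool_id = pool_id, origin_label = origin,
                        stringsAsFactors = FALSE)
    list(contigs = contigs, truth = truth)
  })
}

#' Simulate small RNA reads from contigs under per-class signature models
#'
#' For each contig, draws `reads_per_contig` reads i.i.d. from its class
#' model: read length from the model's size pmf, strand from a Bernoulli
#' with the model's positive-strand fraction, and start position uniform
#' over valid offsets. The read sequence is the contig substring,
#' reverse-complemented for negative-strand reads. True alignment records
#' (0-based starts) are emitted alongside the reads.
#'
#' @param contigs Contig data.frame as from [simulate_contigs()].
#' @param truth Truth table giving each contig's `true_class`.
#' @param models Named list of [signature_model()]s, one per class present.
#' @param seed Integer seed.
#' @param error_rate Per-base substitution rate applied to read sequences
#'   after extraction (default 0; used to exercise mismatch-tolerant
#'   mapping).
#'
#' @return List with `reads` (data.frame: `read_id`, `sequence`) and
#'   `alignments` (data.frame: `read_id`, `contig_id`, `strand`, `start0`,
#'   `read_length`, `mismatches`).
#' @export
simulate_reads <- function(contigs, truth, models, seed, error_rate = 0) {
  assert_that(nrow(contigs) == 0L || all(contigs$id %in% truth$contig_id),
              "every contig needs a truth record")
  classes <- unique(truth$true_class[match(contigs$id, truth$contig_id)])
  missing <- setdiff(classes, names(models))
  assert_that(length(missing) == 0L,
              "no signature model for class(es): %s",
              paste(missing, collapse = ", "))
  assert_that(is.numeric(error_rate) && error_rate >= 0 && error_rate < 1,
              "error_rate must be in [0, 1)")
  max_len <- if (length(classes)) {
    max(vapply(models[classes],
               function(m) max(as.integer(names(m$size_pmf))), integer(1)))
  } else 0L
  short <- contigs$id[contigs$length < max_len]
  assert_that(length(short) == 0L,
              "contig(s) shorter than the maximum read length (%d nt): %s",
              max_len, paste(short, collapse = ", "))

  with_seed(seed, {
    per_contig <- lapply(seq_len(nrow(contigs)), function(i) {
      cid <- contigs$id[i]
      cls <- truth$true_class[match(cid, truth$contig_id)]
      m <- models[[cls]]
      n <- m$reads_per_contig
      sizes <- as.integer(names(m$size_pmf))
      len <- sizes[sample.int(length(sizes), n, replace = TRUE,
                              prob = m$size_pmf)]
      strand <- ifelse(runif(n) < m$positive_strand_fraction, "+", "-")
      # start uniform over the 0-based half-open valid window
      start0 <- floor(runif(n) * (contigs$length[i] - len + 1L))
      sq <- substring(contigs$sequence[i], start0 + 1L, start0 + len)
      neg <- strand == "-"
      if (any(neg)) sq[neg] <- revcomp(sq[neg])
      mism <- integer(n)
      if (error_rate > 0) {
        orig <- sq
        sq <- vapply(sq, mutate_seq, character(1), rate = error_rate,
                     USE.NAMES = FALSE)
        mism <- mapply(function(a, b) {
          sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
        }, orig, sq, USE.NAMES = FALSE)
      }
      data.frame(read_id = sprintf("%s_r%05d", cid, seq_len(n)),
                 contig_id = cid, strand = strand,
                 start0 = as.integer(start0), read_length = len,
                 mismatches = mism, sequence = sq,
                 stringsAsFactors = FALSE)
    })
    aln <- do.call(rbind, c(per_contig,
                            list(data.frame(read_id = character(),
                                            contig_id = character(),
                                            strand = character(),
                                            start0 = integer(),
                                            read_length = integer(),
                                            mismatches = integer(),
                                            sequence = character(),
                                            stringsAsFactors = FALSE))))
    reads <- data.frame(read_id = aln$read_id, sequence = aln$sequence,
                        stringsAsFactors = FALSE)
    aln$sequence <- NULL
    list(reads = reads, alignments = aln)
  })
}

# substitute bases independently at `rate`; substitutions drawn uniformly
# from the three alternative bases
mutate_seq <- function(s, rate) {
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- runif(length(b)) < rate
  if (!any(hit)) return(s)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  b[hit] <- vapply(b[hit],
                   function(x) sample(alt[[x]] %||% c("A", "C", "G", "T"), 1),
                   character(1))
  paste(b, collapse = "")
}

#' Write a simulated dataset to disk as plain-text fixtures
#'
#' Emits the contig FASTA, read FASTQ (dummy quality `I`), the true
#' alignments in both the package's TSV alignment dialect and minimal SAM,
#' and the truth table TSV. All files round-trip through the package's
#' readers.
#'
#' @param sim List with `contigs`, `truth`, `reads`, `alignments` (combine
#'   the outputs of [simulate_contigs()] and [simulate_reads()]).
#' @param outdir Output directory, created if absent.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_fixture <- function(sim, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  assert_that(ok && file.access(outdir, 2) == 0L,
              "cannot write to output directory '%s'", outdir)
  paths <- c(contigs = file.path(outdir, "contigs.fasta"),
             reads = file.path(outdir, "reads.fastq"),
             alignments_tsv = file.path(outdir, "alignments.tsv"),
             alignments_sam = file.path(outdir, "alignments.sam"),
             truth = file.path(outdir, "truth.tsv"))
  write_contigs_fasta(sim$contigs, paths[["contigs"]])
  write_reads_fastq(sim$reads, paths[["reads"]])
  write_alignments_tsv(sim$alignments, paths[["alignments_tsv"]])
  write_alignments_sam(sim$alignments, sim$reads, sim$contigs,
                       paths[["alignments_sam"]])
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Simulate the default three-class benchmark dataset
#'
#' Convenience wrapper producing the package's standard synthetic world:
#' `n_per_class` contigs for each of the siRNA, negative-biased piRNA and
#' degradation classes, with reads drawn under [default_signature_models()].
#'
#' @param n_per_class Contigs per class (default 20).
#' @param reads_per_contig Reads per contig (default 1000).
#' @param seed Integer seed.
#' @param classes Class labels to simulate (subset of the default model
#'   names).
#' @inheritParams simulate_contigs
#' @return List with `contigs`, `truth`, `reads`, `alignments`.
#' @export
simulate_dataset <- function(n_per_class = 20, reads_per_contig = 1000,
                             seed, classes = c("sirna", "pirna",
                                               "degradation"),
                             length_range = c(1000L, 3000L), gc = 0.5) {
  models <- default_signature_models(reads_per_contig = reads_per_contig)
  assert_that(all(classes %in% names(models)),
              "classes must be among: %s",
              paste(names(models), collapse = ", "))
  npc <- setNames(rep(as.integer(n_per_class), length(classes)), classes)
  sim <- simulate_contigs(npc, length_range = length_range, gc = gc,
                          seed = seed)
  rd <- simulate_reads(sim$contigs, sim$truth, models, seed = seed + 1L)
  c(sim, rd)
}
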