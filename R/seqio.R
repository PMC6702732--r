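#' Read contigs from FASTA
#'
#' Sequences are uppercased on load. When a metadata table is supplied
#' (TSV with columns `contig_id`, `origin_label`, `pool_id` — or a
#' data.frame of the same shape, e.g. a truth table), origin labels and
#' pool ids are joined onto the contigs; otherwise both default to
#' `"unknown"`/`NA`.
#'
#' @param path FASTA file.
#' @param metadata Optional path to a metadata TSV, or a data.frame.
#' @return data.frame with `id`, `sequence`, `length`, `origin_label`,
#'   `pool_id`.
#' @export
read_contigs_fasta <- function(path, metadata = NULL) {
  assert_that(file.exists(path), "FASTA file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  assert_that(length(dup) == 0L,
              "duplicate contig id(s) in %s: %s", path,
              paste(unique(dup), collapse = ", "))
  sq <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", sq)
  assert_that(!any(bad),
              "contig(s) with characters outside {A,C,G,T,N}: %s",
              paste(ids[bad], collapse = ", "))
  out <- data.frame(id = ids, sequence = unname(sq),
                    length = unname(nchar(sq)),
                    origin_label = rep("unknown", length(ids)),
                    pool_id = rep(NA_character_, length(ids)),
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    md <- if (is.character(metadata)) {
      read.delim(metadata, stringsAsFactors = FALSE)
    } else metadata
    key <- if ("contig_id" %in% names(md)) "contig_id" else "id"
    i <- match(out$id, md[[key]])
    if ("origin_label" %in% names(md)) {
      out$origin_label <- ifelse(is.na(i), "unknown", md$origin_label[i])
    }
    if ("pool_id" %in% names(md)) {
      out$pool_id <- md$pool_id[i]
    }
  }
  out
}

#' Read small RNA reads from FASTQ
#'
#' @param path FASTQ file.
#' @return data.frame with `read_id`, `sequence` (uppercased).
#' @export
read_reads_fastq <- function(path) {
  assert_that(file.exists(path), "FASTQ file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  assert_that(length(dup) == 0L, "duplicate read id(s) in %s: %s", path,
              paste(unique(dup), collapse = ", "))
  data.frame(read_id = ids, sequence = toupper(unname(as.character(ss))),
             stringsAsFactors = FALSE)
}

#' @rdname read_contigs_fasta
#' @param contigs Contig data.frame to write.
#' @export
write_contigs_fasta <- function(contigs, path) {
  ss <- Biostrings::DNAStringSet(setNames(as.character(contigs$sequence),
                                          contigs$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname read_reads_fastq
#' @param reads Read data.frame to write; quality is a constant `I`.
#' @export
write_reads_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                      strrep("I", nchar(reads$sequence))), con)
  }
  invisible(path)
}

# columns of the TSV alignment dialect, fixed by contract
ALN_COLS <- c("read_id", "contig_id", "strand", "start0", "read_length",
              "mismatches")

#' Read small RNA-to-contig alignments
#'
#' Supports three dialects: the package TSV (`read_id`, `contig_id`,
#' `strand`, `start0`, `read_length`, `mismatches`), SAM and BAM. For
#' SAM/BAM, FLAG bit 0x10 maps to strand `-`; unmapped (0x4), secondary
#' (0x100) and supplementary (0x800) records are skipped; the 1-based POS
#' is converted to the package's 0-based half-open `start0`; `read_length`
#' is the sequence length. Records whose CIGAR contains indels are skipped
#' with a message (size profiles use read length, not reference span).
#'
#' @param path Alignment file.
#' @param format One of `"tsv"`, `"sam"`, `"bam"`; default guessed from
#'   the file extension.
#' @param contigs Optional contig data.frame; when given, alignments must
#'   reference known contigs and must fit inside them.
#' @return data.frame with the TSV dialect columns.
#' @export
read_alignments <- function(path, format = c("auto", "tsv", "sam", "bam"),
                            contigs = NULL) {
  assert_that(file.exists(path), "alignment file not found: %s", path)
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sam = "sam", bam = "bam", "tsv")
  }
  aln <- if (format == "tsv") read_alignments_tsv(path) else {
    read_alignments_sam(path, is_bam = format == "bam")
  }
  if (!is.null(contigs)) {
    unknown <- setdiff(unique(aln$contig_id), contigs$id)
    assert_that(length(unknown) == 0L,
                "alignment(s) reference unknown contig(s): %s",
                paste(unknown, collapse = ", "))
    clen <- contigs$length[match(aln$contig_id, contigs$id)]
    bad <- aln$start0 < 0L | aln$start0 + aln$read_length > clen
    assert_that(!any(bad), "%d alignment(s) extend beyond their contig",
                sum(bad))
  }
  aln
}

read_alignments_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(read_id = "character",
                                  contig_id = "character",
                                  strand = "character",
                                  start0 = "integer",
                                  read_length = "integer",
                                  mismatches = "integer"))
  missing <- setdiff(ALN_COLS, names(df))
  assert_that(length(missing) == 0L,
              "alignment TSV %s lacks column(s): %s", path,
              paste(missing, collapse = ", "))
  assert_that(all(df$strand %in% c("+", "-")),
              "strand column must contain only '+' or '-'")
  df[ALN_COLS]
}

# SAM/BAM ingestion through Rsamtools; SAM text is converted to a
# temporary BAM first
read_alignments_sam <- function(path, is_bam = FALSE) {
  bam <- if (is_bam) path else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "NM")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$qname)
  if (n == 0L) {
    return(data.frame(read_id = character(), contig_id = character(),
                      strand = character(), start0 = integer(),
                      read_length = integer(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  indel <- grepl("[IDNSHP]", b$cigar)
  if (any(indel)) {
    message(sum(indel), " alignment record(s) with indel/clip CIGAR skipped")
  }
  keep <- !indel
  nm <- b$tag$NM %||% rep(0L, n)
  nm[is.na(nm)] <- 0L
  data.frame(read_id = b$qname[keep],
             contig_id = as.character(b$rname[keep]),
             strand = ifelse(bitwAnd(b$flag[keep], 16L) > 0L, "-", "+"),
             start0 = b$pos[keep] - 1L,
             read_length = Biostrings::width(b$seq)[keep],
             mismatches = as.integer(nm[keep]),
             stringsAsFactors = FALSE)
}

#' @rdname read_alignments
#' @param alignments Alignment data.frame to write.
#' @export
write_alignments_tsv <- function(alignments, path) {
  write.table(alignments[ALN_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write alignments as minimal SAM
#'
#' Emits QNAME/FLAG/RNAME/POS/MAPQ/CIGAR (full-length match)/SEQ with an
#' `NM` tag; negative-strand records carry FLAG 16 and the reference-strand
#' (reverse-complemented) sequence, per the SAM convention.
#'
#' @param alignments Alignment data.frame (TSV dialect columns).
#' @param reads Read data.frame supplying sequences.
#' @param contigs Contig data.frame supplying `@SQ` headers.
#' @param path Output path.
#' @export
write_alignments_sam <- function(alignments, reads, contigs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  if (nrow(contigs)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", contigs$id, contigs$length), con)
  }
  if (nrow(alignments)) {
    sq <- reads$sequence[match(alignments$read_id, reads$read_id)]
    neg <- alignments$strand == "-"
    if (any(neg)) sq[neg] <- revcomp(sq[neg])
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                       alignments$read_id, ifelse(neg, 16L, 0L),
                       alignments$contig_id, alignments$start0 + 1L,
                       alignments$read_length, sq,
                       strrep("I", alignments$read_length),
                       alignments$mismatches), con)
  }
  invisible(path)
}

#' Exhaustively map reads onto contigs allowing mismatches
#'
#' A transparent desk-scale stand-in for a seed-based aligner: every read
#' and its reverse complement are scanned against every position of every
#' contig, and all hits with at most `max_mismatch` substitutions are
#' reported (no indels; `N` never matches). A reverse-complement hit is
#' reported as strand `-` with the position of the match on the reference.
#'
#' @param reads Read data.frame (`read_id`, `sequence`).
#' @param contigs Contig data.frame.
#' @param max_mismatch Maximum substitutions per hit (default 1).
#' @param dedupe Collapse duplicate hits by (read sequence, contig, start,
#'   strand), keeping one representative read per duplicate group
#'   (default `FALSE`).
#' @return Alignment data.frame in the TSV dialect.
#' @export
naive_map <- function(reads, contigs, max_mismatch = 1, dedupe = FALSE) {
  subjects <- lapply(contigs$sequence, Biostrings::DNAString)
  names(subjects) <- contigs$id
  hit_one <- function(pattern, read_id, strand) {
    out <- vector("list", length(subjects))
    for (j in seq_along(subjects)) {
      m <- Biostrings::matchPattern(pattern, subjects[[j]],
                                    max.mismatch = max_mismatch,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0L) next
      st <- Biostrings::start(m) - 1L
      mm <- vapply(seq_along(m), function(k) {
        Biostrings::neditAt(pattern, subjects[[j]], at = st[k] + 1L,
                            fixed = TRUE)
      }, integer(1))
      out[[j]] <- data.frame(read_id = read_id, contig_id = names(subjects)[j],
                             strand = strand, start0 = st,
                             read_length = length(pattern),
                             mismatches = mm, stringsAsFactors = FALSE)
    }
    out
  }
  res <- vector("list", 2L * nrow(reads))
  for (i in seq_len(nrow(reads))) {
    p <- Biostrings::DNAString(reads$sequence[i])
    res[[2L * i - 1L]] <- do.call(rbind, hit_one(p, reads$read_id[i], "+"))
    res[[2L * i]] <- do.call(rbind,
                             hit_one(Biostrings::reverseComplement(p),
                                     reads$read_id[i], "-"))
  }
  aln <- do.call(rbind, c(res, list(data.frame(
    read_id = character(), contig_id = character(), strand = character(),
    start0 = integer(), read_length = integer(), mismatches = integer(),
    stringsAsFactors = FALSE))))
  rownames(aln) <- NULL
  if (dedupe && nrow(aln)) {
    sq <- reads$sequence[match(aln$read_id, reads$read_id)]
    key <- paste(sq, aln$contig_id, aln$start0, aln$strand, sep = "\r")
    aln <- aln[!duplicated(key), , drop = FALSE]
    rownames(aln) <- NULL
  }
  aln
}
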