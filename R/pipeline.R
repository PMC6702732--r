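#' Build a pipeline configuration
#'
#' Collects every path, threshold and method switch the pipeline uses into
#' one validated list that round-trips losslessly through JSON.
#'
#' @param contigs_fasta Path to the contig FASTA.
#' @param alignments Path to the small RNA alignments (TSV dialect, SAM or
#'   BAM).
#' @param metadata Path to the contig metadata TSV (`contig_id`,
#'   `origin_label`, `pool_id`); required when `require_same_pool`.
#' @param outdir Output directory.
#' @param min_len Exclusive contig length gate in nt (default 500).
#' @param min_reads Inclusive mapped-read gate per profile (default 100).
#' @param corr_threshold Recruitment correlation threshold (default 0.9).
#' @param identity Redundancy-collapse identity threshold (default 0.95).
#' @param coverage Redundancy-collapse coverage threshold (default 0.90).
#' @param k Number of clusters (default 4).
#' @param corr_method `"pearson"` or `"spearman"`.
#' @param continuity_correction Yates correction for the count test.
#' @param require_same_pool Restrict recruitment to same-pool viruses.
#' @param seed Integer seed for any stochastic step.
#' @return List of class `virosift_config`.
#' @export
virosift_config <- function(contigs_fasta, alignments, metadata = NULL,
                            outdir = "virosift_out",
                            min_len = 500, min_reads = 100,
                            corr_threshold = 0.9, identity = 0.95,
                            coverage = 0.90, k = 4,
                            corr_method = "pearson",
                            continuity_correction = TRUE,
                            require_same_pool = TRUE, seed = 1L) {
  assert_that(min_len >= 0 && min_reads >= 0, "gates must be non-negative")
  assert_that(corr_threshold >= -1 && corr_threshold <= 1,
              "corr_threshold must be a correlation value")
  assert_that(identity > 0 && identity <= 1 && coverage > 0 && coverage <= 1,
              "identity and coverage must be fractions in (0, 1]")
  assert_that(k >= 1, "k must be at least 1")
  assert_that(corr_method %in% c("pearson", "spearman"),
              "corr_method must be 'pearson' or 'spearman'")
  structure(list(contigs_fasta = contigs_fasta, alignments = alignments,
                 metadata = metadata, outdir = outdir, min_len = min_len,
                 min_reads = min_reads, corr_threshold = corr_threshold,
                 identity = identity, coverage = coverage, k = k,
                 corr_method = corr_method,
                 continuity_correction = continuity_correction,
                 require_same_pool = require_same_pool,
                 seed = as.integer(seed)),
            class = "virosift_config")
}

#' @rdname virosift_config
#' @param path JSON file to write to / read from.
#' @param config A `virosift_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname virosift_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(virosift_config, x[!vapply(x, is.null, logical(1))])
}

#' Run the full signature pipeline
#'
#' Executes, in order: contig QC (length filter, redundancy collapse) ->
#' size profiles (+ read gate) -> z-scores -> UPGMA clustering and
#' signature labels on virus-labelled contigs -> recruitment of
#' unclassified contigs -> host reconstruction control -> log2-RPKM
#' abundance matrix. Every stage writes a TSV under `outdir` and the run
#' manifest records inputs, thresholds, seed, per-stage record counts and
#' output file hashes, so a rerun with the same config is byte-auditable.
#'
#' @param config A [virosift_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "virosift_config"),
              "config must be a virosift_config")
  for (p in c(config$contigs_fasta, config$alignments)) {
    assert_that(file.exists(p), "input file not found: %s", p)
  }
  if (config$require_same_pool) {
    assert_that(!is.null(config$metadata),
                "require_same_pool = TRUE needs contig metadata with pool ids")
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, msg, ...) {
    message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
  }
  counts <- list()

  # ---- qc ----
  contigs <- read_contigs_fasta(config$contigs_fasta, config$metadata)
  counts$contigs_in <- nrow(contigs)
  contigs <- filter_by_length(contigs, config$min_len)
  counts$contigs_len_pass <- nrow(contigs)
  log_stage("qc", "%d/%d contigs pass the >%d nt gate",
            nrow(contigs), counts$contigs_in, config$min_len)
  redclust <- collapse_redundancy(contigs, config$identity, config$coverage)
  reps <- redclust$contig_id[redclust$contig_id == redclust$representative]
  contigs <- contigs[contigs$id %in% reps, , drop = FALSE]
  counts$contigs_nonredundant <- nrow(contigs)
  log_stage("qc", "%d non-redundant representatives", nrow(contigs))
  write.table(redclust, file.path(config$outdir, "redundancy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- profile ----
  aln <- read_alignments(config$alignments, contigs = contigs)
  counts$alignments <- nrow(aln)
  profiles <- compute_profiles(aln, contigs)
  profiles <- filter_profiles(profiles, config$min_reads)
  counts$profiles_pass <- nrow(profiles)
  log_stage("profile", "%d contigs with >= %d mapped reads",
            nrow(profiles), config$min_reads)
  write_profiles_tsv(profiles, file.path(config$outdir, "profiles.tsv"))
  zp <- zscore_profiles(profiles)
  write_profiles_tsv(zp, file.path(config$outdir, "zprofiles.tsv"))

  origin <- setNames(contigs$origin_label, contigs$id)
  is_virus <- origin[zp$contig_id] == "virus"
  virus_z <- zp[is_virus, , drop = FALSE]
  virus_p <- profiles[is_virus, , drop = FALSE]
  counts$virus_profiles <- nrow(virus_z)

  # ---- cluster ----
  model <- cluster_profiles(virus_z, virus_p, k = config$k,
                            method = config$corr_method)
  log_stage("cluster", "%d virus profiles in %d clusters",
            nrow(model$assignments), nrow(model$signatures))
  write.table(model$assignments,
              file.path(config$outdir, "cluster_assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(model$signatures,
              file.path(config$outdir, "cluster_signatures.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as_newick(model$dendrogram),
             file.path(config$outdir, "dendrogram.nwk"))

  # ---- recruit ----
  uncl_z <- zp[origin[zp$contig_id] == "unclassified", , drop = FALSE]
  counts$unclassified_profiles <- nrow(uncl_z)
  recr <- if (nrow(uncl_z)) {
    recruit(uncl_z, virus_z, model$assignments,
            threshold = config$corr_threshold,
            require_same_pool = config$require_same_pool,
            method = config$corr_method)
  } else {
    data.frame()
  }
  counts$recruited <- if (nrow(recr)) sum(recr$recruited) else 0L
  log_stage("recruit", "%d/%d unclassified contigs recruited",
            counts$recruited, counts$unclassified_profiles)
  write.table(recr, file.path(config$outdir, "recruitment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- control ----
  host_z <- zp[origin[zp$contig_id] == "host", , drop = FALSE]
  ctrl <- reconstruction_control(host_z, virus_z, model$assignments,
                                 threshold = config$corr_threshold,
                                 require_same_pool = config$require_same_pool,
                                 method = config$corr_method,
                                 signatures = model$signatures)
  counts$host_profiles <- ctrl$n_host
  counts$host_recruited <- ctrl$n_recruited
  log_stage("control", "%d/%d host contigs recruited", ctrl$n_recruited,
            ctrl$n_host)
  jsonlite::write_json(ctrl[c("n_host", "n_recruited", "recruitment_rate",
                              "by_cluster")],
                       file.path(config$outdir, "control.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  # ---- abundance ----
  cm <- count_matrix(aln, contigs)
  lib <- pmax(colSums(cm), 1)
  ab <- rpkm_matrix(cm, contigs$length, lib)
  write.table(data.frame(contig_id = rownames(ab), ab,
                         check.names = FALSE),
              file.path(config$outdir, "abundance_log2rpkm.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("abundance", "matrix %d x %d written", nrow(ab), ncol(ab))

  outputs <- list.files(config$outdir, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(config$outdir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("virosift")),
    config = unclass(config),
    stages = c("qc", "profile", "cluster", "recruit", "control",
               "abundance"),
    counts = counts,
    outputs = lapply(setNames(nm = basename(outputs)), function(b) {
      unname(tools::md5sum(file.path(config$outdir, b)))
    }))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(contigs = contigs, profiles = profiles, zprofiles = zp,
                 cluster_model = model, recruitment = recr, control = ctrl,
                 abundance = ab, manifest = manifest))
}
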