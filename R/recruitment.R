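#' Recruit unclassified contigs into virus signature clusters
#'
#' Each query profile is correlated against every classified virus profile
#' (restricted to viruses from the same sample pool when
#' `require_same_pool`). The best-correlated virus is the match; the query
#' is recruited iff that correlation is at least `threshold` (inclusive),
#' and inherits the match's cluster. Queries with no eligible virus (e.g.
#' no virus in their pool) are emitted unrecruited with `NA` evidence.
#'
#' @param query_z z-profile data.frame of query (unclassified) contigs that
#'   already passed the read-count gate.
#' @param virus_z z-profile data.frame of classified virus contigs.
#' @param virus_assignments data.frame `contig_id`, `cluster` (from
#'   [cluster_profiles()]).
#' @param threshold Minimum correlation for recruitment (default 0.9,
#'   inclusive).
#' @param require_same_pool Restrict candidate viruses to the query's pool
#'   (default `TRUE`).
#' @param method Correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @return data.frame with one row per query: `query_contig`,
#'   `best_match_virus`, `correlation`, `assigned_cluster`,
#'   `mean_cluster_correlation` (mean r against all members of the
#'   assigned cluster, for transparency), `same_pool`, `recruited`.
#' @export
recruit <- function(query_z, virus_z, virus_assignments, threshold = 0.9,
                    require_same_pool = TRUE,
                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_that(nrow(virus_z) >= 1L, "empty virus profile set")
  missing <- setdiff(virus_z$contig_id, virus_assignments$contig_id)
  assert_that(length(missing) == 0L,
              "virus profile(s) without cluster assignment: %s",
              paste(missing, collapse = ", "))
  if (require_same_pool) {
    assert_that(!anyNA(query_z$pool_id) && !anyNA(virus_z$pool_id),
                "pool ids are required when require_same_pool = TRUE")
  }
  drop_q <- query_z$degenerate %||% rep(FALSE, nrow(query_z))
  drop_v <- virus_z$degenerate %||% rep(FALSE, nrow(virus_z))
  query_z <- query_z[!drop_q, , drop = FALSE]
  virus_z <- virus_z[!drop_v, , drop = FALSE]
  qm <- profile_matrix(query_z)
  vm <- profile_matrix(virus_z)
  vcl <- setNames(virus_assignments$cluster, virus_assignments$contig_id)

  rows <- lapply(seq_len(nrow(query_z)), function(i) {
    eligible <- if (require_same_pool) {
      which(virus_z$pool_id == query_z$pool_id[i])
    } else seq_len(nrow(virus_z))
    if (length(eligible) == 0L) {
      return(data.frame(query_contig = query_z$contig_id[i],
                        best_match_virus = NA_character_,
                        correlation = NA_real_,
                        assigned_cluster = NA_integer_,
                        mean_cluster_correlation = NA_real_,
                        same_pool = require_same_pool, recruited = FALSE,
                        stringsAsFactors = FALSE))
    }
    r <- as.numeric(cor(qm[i, ], t(vm[eligible, , drop = FALSE]),
                        method = method))
    best <- which.max(r)
    best_id <- virus_z$contig_id[eligible[best]]
    cl <- unname(vcl[best_id])
    members <- intersect(names(vcl)[vcl == cl],
                         virus_z$contig_id[eligible])
    mean_r <- mean(r[match(members, virus_z$contig_id[eligible])])
    data.frame(query_contig = query_z$contig_id[i],
               best_match_virus = best_id,
               correlation = r[best],
               assigned_cluster = cl,
               mean_cluster_correlation = mean_r,
               same_pool = require_same_pool,
               recruited = r[best] >= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    query_contig = character(), best_match_virus = character(),
    correlation = numeric(), assigned_cluster = integer(),
    mean_cluster_correlation = numeric(), same_pool = logical(),
    recruited = logical(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Host-contig reconstruction control
#'
#' Runs [recruit()] on profiles of contigs known to be of host origin. A
#' signature class that recruits many host contigs is non-specific for
#' viral origin; in practice the strand-biased (piRNA-like/degradation)
#' clusters absorb almost all host contigs while the siRNA cluster stays
#' clean.
#'
#' @inheritParams recruit
#' @param host_z z-profile data.frame of host contigs (passed the
#'   read-count gate).
#' @param signatures Optional signature table from [cluster_profiles()],
#'   joined onto the per-cluster summary.
#' @return List of class `reconstruction_control`: `records` (the
#'   recruitment table), `n_host`, `n_recruited`, `recruitment_rate`
#'   (`NA` when `n_host == 0`), `by_cluster` (data.frame `cluster`,
#'   `signature`, `n`, `fraction_of_recruited`).
#' @export
reconstruction_control <- function(host_z, virus_z, virus_assignments,
                                   threshold = 0.9,
                                   require_same_pool = TRUE,
                                   method = c("pearson", "spearman"),
                                   signatures = NULL) {
  method <- match.arg(method)
  if (nrow(host_z) == 0L) {
    return(structure(list(records = NULL, n_host = 0L, n_recruited = 0L,
                          recruitment_rate = NA_real_,
                          by_cluster = data.frame()),
                     class = "reconstruction_control"))
  }
  rec <- recruit(host_z, virus_z, virus_assignments, threshold = threshold,
                 require_same_pool = require_same_pool, method = method)
  n_rec <- sum(rec$recruited)
  got <- rec$assigned_cluster[rec$recruited]
  tab <- table(got)
  by_cl <- data.frame(cluster = as.integer(names(tab)),
                      n = as.integer(tab),
                      stringsAsFactors = FALSE)
  by_cl$fraction_of_recruited <- if (n_rec > 0) by_cl$n / n_rec else numeric(0)
  if (!is.null(signatures)) {
    by_cl$signature <- signatures$signature[match(by_cl$cluster,
                                                  signatures$cluster)]
  }
  structure(list(records = rec, n_host = nrow(rec), n_recruited = n_rec,
                 recruitment_rate = n_rec / nrow(rec), by_cluster = by_cl),
            class = "reconstruction_control")
}

#' @export
print.reconstruction_control <- function(x, ...) {
  cat(sprintf("<reconstruction control: %d host contigs, %d recruited (%s)>\n",
              x$n_host, x$n_recruited,
              ifelse(is.na(x$recruitment_rate), "rate undefined",
                     sprintf("%.1f%%", 100 * x$recruitment_rate))))
  if (nrow(x$by_cluster)) print(x$by_cluster, row.names = FALSE)
  invisible(x)
}
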