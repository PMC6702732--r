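#' Correlation matrix of z-score profiles
#'
#' Pairwise correlation of the 42-cell z-profiles. Degenerate (flat)
#' profiles have no defined correlation and are excluded with a message.
#'
#' @param zprofiles z-profile data.frame from [zscore_profiles()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal, dimnames =
#'   contig ids.
#' @export
correlation_matrix <- function(zprofiles,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  drop <- zprofiles$degenerate %||% rep(FALSE, nrow(zprofiles))
  if (any(drop)) {
    message("excluding degenerate profile(s): ",
            paste(zprofiles$contig_id[drop], collapse = ", "))
  }
  z <- profile_matrix(zprofiles[!drop, , drop = FALSE])
  assert_that(nrow(z) >= 2L,
              "need at least 2 non-degenerate profiles, got %d", nrow(z))
  r <- cor(t(z), method = method)
  diag(r) <- 1
  r
}

#' UPGMA (average linkage) hierarchical clustering
#'
#' Agglomerates the closest pair at each step; the distance between two
#' groups is the unweighted mean of all between-group pairwise distances,
#' and each merge is recorded at that height. Ties are broken by the
#' lexicographically smallest pair of group labels (a group is labelled by
#' its smallest member), making the dendrogram fully deterministic.
#'
#' @param d Square symmetric distance matrix with zero diagonal and
#'   dimnames, or a [stats::dist] object. For correlation clustering use
#'   `correlation_distance()`.
#' @return An object of class `hclust` (merge/height/order/labels), usable
#'   with [stats::cutree()] and [as_newick()].
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  assert_that(is.matrix(d) && nrow(d) == ncol(d),
              "distance matrix must be square")
  assert_that(max(abs(d - t(d))) <= 1e-12,
              "distance matrix must be symmetric")
  assert_that(all(abs(diag(d)) <= 1e-12),
              "distance matrix must have zero diagonal")
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  assert_that(n >= 2L, "need at least two leaves")

  # active clusters: id (negative leaf index or positive merge index),
  # size, label (smallest member id, for tie-breaking)
  active <- data.frame(node = -seq_len(n), size = 1L, label = labels,
                       stringsAsFactors = FALSE)
  dm <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    k <- nrow(dm)
    # closest pair; ties -> lexicographically smallest sorted label pair
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        lab <- sort(c(active$label[i], active$label[j]))
        cand <- list(i = i, j = j, dist = dm[i, j], lab = lab)
        if (is.null(best) || cand$dist < best$dist - 1e-15 ||
            (abs(cand$dist - best$dist) <= 1e-15 &&
             (lab[1] < best$lab[1] ||
              (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    merge[s, ] <- sort(c(active$node[i], active$node[j]))
    height[s] <- best$dist
    ni <- active$size[i]; nj <- active$size[j]
    # UPGMA update: unweighted average over original pairs
    newd <- (ni * dm[i, ] + nj * dm[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(k), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    active <- rbind(active[keep, , drop = FALSE],
                    data.frame(node = s, size = ni + nj,
                               label = min(active$label[c(i, j)]),
                               stringsAsFactors = FALSE))
  }
  hc <- list(merge = merge, height = height, order = integer(n),
             labels = labels, method = "average",
             call = match.call(), dist.method = "user")
  hc$order <- hclust_order(merge, n)
  class(hc) <- "hclust"
  hc
}

# leaf order for plotting: left-to-right traversal of the merge tree
hclust_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand_it <- expand(n - 1L)
  as.integer(expand_it)
}

#' Correlation distance matrix
#'
#' `d = 1 - r`, range \[0, 2\]: the standard distance for correlation
#' clustering of profiles.
#'
#' @param r Correlation matrix.
#' @return Distance matrix of the same shape.
#' @export
correlation_distance <- function(r) {
  d <- 1 - r
  diag(d) <- 0
  d
}

#' Cut a dendrogram into k clusters
#'
#' @param dend `hclust` object from [upgma()].
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Named integer vector mapping leaf label to cluster id.
#' @export
cut_clusters <- function(dend, k = 4) {
  n <- length(dend$labels)
  assert_that(k >= 1 && k <= n,
              "k must be between 1 and the number of leaves (%d), got %s",
              n, format(k))
  cutree(dend, k = k)
}

#' Classify a cluster's small RNA signature
#'
#' Rule-based labelling of a cluster from its mean z-profile and mean
#' positive-strand fraction, applied in order:
#' \enumerate{
#'   \item `sirna`: 21 nt enriched (`z >= z_enrich`) on both strands, no
#'     piRNA-band (23-29 nt) enrichment on either strand;
#'   \item `sirna_pirna_mixed`: 21 nt enriched on both strands and the
#'     mean z over 23-29 nt on either strand also `>= z_enrich`;
#'   \item `pirna_positive_biased`: 23-29 nt band enriched on the positive
#'     strand and strand fraction `>= bias_threshold`;
#'   \item `pirna_negative_biased`: the mirror on the negative strand with
#'     strand fraction `<= 1 - bias_threshold`;
#'   \item otherwise `unassigned`.
#' }
#'
#' @param mean_z Named 42-vector (cells `p15..p35`, `m15..m35`): the mean
#'   z-profile of the cluster's members.
#' @param mean_strand_fraction Mean positive-strand fraction of the
#'   members.
#' @param z_enrich Enrichment threshold on z (default 1.0).
#' @param bias_threshold Strand-bias threshold (default 0.75).
#' @return One of `"sirna"`, `"sirna_pirna_mixed"`,
#'   `"pirna_positive_biased"`, `"pirna_negative_biased"`, `"unassigned"`.
#' @export
classify_signature <- function(mean_z, mean_strand_fraction,
                               z_enrich = 1.0, bias_threshold = 0.75) {
  band <- 23:29
  z21p <- mean_z[["p21"]]
  z21m <- mean_z[["m21"]]
  band_p <- mean(mean_z[paste0("p", band)])
  band_m <- mean(mean_z[paste0("m", band)])
  sirna21 <- z21p >= z_enrich && z21m >= z_enrich
  band_enriched <- band_p >= z_enrich || band_m >= z_enrich
  if (sirna21 && !band_enriched) return("sirna")
  if (sirna21 && band_enriched) return("sirna_pirna_mixed")
  if (band_p >= z_enrich && mean_strand_fraction >= bias_threshold) {
    return("pirna_positive_biased")
  }
  if (band_m >= z_enrich && mean_strand_fraction <= 1 - bias_threshold) {
    return("pirna_negative_biased")
  }
  "unassigned"
}

#' Cluster z-profiles and label cluster signatures
#'
#' End-to-end clustering stage: correlation matrix, UPGMA on `1 - r`,
#' cut at `k`, then [classify_signature()] per cluster using the mean
#' z-profile and mean strand fraction of its members.
#'
#' @param zprofiles z-profile data.frame (non-degenerate rows used).
#' @param profiles Matching raw profile data.frame (for strand fractions).
#' @param k Number of clusters (default 4).
#' @param method Correlation method.
#' @inheritParams classify_signature
#' @return List of class `cluster_model`: `dendrogram` (`hclust`),
#'   `correlation` (matrix), `assignments` (data.frame `contig_id`,
#'   `cluster`), `signatures` (data.frame `cluster`, `signature`,
#'   `n_members`, `mean_strand_fraction`).
#' @export
cluster_profiles <- function(zprofiles, profiles, k = 4,
                             method = c("pearson", "spearman"),
                             z_enrich = 1.0, bias_threshold = 0.75) {
  method <- match.arg(method)
  r <- correlation_matrix(zprofiles, method = method)
  dend <- upgma(correlation_distance(r))
  assign_vec <- cut_clusters(dend, k = k)
  ids <- names(assign_vec)
  zm <- profile_matrix(zprofiles)[ids, , drop = FALSE]
  sf <- setNames(strand_fraction(profiles), profiles$contig_id)[ids]
  sig <- lapply(sort(unique(assign_vec)), function(cl) {
    members <- ids[assign_vec == cl]
    mean_z <- colMeans(zm[members, , drop = FALSE])
    msf <- mean(sf[members])
    data.frame(cluster = cl,
               signature = classify_signature(mean_z, msf,
                                              z_enrich = z_enrich,
                                              bias_threshold = bias_threshold),
               n_members = length(members),
               mean_strand_fraction = msf,
               stringsAsFactors = FALSE)
  })
  structure(
    list(dendrogram = dend, correlation = r,
         assignments = data.frame(contig_id = ids,
                                  cluster = unname(assign_vec),
                                  stringsAsFactors = FALSE),
         signatures = do.call(rbind, sig)),
    class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model: %d profiles, %d clusters>\n",
              nrow(x$assignments), nrow(x$signatures)))
  print(x$signatures, row.names = FALSE)
  invisible(x)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths place each node at half its merge height (ultrametric
#' tree, leaves at depth 0).
#'
#' @param dend `hclust` object.
#' @return Newick string terminated with `;`.
#' @export
as_newick <- function(dend) {
  build <- function(node) {
    if (node < 0) {
      list(str = dend$labels[-node], h = 0)
    } else {
      l <- build(dend$merge[node, 1])
      r <- build(dend$merge[node, 2])
      h <- dend$height[node] / 2
      list(str = sprintf("(%s:%.10g,%s:%.10g)", l$str, h - l$h,
                         r$str, h - r$h),
           h = h)
    }
  }
  paste0(build(nrow(dend$merge))$str, ";")
}
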