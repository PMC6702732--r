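# a small reference world: two virus profile archetypes in two clusters
make_reference <- function() {
  sirna_cells <- c(p21 = 400, m21 = 380, p20 = 40, m22 = 40)
  pirna_cells <- c(m27 = 250, m28 = 250, m26 = 120, m25 = 60, m23 = 30)
  vz <- rbind(make_profile(sirna_cells, contig_id = "v_sirna"),
              make_profile(pirna_cells, contig_id = "v_pirna"))
  list(profiles = vz, z = zscore_profiles(vz),
       assignments = data.frame(contig_id = c("v_sirna", "v_pirna"),
                                cluster = c(1L, 2L)))
}

test_that("a query identical in profile to a virus recruits at r = 1", {
  ref <- make_reference()
  q <- make_profile(c(p21 = 400, m21 = 380, p20 = 40, m22 = 40),
                    contig_id = "query1")
  rec <- recruit(zscore_profiles(q), ref$z, ref$assignments)
  expect_equal(rec$correlation, 1)
  expect_equal(rec$best_match_virus, "v_sirna")
  expect_equal(rec$assigned_cluster, 1L)
  expect_true(rec$recruited)
})

test_that("threshold is inclusive: correlation exactly at threshold recruits", {
  ref <- make_reference()
  q <- make_profile(c(p21 = 300, m21 = 200, m27 = 100, p18 = 50),
                    contig_id = "qb")
  qz <- zscore_profiles(q)
  free <- recruit(qz, ref$z, ref$assignments, threshold = -1)
  r_best <- free$correlation
  expect_lt(r_best, 1)
  at <- recruit(qz, ref$z, ref$assignments, threshold = r_best)
  expect_true(at$recruited)
  above <- recruit(qz, ref$z, ref$assignments,
                   threshold = r_best + 1e-12)
  expect_false(above$recruited)
})

test_that("uncorrelated queries are not recruited", {
  ref <- make_reference()
  q <- make_profile(c(p33 = 100, m15 = 100, p16 = 90, m34 = 110),
                    contig_id = "junk")
  rec <- recruit(zscore_profiles(q), ref$z, ref$assignments)
  expect_false(rec$recruited)
  expect_lt(rec$correlation, 0.9)
})

test_that("raising the threshold never increases the recruited count", {
  sim <- simulate_dataset(n_per_class = 8, reads_per_contig = 400, seed = 81)
  pr <- filter_profiles(compute_profiles(sim$alignments, sim$contigs))
  zp <- zscore_profiles(pr)
  truth <- setNames(sim$truth$true_class, sim$truth$contig_id)
  vz <- zp[truth[zp$contig_id] != "degradation", ]
  qz <- zp[truth[zp$contig_id] == "degradation", ]
  va <- data.frame(contig_id = vz$contig_id,
                   cluster = as.integer(factor(truth[vz$contig_id])))
  n_rec <- vapply(c(-1, 0, 0.5, 0.9, 0.99, 1), function(th) {
    sum(recruit(qz, vz, va, threshold = th,
                require_same_pool = FALSE)$recruited)
  }, numeric(1))
  expect_true(all(diff(n_rec) <= 0))
  expect_equal(n_rec[1], nrow(qz))
})

test_that("recruitment is independent of query order and deterministic", {
  sim <- simulate_dataset(n_per_class = 6, reads_per_contig = 300, seed = 82)
  pr <- filter_profiles(compute_profiles(sim$alignments, sim$contigs))
  zp <- zscore_profiles(pr)
  truth <- setNames(sim$truth$true_class, sim$truth$contig_id)
  vz <- zp[truth[zp$contig_id] == "sirna", ]
  qz <- zp[truth[zp$contig_id] != "sirna", ]
  va <- data.frame(contig_id = vz$contig_id, cluster = 1L)
  r1 <- recruit(qz, vz, va, require_same_pool = FALSE)
  r2 <- recruit(qz[rev(seq_len(nrow(qz))), ], vz, va,
                require_same_pool = FALSE)
  r2 <- r2[match(r1$query_contig, r2$query_contig), ]
  rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("pool constraint restricts candidates and is validated", {
  ref <- make_reference()
  ref$z$pool_id <- c("poolA", "poolA")
  q <- make_profile(c(p21 = 400, m21 = 380), contig_id = "q",
                    pool_id = "poolB")
  rec <- recruit(zscore_profiles(q), ref$z, ref$assignments,
                 require_same_pool = TRUE)
  expect_false(rec$recruited)
  expect_true(is.na(rec$best_match_virus))

  qa <- make_profile(c(p21 = 400, m21 = 380), contig_id = "q",
                     pool_id = "poolA")
  rec2 <- recruit(zscore_profiles(qa), ref$z, ref$assignments,
                  require_same_pool = TRUE)
  expect_true(rec2$recruited)

  ref_na <- make_reference()
  ref_na$z$pool_id <- NA_character_
  expect_error(recruit(zscore_profiles(qa), ref_na$z, ref_na$assignments),
               "pool ids are required")
})

test_that("empty virus set errors; empty host control is flagged", {
  ref <- make_reference()
  q <- zscore_profiles(make_profile(c(p21 = 10), contig_id = "q"))
  expect_error(recruit(q, ref$z[0, ], ref$assignments), "empty virus")
  ctrl <- reconstruction_control(ref$z[0, ], ref$z, ref$assignments)
  expect_equal(ctrl$n_host, 0L)
  expect_true(is.na(ctrl$recruitment_rate))
})

test_that("host contigs identical to a virus recruit 100% to its cluster", {
  ref <- make_reference()
  host <- rbind(
    make_profile(c(m27 = 250, m28 = 250, m26 = 120, m25 = 60, m23 = 30),
                 contig_id = "h1"),
    make_profile(c(m27 = 250, m28 = 250, m26 = 120, m25 = 60, m23 = 30),
                 contig_id = "h2"))
  ctrl <- reconstruction_control(zscore_profiles(host), ref$z,
                                 ref$assignments,
                                 require_same_pool = FALSE)
  expect_equal(ctrl$recruitment_rate, 1)
  expect_equal(ctrl$by_cluster$cluster, 2L)
  expect_equal(ctrl$by_cluster$fraction_of_recruited, 1)
})

test_that("degradation-profile host contigs avoid the siRNA cluster", {
  sim <- simulate_dataset(n_per_class = 12, reads_per_contig = 1000,
                          seed = 83)
  pr <- filter_profiles(compute_profiles(sim$alignments, sim$contigs))
  zp <- zscore_profiles(pr)
  truth <- setNames(sim$truth$true_class, sim$truth$contig_id)
  is_virus <- truth[zp$contig_id] %in% c("sirna", "pirna")
  model <- cluster_profiles(zp[is_virus, ], pr[is_virus, ], k = 2)
  sirna_cluster <- model$signatures$cluster[
    model$signatures$signature == "sirna"]
  expect_length(sirna_cluster, 1)
  host_z <- zp[truth[zp$contig_id] == "degradation", ]
  ctrl <- reconstruction_control(host_z, zp[is_virus, ],
                                 model$assignments,
                                 require_same_pool = FALSE,
                                 signatures = model$signatures)
  in_sirna <- ctrl$records$recruited &
    ctrl$records$assigned_cluster == sirna_cluster
  frac <- if (ctrl$n_recruited > 0) sum(in_sirna) / ctrl$n_recruited else 0
  expect_lte(frac, 0.05)
})
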