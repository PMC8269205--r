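# Endemism statistics, compositional transforms, sample clustering,
# top-feature cross-check.

toy_incidence <- function() {
  # 10 features x 7 sites in 3 regions (2 + 2 + 3 sites)
  sites <- c("r1s1", "r1s2", "r2s1", "r2s2", "r3s1", "r3s2", "r3s3")
  hier <- data.frame(site = sites,
                     field = rep(c("f1", "f2", "f3"), c(2, 2, 3)),
                     region = rep(c("R1", "R2", "R3"), c(2, 2, 3)),
                     stringsAsFactors = FALSE)
  mat <- matrix(0L, 10, 7, dimnames = list(paste0("x", 1:10), sites))
  mat["x1", ] <- 1                        # everywhere
  mat["x2", c("r1s1", "r1s2")] <- 1       # all sites of R1 only
  mat["x3", "r1s1"] <- 1                  # single site
  mat["x4", c("r1s1", "r2s1")] <- 1       # one site in each of R1, R2
  mat["x5", c("r3s1", "r3s2")] <- 1       # 2 of 3 sites in R3
  mat["x6", c("r3s1", "r3s2", "r3s3")] <- 1
  mat["x7", "r2s2"] <- 1
  mat["x8", c("r2s1", "r2s2")] <- 1
  mat["x9", c("r1s2", "r2s2", "r3s3")] <- 1
  mat["x10", "r3s3"] <- 1
  incidence_matrix(mat, hier)
}

test_that("endemism statistics equal the exhaustive hand count", {
  st <- endemism_stats(toy_incidence())
  # R1 features: x1,x2,x3,x4,x9 (5). multi-site: x1,x2 (2). all sites: x1,x2.
  r1 <- st[st$scope == "R1", ]
  expect_identical(r1$n_features, 5L)
  expect_equal(r1$pct_multi_site, 100 * 2 / 5)
  expect_equal(r1$pct_all_sites, 100 * 2 / 5)
  # R2 features: x1,x4,x7,x8,x9 (5). multi: x1,x8. all: x1,x8.
  r2 <- st[st$scope == "R2", ]
  expect_identical(r2$n_features, 5L)
  expect_equal(r2$pct_multi_site, 40)
  expect_equal(r2$pct_all_sites, 40)
  # R3 features: x1,x5,x6,x9,x10 (5). multi: x1,x5,x6. all 3 sites: x1,x6.
  r3 <- st[st$scope == "R3", ]
  expect_identical(r3$n_features, 5L)
  expect_equal(r3$pct_multi_site, 60)
  expect_equal(r3$pct_all_sites, 40)
  # all regions: x1,x4? x4 misses R3. x9 in all three; x1 in all three -> 2/10
  glob <- st[st$scope == "all regions", ]
  expect_equal(glob$pct_all_regions, 20)

  # single-region single-feature degenerate case
  m <- matrix(c(1L, 0L, 0L), 1, 3,
              dimnames = list("f", c("s1", "s2", "s3")))
  h <- data.frame(site = c("s1", "s2", "s3"), field = "f1", region = "R")
  st1 <- endemism_stats(incidence_matrix(m, h))
  expect_equal(st1$pct_multi_site[1], 0)
  expect_equal(st1$pct_all_sites[1], 0)
})

test_that("zero replacement follows the multiplicative formulas", {
  tbl <- rbind(S1 = c(0, 5, 5), S2 = c(2, 3, 5), S3 = c(0, 0, 10))
  colnames(tbl) <- c("p1", "p2", "p3")

  czm <- zero_replace(tbl, "CZM", frac = 0.65)
  expect_true(all(czm > 0))
  expect_identical(czm["S2", ], tbl["S2", ])        # no zeros: unchanged
  expect_lt(czm["S1", "p1"], min(tbl["S1", tbl["S1", ] > 0]))
  # direct transcription of the formula, proportions then count scale
  n <- 10; delta <- 0.65 / n
  expect_equal(unname(czm["S1", ]),
               c(delta, 0.5 * (1 - delta), 0.5 * (1 - delta)) * n)

  bl <- zero_replace(tbl, "BayesLaplace")
  expect_true(all(bl > 0))
  expect_identical(bl["S2", ], tbl["S2", ])
  d_bl <- 1 / (10 + 3)
  expect_equal(unname(bl["S3", ]),
               c(d_bl, d_bl, 1 * (1 - 2 * d_bl)) * 10)

  expect_error(zero_replace(rbind(S1 = c(0, 0, 0))), "S1")
})

test_that("clr rows sum to zero, are scale invariant, and symmetric rows
           vanish", {
  expect_equal(unname(clr_transform(rbind(c(7, 7, 7, 7)))[1, ]), rep(0, 4))
  set.seed(61)
  x <- matrix(rexp(60) + 0.1, 6, 10)
  z <- clr_transform(x)
  expect_true(all(abs(rowSums(z)) < 1e-12))
  expect_equal(clr_transform(10 * x), z)
  expect_error(clr_transform(rbind(c(1, 0, 2))), "non-positive")

  # rows with identical composition and zero pattern give identical clr
  # output (the imputed value depends on the row total, so equality is
  # guaranteed at equal totals)
  tbl <- rbind(a = c(0, 4, 6, 10), b = c(0, 4, 6, 10))
  colnames(tbl) <- paste0("p", 1:4)
  z2 <- clr_transform(zero_replace(tbl, "CZM"))
  expect_equal(unname(z2["a", ]), unname(z2["b", ]))
})

test_that("Ward.D2 clustering heights, duplicates and order invariance", {
  m <- rbind(A = c(0, 0, 0), B = c(3, 4, 0))
  cl <- cluster_samples(m, n_boot = 0)
  expect_equal(cl$hclust$height, 5)    # the Euclidean distance

  m3 <- rbind(A = c(0, 0, 0), B = c(3, 4, 0), B2 = c(3, 4, 0))
  cl3 <- cluster_samples(m3, n_boot = 0)
  expect_equal(min(cl3$hclust$height), 0)   # duplicated sample merges first

  set.seed(62)
  m4 <- matrix(rnorm(40), 8, 5,
               dimnames = list(paste0("S", 1:8), paste0("p", 1:5)))
  c1 <- cluster_samples(m4, n_boot = 0)
  c2 <- cluster_samples(m4[sample(8), ], n_boot = 0)
  d1 <- as.matrix(stats::cophenetic(c1$hclust))
  d2 <- as.matrix(stats::cophenetic(c2$hclust))[rownames(d1), colnames(d1)]
  expect_equal(d1, d2)

  expect_error(cluster_samples(m[1, , drop = FALSE]), "2 samples")
})

test_that("well-separated groups get near-full bootstrap support", {
  set.seed(63)
  g1 <- matrix(rnorm(40, 0, 0.1), 4, 10)
  g2 <- matrix(rnorm(40, 5, 0.1), 4, 10)
  m <- rbind(g1, g2)
  rownames(m) <- paste0("S", 1:8)
  colnames(m) <- paste0("p", 1:10)
  cl <- cluster_samples(m, n_boot = 100)
  sup <- group_support(m, list(grp1 = paste0("S", 1:4),
                               grp2 = paste0("S", 5:8)), n_boot = 100)
  expect_gte(min(sup), 95)
})

test_that("top-feature selection and cross-check match an exhaustive oracle", {
  ab <- c(v1 = 5, v2 = 10, v3 = 10, v4 = 1)
  expect_identical(top_features(ab, 2), c("v2", "v3"))  # tie by identifier
  expect_message(all4 <- top_features(ab, 9), "4")
  expect_length(all4, 4)

  set.seed(64)
  contigs <- setNames(vapply(1:6, function(i) rand_seq(800), ""),
                      paste0("vc", 1:6))
  votu <- data.frame(contig_id = names(contigs),
                     votu_id = paste0("vOTU", rep(1:3, each = 2)),
                     is_representative = rep(c(TRUE, FALSE), 3),
                     contig_length = 800L, stringsAsFactors = FALSE)
  # spacer cluster members: one planted from vOTU2's second contig
  spacers <- c(spA = substr(contigs[["vc4"]], 101, 134),
               spB = rand_seq(34), spC = rand_seq(34))
  sc <- data.frame(node = names(spacers),
                   cluster_id = c("SC1", "SC1", "SC2"),
                   stringsAsFactors = FALSE)
  hits <- top_feature_crosscheck(c("vOTU1", "vOTU2"), c("SC1", "SC2"),
                                 votu, sc, contigs, spacers)
  expect_identical(hits$votu_id, "vOTU2")
  expect_identical(hits$spacer_cluster_id, "SC1")
  expect_identical(attr(hits, "n_top_clusters_matched"), 1L)

  # exhaustive oracle over all (cluster, votu) pairs
  oracle <- list()
  for (cid in c("SC1", "SC2")) {
    for (v in c("vOTU1", "vOTU2")) {
      mem_sp <- spacers[sc$node[sc$cluster_id == cid]]
      mem_ct <- contigs[votu$contig_id[votu$votu_id == v]]
      found <- nrow(naive_hamming_scan(mem_sp, mem_ct, 1)) > 0
      if (found) oracle[[length(oracle) + 1L]] <- c(v, cid)
    }
  }
  oracle_df <- do.call(rbind, oracle)
  expect_identical(nrow(hits), nrow(oracle_df))
  expect_identical(hits$votu_id, oracle_df[, 1])
  expect_identical(hits$spacer_cluster_id, oracle_df[, 2])

  # disjoint sets: zero overlap
  none <- top_feature_crosscheck("vOTU1", "SC2", votu, sc, contigs, spacers)
  expect_identical(nrow(none), 0L)
})
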